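# Canonical study configuration: full factorial measurement-heterogeneity
# grid (432 scenarios), n = 2000 per sample, 10 000 replications each.
run:
  n_derivation: 2000
  n_validation: 2000
  replications: 10000
  seed: 2019
grid:
  families: [single, two_both, two_one, differential]
  psi_val: [0.0, 0.25]
  theta_val: [0.5, 1.0, 2.0]
  err_var_val: [0.5, 1.0, 2.0]   # validation error variances
  err_var_der: [0.5, 1.0, 2.0]   # derivation error variances
  rho: [0.0, 0.5, 0.9]           # two-predictor equicorrelations
  diff_site: [derivation, validation]
  diff_case_sd: [0.5, 1.0, 2.0]  # case-specific error SDs (noncase var 1.0)
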