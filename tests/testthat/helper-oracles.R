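# Independent brute-force oracle for the c-statistic: enumerate all
# case-noncase pairs, half credit for ties.
concordance_brute <- function(y, s) {
  cases <- s[y == 1]
  noncases <- s[y == 0]
  total <- 0
  for (a in cases) {
    for (b in noncases) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(noncases))
}

# Small single-predictor scenario used across tests.
quick_scenario <- function(err_var_der = 1, err_var_val = 1, psi_val = 0,
                           theta_val = 1, n = 2000, reps = 30, seed = 42) {
  scenario_spec(
    dgm = single_predictor_model(),
    derivation_specs = measurement_spec(err_var = err_var_der),
    validation_specs = measurement_spec(psi = psi_val, theta = theta_val,
                                        err_var = err_var_val),
    n_derivation = n, n_validation = n,
    n_replications = reps, seed = seed,
    id = "quick", family = "single",
    params = list(rho = NA_real_, psi_val = psi_val, theta_val = theta_val,
                  err_var_der = err_var_der, err_var_val = err_var_val,
                  diff_site = NA_character_, diff_case_var = NA_real_)
  )
}
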