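test_that("configurations are validated with offending keys named", {
  expect_silent(validate_config(default_config()))
  bad_rho <- default_config()
  bad_rho$grid$rho <- c(0, 1.2)
  expect_error(validate_config(bad_rho), "grid\\$rho")
  bad_fam <- default_config()
  bad_fam$grid$families <- c("single", "probit")
  expect_error(validate_config(bad_fam), "grid\\$families")
  bad_n <- default_config()
  bad_n$run$n_derivation <- 1
  expect_error(validate_config(bad_n), "run\\$n_derivation")
  bad_var <- default_config()
  bad_var$grid$err_var_val <- c(-1, 1)
  expect_error(validate_config(bad_var), "grid\\$err_var_val")
})

test_that("duplicate factor values are deduplicated with a warning", {
  cfg <- default_config()
  cfg$grid$psi_val <- c(0, 0, 0.25)
  expect_warning(out <- validate_config(cfg), "psi_val")
  expect_equal(out$grid$psi_val, c(0, 0.25))
  suppressWarnings(expect_length(build_grid(cfg, families = "single"), 54))
})

test_that("YAML configurations round-trip and partial files inherit defaults", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    run = list(replications = 5, seed = 11),
    grid = list(families = "single", psi_val = 0, theta_val = 1,
                err_var_val = 1, err_var_der = 1)
  ), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$run$replications, 5)
  expect_equal(cfg$run$n_derivation, 2000L) # inherited default
  grid <- build_grid(cfg)
  expect_length(grid, 1)
  expect_equal(grid[[1]]$n_replications, 5L)
  unlink(path)
  expect_error(read_run_config(path), "not found")
})

test_that("the packaged default configuration reproduces the full grid", {
  path <- system.file("extdata", "default_config.yaml", package = "measureval")
  expect_true(nzchar(path))
  man <- cmd_grid(read_run_config(path))
  expect_equal(nrow(man), 432)
})

test_that("cmd_grid writes a manifest without simulating", {
  out <- tempfile(fileext = ".csv")
  man <- cmd_grid(
    {
      cfg <- default_config()
      cfg$grid$families <- "single"
      cfg
    },
    out = out
  )
  expect_equal(nrow(man), 54)
  disk <- utils::read.csv(out)
  expect_equal(nrow(disk), 54)
  expect_true(all(c("id", "family", "psi_val", "theta_val", "err_var_der",
                    "err_var_val", "seed") %in% names(disk)))
  unlink(out)
})

test_that("cmd_simulate is deterministic, resumable and logged", {
  cfg <- default_config()
  cfg$run$replications <- 5L
  cfg$run$n_derivation <- 500L
  cfg$run$n_validation <- 500L
  cfg$grid <- utils::modifyList(cfg$grid, list(
    families = "single", psi_val = 0, theta_val = 1,
    err_var_val = c(0.5, 1), err_var_der = 1))

  dir1 <- tempfile(); dir2 <- tempfile()
  s1 <- cmd_simulate(cfg, dir1)
  s2 <- cmd_simulate(cfg, dir2)
  expect_identical(readLines(file.path(dir1, "scenario_summary.csv")),
                   readLines(file.path(dir2, "scenario_summary.csv")))
  expect_equal(nrow(s1), 2)
  log <- utils::read.csv(file.path(dir1, "run_log.csv"))
  expect_equal(log$id, s1$id)
  expect_true(all(log$n_excluded == s1$n_excluded))

  # resume: completed rows are kept untouched, nothing is recomputed
  s3 <- cmd_simulate(cfg, dir1)
  expect_equal(s3, s1)
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("cmd_report scales CITL for display and rejects bad input", {
  spec <- quick_scenario(psi_val = 0.25, reps = 10, seed = 13)
  summary <- run_scenario(spec)
  report <- cmd_report(summary)
  expect_equal(report$citl_mean_x10, 10 * summary$citl_mean)
  expect_match(report$c_validation, "^0\\.\\d{3} \\(0\\.\\d{3}\\)$")
  expect_equal(report$block, "sigma2(D) = sigma2(V)")

  expect_error(cmd_report(summary[, setdiff(names(summary), "slope_median")]),
               "slope_median")
  expect_error(cmd_report(summary[0, ]), "empty")
})

test_that("report files and figures are written", {
  cfg <- default_config()
  cfg$run$replications <- 4L
  cfg$run$n_derivation <- 400L
  cfg$run$n_validation <- 400L
  cfg$grid <- utils::modifyList(cfg$grid, list(
    families = "single", psi_val = 0, theta_val = 1,
    err_var_val = c(0.5, 1), err_var_der = 1))
  dir <- tempfile()
  s <- cmd_simulate(cfg, dir)
  rep_dir <- file.path(dir, "report")
  out <- cmd_report(file.path(dir, "scenario_summary.csv"), out_dir = rep_dir)
  expect_true(file.exists(file.path(rep_dir, "report.csv")))
  expect_true(file.exists(file.path(rep_dir, "slopes.pdf")))
  disk <- utils::read.csv(file.path(rep_dir, "report.csv"))
  expect_equal(disk$citl_mean_x10, out$citl_mean_x10, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("calibration plots are well-formed ggplot objects", {
  set.seed(71)
  coh <- draw_cohort(2000, single_predictor_model())
  fit <- fit_logistic(coh$y, coh$X)
  p <- plot_calibration(coh$y, fit$fitted)
  expect_s3_class(p, "ggplot")
  spec <- quick_scenario(reps = 4, seed = 3)
  s <- run_scenario(spec)
  expect_s3_class(plot_slope_summary(s), "ggplot")
})
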