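#' Define one derivation-to-validation simulation scenario
#'
#' A scenario fixes the outcome-generating model, the per-predictor
#' measurement specifications in the derivation and validation settings,
#' sample sizes, the number of Monte Carlo replications and the root seed.
#' Predictors whose `heterogeneous_mask` entry is `FALSE` are measured
#' consistently across settings: their validation specification is forced to
#' equal the derivation one.
#'
#' @param dgm An [outcome_model()].
#' @param derivation_specs,validation_specs A single [measurement_spec()]
#'   (recycled over predictors) or a list with one spec per predictor.
#' @param heterogeneous_mask Logical vector, one flag per predictor;
#'   default: all heterogeneous.
#' @param n_derivation,n_validation Sample sizes (default 2000 each).
#' @param n_replications Monte Carlo replications (default 10000).
#' @param seed Root seed of the scenario; per-replication seeds are derived
#'   from it (see [replication_seeds()]).
#' @param id Optional scenario identifier.
#' @param family Optional family label (e.g. `"single"`).
#' @param params Optional named list of factor values, carried into
#'   summaries.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(dgm, derivation_specs, validation_specs,
                          heterogeneous_mask = NULL,
                          n_derivation = 2000L, n_validation = 2000L,
                          n_replications = 10000L, seed = 1L,
                          id = NULL, family = NA_character_,
                          params = list()) {
  stopifnot(inherits(dgm, "outcome_model"),
            n_derivation >= 2, n_validation >= 2, n_replications >= 1)
  P <- dgm$n_predictors
  derivation_specs <- as_spec_list(derivation_specs, P)
  validation_specs <- as_spec_list(validation_specs, P)
  if (is.null(heterogeneous_mask)) heterogeneous_mask <- rep(TRUE, P)
  stopifnot(is.logical(heterogeneous_mask), length(heterogeneous_mask) == P)
  validation_specs[!heterogeneous_mask] <- derivation_specs[!heterogeneous_mask]
  structure(
    list(
      dgm = dgm,
      derivation_specs = derivation_specs,
      validation_specs = validation_specs,
      heterogeneous_mask = heterogeneous_mask,
      n_derivation = as.integer(n_derivation),
      n_validation = as.integer(n_validation),
      n_replications = as.integer(n_replications),
      seed = as.integer(seed),
      id = if (is.null(id)) NA_character_ else as.character(id),
      family = family,
      params = params
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s [%s]: P = %d, n = %d/%d, %d replications, seed %d\n",
              x$id, x$family, x$dgm$n_predictors, x$n_derivation,
              x$n_validation, x$n_replications, x$seed))
  invisible(x)
}

#' Per-replication seed table of a scenario
#'
#' Derives a deterministic vector of sub-stream seeds from a root seed, so
#' that any single replication can be reproduced in isolation.
#'
#' @param seed Root seed.
#' @param n_replications Number of replications.
#' @return Integer vector of seeds.
#' @export
replication_seeds <- function(seed, n_replications) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n_replications)
}

#' Run a single derivation-to-validation replication
#'
#' Draws a derivation cohort, applies the derivation measurement
#' specifications, fits the prediction model on the pragmatic measurements,
#' records in-sample performance, then draws an independent validation
#' cohort from the same population, applies the validation specifications,
#' forms the transported linear predictor (derivation coefficients applied
#' to validation measurements) and records out-of-sample performance.
#' Replications in which a maximum likelihood fit fails to converge (e.g.
#' separation) are flagged as excluded, never redrawn.
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional seed for this replication.
#' @return A named numeric vector with elements `c_der`, `brier_der`,
#'   `c_val`, `slope`, `citl`, `brier_val`, `brier_cal_val`,
#'   `brier_ref_val`, `excluded`.
#' @export
run_replication <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  excluded_record <- c(
    c_der = NA_real_, brier_der = NA_real_, c_val = NA_real_,
    slope = NA_real_, citl = NA_real_, brier_val = NA_real_,
    brier_cal_val = NA_real_, brier_ref_val = NA_real_, excluded = 1
  )

  der <- draw_cohort(spec$n_derivation, spec$dgm)
  w_der <- apply_measurement(der$X, der$y, spec$derivation_specs)
  fit <- fit_logistic(der$y, w_der)
  if (!fit$converged) return(excluded_record)
  lp_der <- linear_predictor(fit, w_der)

  val <- draw_cohort(spec$n_validation, spec$dgm)
  w_val <- apply_measurement(val$X, val$y, spec$validation_specs)
  lp_val <- linear_predictor(fit, w_val)
  p_val <- stats::plogis(lp_val)

  cal <- recalibrate(val$y, lp_val)
  if (!cal$converged) return(excluded_record)
  parts <- brier_decomposition(val$y, p_val)

  c(
    c_der = concordance(der$y, lp_der),
    brier_der = brier_score(der$y, stats::plogis(lp_der)),
    c_val = concordance(val$y, lp_val),
    slope = cal$slope,
    citl = calibration_in_the_large(val$y, lp_val),
    brier_val = parts$total,
    brier_cal_val = parts$calibration_term,
    brier_ref_val = parts$refinement_term,
    excluded = 0
  )
}

#' Aggregate per-replication records into a scenario summary
#'
#' The c-statistic, calibration-in-the-large and Brier score are summarized
#' by their mean, the calibration slope by its median; every metric also
#' reports its across-replication standard deviation. Excluded replications
#' are dropped from the aggregation and counted.
#'
#' @param records Matrix or data frame of [run_replication()] records.
#' @param spec Optional [scenario_spec()]; when given, its id, family and
#'   factor values prefix the summary row.
#' @return A one-row data frame (the shape of one scenario summary row).
#' @export
summarize_replications <- function(records, spec = NULL) {
  records <- as.data.frame(records)
  n_total <- nrow(records)
  keep <- records$excluded == 0
  n_excluded <- sum(!keep)
  if (!any(keep)) {
    stop("all replications were excluded (non-convergence)", call. = FALSE)
  }
  r <- records[keep, , drop = FALSE]
  head <- data.frame(id = NA_character_, family = NA_character_)
  if (!is.null(spec)) {
    head$id <- spec$id
    head$family <- spec$family
    for (nm in names(spec$params)) head[[nm]] <- spec$params[[nm]]
  }
  cbind(head, data.frame(
    n_replications = n_total,
    n_excluded = n_excluded,
    c_der_mean = mean(r$c_der), c_der_sd = stats::sd(r$c_der),
    c_val_mean = mean(r$c_val), c_val_sd = stats::sd(r$c_val),
    slope_median = stats::median(r$slope), slope_sd = stats::sd(r$slope),
    citl_mean = mean(r$citl), citl_sd = stats::sd(r$citl),
    brier_der_mean = mean(r$brier_der), brier_der_sd = stats::sd(r$brier_der),
    brier_val_mean = mean(r$brier_val), brier_val_sd = stats::sd(r$brier_val),
    brier_cal_val_mean = mean(r$brier_cal_val),
    brier_ref_val_mean = mean(r$brier_ref_val)
  ))
}

#' Run all replications of a scenario and summarize them
#'
#' Deterministic given the scenario seed: per-replication seeds come from
#' [replication_seeds()], so the aggregate is invariant to execution order
#' and any replication can be re-run in isolation.
#'
#' @param spec A [scenario_spec()].
#' @param n_replications Optional override of the replication count.
#' @param keep_replications If `TRUE`, the per-replication records are
#'   attached as attribute `"replications"`.
#' @return A one-row data frame, see [summarize_replications()].
#' @export
run_scenario <- function(spec, n_replications = NULL,
                         keep_replications = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  n_rep <- if (is.null(n_replications)) spec$n_replications else as.integer(n_replications)
  stopifnot(n_rep >= 2)
  seeds <- replication_seeds(spec$seed, n_rep)
  records <- matrix(NA_real_, nrow = n_rep, ncol = 9L)
  for (r in seq_len(n_rep)) {
    records[r, ] <- run_replication(spec, seed = seeds[r])
  }
  colnames(records) <- c("c_der", "brier_der", "c_val", "slope", "citl",
                         "brier_val", "brier_cal_val", "brier_ref_val",
                         "excluded")
  out <- summarize_replications(records, spec)
  if (keep_replications) attr(out, "replications") <- as.data.frame(records)
  out
}

#' Run a list of scenarios
#'
#' @param scenarios List of [scenario_spec()] objects (e.g. from
#'   [build_grid()]).
#' @param n_replications Optional override applied to every scenario.
#' @param progress Print one line per completed scenario.
#' @return A data frame with one summary row per scenario.
#' @export
run_scenarios <- function(scenarios, n_replications = NULL, progress = FALSE) {
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    rows[[i]] <- run_scenario(scenarios[[i]], n_replications = n_replications)
    if (progress) {
      message(sprintf("[%d/%d] %s done", i, length(scenarios),
                      scenarios[[i]]$id))
    }
  }
  do.call(rbind, rows)
}

# ---- scenario grid ----------------------------------------------------------

grid_family_single <- function(g, run, dgm = single_predictor_model(),
                               family = "single", rho = NA_real_,
                               mask = NULL) {
  factors <- expand.grid(
    err_var_der = g$err_var_der, err_var_val = g$err_var_val,
    theta_val = g$theta_val, psi_val = g$psi_val,
    KEEP.OUT.ATTRS = FALSE
  )
  lapply(seq_len(nrow(factors)), function(i) {
    f <- factors[i, ]
    scenario_spec(
      dgm = dgm,
      derivation_specs = measurement_spec(err_var = f$err_var_der),
      validation_specs = measurement_spec(psi = f$psi_val,
                                          theta = f$theta_val,
                                          err_var = f$err_var_val),
      heterogeneous_mask = mask,
      n_derivation = run$n_derivation, n_validation = run$n_validation,
      n_replications = run$replications,
      family = family,
      params = list(rho = rho, psi_val = f$psi_val, theta_val = f$theta_val,
                    err_var_der = f$err_var_der, err_var_val = f$err_var_val,
                    diff_site = NA_character_, diff_case_var = NA_real_)
    )
  })
}

grid_family_differential <- function(g, run) {
  factors <- expand.grid(
    other_err_var = g$err_var_der, theta_val = g$theta_val,
    diff_case_sd = g$diff_case_sd, diff_site = g$diff_site,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(factors)), function(i) {
    f <- factors[i, ]
    case_var <- f$diff_case_sd^2
    diff_spec <- measurement_spec(err_var0 = 1, err_var1 = case_var)
    if (f$diff_site == "derivation") {
      der <- diff_spec
      val <- measurement_spec(theta = f$theta_val, err_var = f$other_err_var)
      evd <- NA_real_; evv <- f$other_err_var
    } else {
      der <- measurement_spec(err_var = f$other_err_var)
      val <- measurement_spec(theta = f$theta_val,
                              err_var0 = 1, err_var1 = case_var)
      evd <- f$other_err_var; evv <- NA_real_
    }
    scenario_spec(
      dgm = single_predictor_model(),
      derivation_specs = der, validation_specs = val,
      n_derivation = run$n_derivation, n_validation = run$n_validation,
      n_replications = run$replications,
      family = "differential",
      params = list(rho = NA_real_, psi_val = 0, theta_val = f$theta_val,
                    err_var_der = evd, err_var_val = evv,
                    diff_site = f$diff_site, diff_case_var = case_var)
    )
  })
}

#' Build the full-factorial scenario grid
#'
#' Enumerates the canonical study grid: for every nondifferential family, a
#' full factorial over validation shift \eqn{\psi_V \in \{0, 0.25\}},
#' validation association \eqn{\theta_V \in \{0.5, 1, 2\}} and the
#' derivation and validation error variances
#' \eqn{\sigma^2_{\varepsilon} \in \{0.5, 1, 2\}} (derivation always random:
#' \eqn{\psi_D = 0}, \eqn{\theta_D = 1}), giving 54 single-predictor
#' scenarios and, crossed with \eqn{\rho \in \{0, 0.5, 0.9\}}, 162
#' scenarios each for the two-predictor model with both predictors
#' heterogeneous and with only the first heterogeneous. The differential
#' add-on family crosses the error site (derivation or validation), the
#' case-specific error SD \eqn{\{0.5, 1, 2\}} (noncase variance fixed at 1;
#' note the case-specific values are SDs, i.e. variances 0.25/1/4),
#' \eqn{\theta_V} and the nondifferential-side error variance: 54 more
#' scenarios, 432 in total. Duplicated factor values in the configuration
#' are dropped with a warning.
#'
#' @param config A configuration list, see [default_config()] /
#'   [read_run_config()].
#' @param families Subset of
#'   `c("single", "two_both", "two_one", "differential")` to enumerate.
#' @return A list of [scenario_spec()] objects with ids and seeds assigned.
#' @seealso [grid_manifest()], [differential_presets()]
#' @export
#' @examples
#' length(build_grid(families = "single")) # 54
build_grid <- function(config = default_config(),
                       families = config$grid$families) {
  config <- validate_config(config)
  g <- config$grid
  run <- config$run
  families <- match.arg(families,
                        c("single", "two_both", "two_one", "differential"),
                        several.ok = TRUE)
  out <- list()
  for (fam in families) {
    scns <- switch(fam,
      single = grid_family_single(g, run),
      two_both = unlist(lapply(g$rho, function(rho) {
        grid_family_single(g, run, dgm = two_predictor_model(rho),
                           family = "two_both", rho = rho)
      }), recursive = FALSE),
      two_one = unlist(lapply(g$rho, function(rho) {
        grid_family_single(g, run, dgm = two_predictor_model(rho),
                           family = "two_one", rho = rho,
                           mask = c(TRUE, FALSE))
      }), recursive = FALSE),
      differential = grid_family_differential(g, run)
    )
    for (i in seq_along(scns)) scns[[i]]$id <- sprintf("%s_%03d", fam, i)
    out <- c(out, scns)
  }
  for (i in seq_along(out)) out[[i]]$seed <- as.integer(run$seed + i)
  out
}

#' Tabulate a scenario grid
#'
#' @param scenarios List of [scenario_spec()] objects.
#' @return A data frame with one row per scenario: id, family, factor
#'   values, sample sizes, replication count and seed.
#' @export
grid_manifest <- function(scenarios) {
  rows <- lapply(scenarios, function(s) {
    cbind(
      data.frame(id = s$id, family = s$family),
      as.data.frame(s$params, stringsAsFactors = FALSE),
      data.frame(n_derivation = s$n_derivation,
                 n_validation = s$n_validation,
                 n_replications = s$n_replications, seed = s$seed)
    )
  })
  do.call(rbind, rows)
}

#' Canonical differential measurement presets
#'
#' The four named single-predictor scenarios in which one setting has
#' differential random error (case-specific error SD 0.5 or 2.0, i.e.
#' variance 0.25 or 4; noncase variance 1.0) and the other setting is
#' nondifferential with error variance 1.0. With case SD 0.5 the cases are
#' measured more precisely than the noncases; with case SD 2.0 less
#' precisely.
#'
#' @param n_replications Replications per scenario.
#' @param seed Base seed; preset i uses `seed + i`.
#' @return Named list of four [scenario_spec()] objects:
#'   `derivation_case_sd_0.5`, `derivation_case_sd_2.0`,
#'   `validation_case_sd_0.5`, `validation_case_sd_2.0`.
#' @export
differential_presets <- function(n_replications = 10000L, seed = 2019L) {
  nondiff <- measurement_spec(err_var = 1)
  mk <- function(site, case_sd, i) {
    diff_spec <- measurement_spec(err_var0 = 1, err_var1 = case_sd^2)
    scenario_spec(
      dgm = single_predictor_model(),
      derivation_specs = if (site == "derivation") diff_spec else nondiff,
      validation_specs = if (site == "validation") diff_spec else nondiff,
      n_replications = n_replications, seed = seed + i,
      id = sprintf("%s_case_sd_%.1f", site, case_sd),
      family = "differential",
      params = list(diff_site = site, diff_case_var = case_sd^2)
    )
  }
  specs <- list(mk("derivation", 0.5, 1L), mk("derivation", 2.0, 2L),
                mk("validation", 0.5, 3L), mk("validation", 2.0, 4L))
  names(specs) <- vapply(specs, `[[`, "", "id")
  specs
}

#' Large-sample measurement error versus measurement heterogeneity
#'
#' Contrasts within-sample measurement error with cross-setting measurement
#' heterogeneity in one large sample per error variance. Three settings:
#' `"re_estimated"` fits the model on the pragmatic measurement W and
#' evaluates it in-sample (within-sample error; slope 1 and zero Brier
#' calibration term by construction); `"exact_to_pragmatic"` fits on the
#' exact measurement X and transports the coefficients to W
#' (validation noisier: slope below 1); `"pragmatic_to_exact"` fits on W
#' and transports to X (validation more precise: slope above 1).
#'
#' @param setting One of `"exact_to_pragmatic"`, `"re_estimated"`,
#'   `"pragmatic_to_exact"`.
#' @param err_var_grid Error variances of the pragmatic measurement.
#' @param n Sample size (default one million).
#' @param model The outcome-generating model.
#' @return A data frame with one row per error variance: calibration slope,
#'   calibration-in-the-large, c-statistic, Brier score and its components.
#' @export
run_large_sample <- function(setting = c("exact_to_pragmatic", "re_estimated",
                                         "pragmatic_to_exact"),
                             err_var_grid = c(0.5, 1, 2), n = 1e6,
                             model = single_predictor_model()) {
  setting <- match.arg(setting)
  rows <- lapply(err_var_grid, function(v) {
    coh <- draw_cohort(n, model)
    w <- apply_measurement(coh$X, coh$y, measurement_spec(err_var = v))
    fit_on <- switch(setting,
                     re_estimated = w,
                     exact_to_pragmatic = coh$X,
                     pragmatic_to_exact = w)
    eval_on <- switch(setting,
                      re_estimated = w,
                      exact_to_pragmatic = w,
                      pragmatic_to_exact = coh$X)
    fit <- fit_logistic(coh$y, fit_on)
    lp <- linear_predictor(fit, eval_on)
    cal <- recalibrate(coh$y, lp)
    parts <- brier_decomposition(coh$y, stats::plogis(lp))
    data.frame(
      setting = setting, err_var = v,
      slope = cal$slope,
      citl = calibration_in_the_large(coh$y, lp),
      c_stat = concordance(coh$y, lp),
      brier = parts$total,
      brier_calibration = parts$calibration_term,
      brier_refinement = parts$refinement_term,
      n = n
    )
  })
  do.call(rbind, rows)
}
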