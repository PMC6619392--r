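#' Default run configuration
#'
#' The canonical study configuration: derivation and validation samples of
#' n = 2000, 10 000 replications per scenario, and the full factor grid
#' (see [build_grid()]).
#'
#' @return A nested list with blocks `run` and `grid`.
#' @export
default_config <- function() {
  list(
    run = list(n_derivation = 2000L, n_validation = 2000L,
               replications = 10000L, seed = 2019L),
    grid = list(
      families = c("single", "two_both", "two_one", "differential"),
      psi_val = c(0, 0.25),
      theta_val = c(0.5, 1, 2),
      err_var_val = c(0.5, 1, 2),
      err_var_der = c(0.5, 1, 2),
      rho = c(0, 0.5, 0.9),
      diff_site = c("derivation", "validation"),
      diff_case_sd = c(0.5, 1, 2)
    )
  )
}

config_fail <- function(key, msg) {
  stop(sprintf("config key '%s': %s", key, msg), call. = FALSE)
}

check_numeric_factor <- function(x, key, lower = -Inf, upper = Inf,
                                 open_upper = FALSE) {
  if (is.null(x) || length(x) == 0) config_fail(key, "no values supplied")
  if (!is.numeric(x) || anyNA(x)) config_fail(key, "values must be numeric")
  if (any(x < lower) || any(if (open_upper) x >= upper else x > upper)) {
    config_fail(key, sprintf("values must lie in [%g, %g%s", lower, upper,
                             if (open_upper) ")" else "]"))
  }
  ux <- unique(x)
  if (length(ux) < length(x)) {
    warning(sprintf("config key '%s': duplicated values dropped", key),
            call. = FALSE)
  }
  ux
}

#' Validate (and normalize) a run configuration
#'
#' Fills missing entries from [default_config()], checks every factor value
#' against its admissible range before any simulation starts, and drops
#' duplicated factor values with a warning. Errors name the offending key.
#'
#' @param config A configuration list.
#' @return The validated configuration.
#' @export
validate_config <- function(config) {
  base <- default_config()
  config <- utils::modifyList(base, config)
  run <- config$run
  for (k in c("n_derivation", "n_validation")) {
    if (!is.numeric(run[[k]]) || length(run[[k]]) != 1L || run[[k]] < 2) {
      config_fail(paste0("run$", k), "must be a single integer >= 2")
    }
  }
  if (!is.numeric(run$replications) || run$replications < 1) {
    config_fail("run$replications", "must be a positive integer")
  }
  if (!is.numeric(run$seed) || length(run$seed) != 1L ||
      abs(run$seed) >= 2^31 - 1) {
    config_fail("run$seed", "must be a single integer below 2^31")
  }
  g <- config$grid
  bad <- setdiff(g$families, c("single", "two_both", "two_one", "differential"))
  if (length(bad)) {
    config_fail("grid$families", paste("unknown family:", paste(bad, collapse = ", ")))
  }
  g$psi_val <- check_numeric_factor(g$psi_val, "grid$psi_val")
  g$theta_val <- check_numeric_factor(g$theta_val, "grid$theta_val")
  g$err_var_val <- check_numeric_factor(g$err_var_val, "grid$err_var_val", lower = 0)
  g$err_var_der <- check_numeric_factor(g$err_var_der, "grid$err_var_der", lower = 0)
  g$rho <- check_numeric_factor(g$rho, "grid$rho", lower = 0, upper = 1,
                                open_upper = TRUE)
  g$diff_case_sd <- check_numeric_factor(g$diff_case_sd, "grid$diff_case_sd",
                                         lower = 0)
  bad <- setdiff(g$diff_site, c("derivation", "validation"))
  if (length(bad)) config_fail("grid$diff_site", "must be 'derivation' and/or 'validation'")
  config$run <- run
  config$grid <- g
  config
}

#' Read a run configuration from a YAML (or JSON-like) file
#'
#' @param path Path to a YAML configuration file with blocks `run` and
#'   `grid`; missing entries fall back to [default_config()].
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  }
  config <- yaml::read_yaml(path)
  if (!is.list(config)) config_fail(path, "top level must be a mapping")
  validate_config(config)
}

#' Enumerate the scenario grid and write a manifest
#'
#' Builds the scenario list from a configuration and writes one manifest
#' row per scenario (id, factor values, sample sizes, seed). No simulation
#' is performed.
#'
#' @param config Configuration list or path to a YAML file.
#' @param out Optional path of the manifest CSV.
#' @return The manifest data frame, invisibly.
#' @export
cmd_grid <- function(config = default_config(), out = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  man <- grid_manifest(build_grid(config))
  if (!is.null(out)) {
    utils::write.csv(man, out, row.names = FALSE)
    message(sprintf("wrote %d scenarios to %s", nrow(man), out))
  }
  invisible(man)
}

#' Run the scenario grid and write summary rows
#'
#' Executes [run_scenario()] for every scenario in the grid, appending one
#' summary row to `<out_dir>/scenario_summary.csv` as each scenario
#' completes, plus a run log with exclusion counts. The run is resumable:
#' scenario ids already present in the summary file are skipped, and an
#' interrupted run leaves completed rows intact. Deterministic under a
#' fixed configuration seed.
#'
#' @param config Configuration list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param n_replications Optional override of the per-scenario replication
#'   count (e.g. for pilot runs).
#' @param progress Print one line per completed scenario.
#' @return The full summary data frame, invisibly.
#' @export
cmd_simulate <- function(config = default_config(), out_dir,
                         n_replications = NULL, progress = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(out_dir, "scenario_summary.csv")
  log_path <- file.path(out_dir, "run_log.csv")
  scenarios <- build_grid(config)
  done <- character(0)
  if (file.exists(summary_path)) {
    done <- utils::read.csv(summary_path)$id
  }
  for (i in seq_along(scenarios)) {
    s <- scenarios[[i]]
    if (s$id %in% done) next
    t0 <- proc.time()[["elapsed"]]
    row <- run_scenario(s, n_replications = n_replications)
    append_csv_row(row, summary_path)
    log_row <- data.frame(id = s$id, n_replications = row$n_replications,
                          n_excluded = row$n_excluded,
                          elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    append_csv_row(log_row, log_path)
    if (progress) {
      message(sprintf("[%d/%d] %s: slope %.3f, c(val) %.3f (%d excluded)",
                      i, length(scenarios), s$id, row$slope_median,
                      row$c_val_mean, row$n_excluded))
    }
  }
  invisible(utils::read.csv(summary_path))
}

append_csv_row <- function(row, path) {
  if (file.exists(path)) {
    utils::write.table(row, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  } else {
    utils::write.table(row, path, sep = ",", row.names = FALSE,
                       col.names = TRUE)
  }
}

block_label <- function(err_var_der, err_var_val) {
  ifelse(is.na(err_var_der) | is.na(err_var_val), "differential",
    ifelse(err_var_der < err_var_val, "sigma2(D) < sigma2(V)",
      ifelse(err_var_der > err_var_val, "sigma2(D) > sigma2(V)",
             "sigma2(D) = sigma2(V)")))
}

fmt_pair <- function(m, s) sprintf("%.3f (%.3f)", m, s)

#' Render a formatted report from scenario summaries
#'
#' Produces a grouped report table in the conventional layout: one row per
#' scenario, grouped by the comparison of derivation and validation error
#' variance, with calibration-in-the-large rescaled to the customary x10
#' display scale and each metric shown as "mean (SD)" (median for the
#' slope). Optionally writes the table and a calibration-slope overview
#' figure.
#'
#' @param summary A summary data frame from [cmd_simulate()] /
#'   [run_scenarios()], or the path of a summary CSV.
#' @param out_dir Optional output directory for `report.csv` and
#'   `slopes.pdf`.
#' @return The report data frame, invisibly.
#' @export
cmd_report <- function(summary, out_dir = NULL) {
  if (is.character(summary)) summary <- utils::read.csv(summary)
  required <- c("id", "family", "c_der_mean", "c_der_sd", "c_val_mean",
                "c_val_sd", "slope_median", "slope_sd", "citl_mean",
                "citl_sd", "brier_der_mean", "brier_der_sd",
                "brier_val_mean", "brier_val_sd")
  missing <- setdiff(required, names(summary))
  if (length(missing)) {
    stop("summary is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(summary) == 0L) stop("empty summary: nothing to report", call. = FALSE)
  evd <- if ("err_var_der" %in% names(summary)) summary$err_var_der else NA_real_
  evv <- if ("err_var_val" %in% names(summary)) summary$err_var_val else NA_real_
  report <- data.frame(
    id = summary$id,
    family = summary$family,
    block = block_label(evd, evv),
    c_derivation = fmt_pair(summary$c_der_mean, summary$c_der_sd),
    c_validation = fmt_pair(summary$c_val_mean, summary$c_val_sd),
    calibration_slope = fmt_pair(summary$slope_median, summary$slope_sd),
    citl_x10 = fmt_pair(10 * summary$citl_mean, 10 * summary$citl_sd),
    brier_derivation = fmt_pair(summary$brier_der_mean, summary$brier_der_sd),
    brier_validation = fmt_pair(summary$brier_val_mean, summary$brier_val_sd),
    citl_mean_x10 = 10 * summary$citl_mean
  )
  for (f in intersect(c("psi_val", "theta_val", "err_var_der", "err_var_val",
                        "rho", "diff_site", "diff_case_var"), names(summary))) {
    report[[f]] <- summary[[f]]
  }
  report <- report[order(report$family, report$block, report$id), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    p <- plot_slope_summary(summary)
    if (!is.null(p)) {
      ggplot2::ggsave(file.path(out_dir, "slopes.pdf"), p,
                      width = 8, height = 5)
    }
  }
  invisible(report)
}

#' Calibration-slope overview figure
#'
#' Median calibration slope per scenario against the validation error
#' variance, split by the validation association strength and additive
#' shift. Returns `NULL` when the summary has no nondifferential rows.
#'
#' @param summary Scenario summary data frame.
#' @return A ggplot object, or `NULL`.
#' @export
plot_slope_summary <- function(summary) {
  needed <- c("err_var_der", "err_var_val", "theta_val", "psi_val")
  if (!all(needed %in% names(summary))) return(NULL)
  df <- summary[!is.na(summary$err_var_der) & !is.na(summary$err_var_val), ]
  if (nrow(df) == 0L) return(NULL)
  df$theta <- factor(df$theta_val)
  df$psi <- factor(df$psi_val)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$err_var_val,
                                   y = .data$slope_median,
                                   colour = .data$theta,
                                   shape = .data$psi)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$theta, .data$psi))) +
    ggplot2::facet_wrap(~err_var_der, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "validation error variance",
                  y = "median calibration slope",
                  colour = expression(theta[V]), shape = expression(psi[V])) +
    ggplot2::theme_bw()
}

#' Calibration curve plot with a predicted-probability histogram
#'
#' @param y Binary outcomes.
#' @param p Predicted probabilities.
#' @param n_bins Quantile bins for the curve.
#' @return A ggplot object: binned calibration curve against the identity
#'   line, with a marginal histogram of the predictions.
#' @export
plot_calibration <- function(y, p, n_bins = 10L) {
  curve <- calibration_curve(y, p, n_bins = n_bins)
  hist_df <- data.frame(p = p)
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = hist_df,
      ggplot2::aes(x = .data$p, y = ggplot2::after_stat(.data$ncount) / 5),
      bins = 50, fill = "grey80", colour = NA
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$mean_pred, y = .data$obs_frac)) +
    ggplot2::geom_point(data = curve,
                        ggplot2::aes(x = .data$mean_pred, y = .data$obs_frac)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted probability", y = "observed fraction") +
    ggplot2::theme_bw()
}
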