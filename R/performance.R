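#' Empirical concordance (c-statistic)
#'
#' Fraction of case-noncase pairs in which the case has the higher score,
#' counting ties as half a concordant pair; equal to the area under the ROC
#' curve. Computed from midranks in O(n log n).
#'
#' @param y Binary 0/1 outcome vector with both classes present.
#' @param scores Numeric scores (risk predictions, linear predictors or raw
#'   measurements; any strictly increasing transform gives the same value).
#' @return The c-statistic, a number in \[0, 1\].
#' @export
#' @examples
#' concordance(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
concordance <- function(y, scores) {
  y <- as.numeric(y)
  if (length(y) != length(scores)) stop("length mismatch", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1", call. = FALSE)
  n1 <- sum(y)
  n0 <- length(y) - n1
  if (n1 == 0 || n0 == 0) {
    stop("concordance is undefined with a single outcome class", call. = FALSE)
  }
  r <- rank(scores) # midranks give ties half credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Class-conditional summary statistics of a measurement
#'
#' Sample means and variances of a measurement among cases and noncases,
#' the inputs of the binormal c-statistic approximation.
#'
#' @param y Binary 0/1 outcome vector.
#' @param m Numeric measurement vector.
#' @return An object of class `group_stats` with `mean1`, `mean0`, `var1`,
#'   `var0`, `n1`, `n0`.
#' @export
group_stats <- function(y, m) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(m), all(y %in% c(0, 1)))
  m1 <- m[y == 1]
  m0 <- m[y == 0]
  if (length(m1) < 1L || length(m0) < 1L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  structure(
    list(mean1 = mean(m1), mean0 = mean(m0),
         var1 = stats::var(m1), var0 = stats::var(m0),
         n1 = length(m1), n0 = length(m0)),
    class = "group_stats"
  )
}

#' Binormal approximation to the c-statistic
#'
#' Under class-conditional normality of the measurement,
#' \eqn{AUC = \Phi\left((\bar m_1 - \bar m_0) / \sqrt{s_1^2 + s_0^2}\right)}.
#'
#' @param stats A [group_stats()] object (or anything with the same fields).
#' @return The approximate c-statistic.
#' @export
binormal_auc <- function(stats) {
  total_var <- stats$var1 + stats$var0
  if (!is.finite(total_var) || total_var <= 0) {
    stop("binormal c-statistic is undefined with zero total variance",
         call. = FALSE)
  }
  stats::pnorm((stats$mean1 - stats$mean0) / sqrt(total_var))
}

#' Analytic change in the c-statistic under measurement error
#'
#' Given class-conditional statistics of the exact measurement x and a
#' measurement error specification, the pragmatic measurement w has
#' class-conditional moments
#' \eqn{\bar w_y = \psi_y + \theta_y \bar x_y} and
#' \eqn{s^2_{w_y} = \theta_y^2 s^2_{x_y} + \sigma^2_{\varepsilon, y}};
#' the change in the binormal c-statistic is
#' \deqn{\Delta AUC = \Phi\!\left(\frac{(\psi_1 + \theta_1 \bar x_1) -
#'   (\psi_0 + \theta_0 \bar x_0)}
#'   {\sqrt{\theta_1^2 s_{x_1}^2 + \sigma^2_{\varepsilon 1} +
#'          \theta_0^2 s_{x_0}^2 + \sigma^2_{\varepsilon 0}}}\right)
#'   - \Phi\!\left(\frac{\bar x_1 - \bar x_0}
#'   {\sqrt{s_{x_1}^2 + s_{x_0}^2}}\right).}
#' Random error (\eqn{\sigma^2_\varepsilon > 0}) makes \eqn{\Delta AUC < 0};
#' nondifferential systematic error leaves it unchanged beyond the random
#' part; differential error can move it in either direction.
#'
#' @param stats_x [group_stats()] of the exact measurement.
#' @param spec A [measurement_spec()].
#' @return The expected change in c-statistic \eqn{AUC_w - AUC_x}.
#' @export
delta_auc <- function(stats_x, spec) {
  stopifnot(inherits(spec, "measurement_spec"))
  auc_x <- binormal_auc(stats_x)
  w_stats <- list(
    mean1 = spec$psi1 + spec$theta1 * stats_x$mean1,
    mean0 = spec$psi0 + spec$theta0 * stats_x$mean0,
    var1 = spec$theta1^2 * stats_x$var1 + spec$err_var1,
    var0 = spec$theta0^2 * stats_x$var0 + spec$err_var0
  )
  binormal_auc(w_stats) - auc_x
}

check_probabilities <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("predicted probabilities must lie in [0, 1]", call. = FALSE)
  }
}

#' Brier score
#'
#' Mean squared difference between binary outcomes and predicted
#' probabilities, \eqn{BS = n^{-1} \sum_i (y_i - p_i)^2}; lower is better.
#'
#' @param y Binary 0/1 outcome vector.
#' @param p Predicted probabilities in \[0, 1\].
#' @return The Brier score, a number in \[0, 1\].
#' @export
brier_score <- function(y, p) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  check_probabilities(p)
  mean((y - p)^2)
}

#' Spiegelhalter decomposition of the Brier score
#'
#' For binary y the Brier score splits exactly into a calibration term
#' \eqn{n^{-1}\sum_i (y_i - p_i)(1 - 2 p_i)}, with expectation 0 under
#' perfect calibration, and a refinement term
#' \eqn{n^{-1}\sum_i p_i(1 - p_i)}, which is smaller the closer the
#' predictions are to 0 or 1. The identity
#' \eqn{(y-p)^2 = (y-p)(1-2p) + p(1-p)} holds term by term for
#' \eqn{y \in \{0,1\}}.
#'
#' @inheritParams brier_score
#' @return An object of class `brier_parts` with `total`,
#'   `calibration_term` and `refinement_term`.
#' @export
#' @examples
#' brier_decomposition(c(1, 0), c(0.8, 0.4))
brier_decomposition <- function(y, p) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  check_probabilities(p)
  calib <- mean((y - p) * (1 - 2 * p))
  refine <- mean(p * (1 - p))
  structure(
    list(total = calib + refine,
         calibration_term = calib,
         refinement_term = refine),
    class = "brier_parts"
  )
}

#' @export
print.brier_parts <- function(x, ...) {
  cat(sprintf("Brier score %.4f = calibration %.4f + refinement %.4f\n",
              x$total, x$calibration_term, x$refinement_term))
  invisible(x)
}

#' Expected change in Brier score under perfect calibration
#'
#' Under the null of perfect calibration the expected Brier score equals the
#' refinement term, so the expected impact of substituting the exact
#' measurement x by a pragmatic measurement w within the derivation sample
#' is the difference of refinement terms,
#' \eqn{E_0(\Delta BS) = n^{-1}\sum_i \hat\pi(w_i)(1 - \hat\pi(w_i)) -
#'       n^{-1}\sum_i \hat\pi(x_i)(1 - \hat\pi(x_i))};
#' a positive value means the w-based predictions are less accurate.
#'
#' @param p_w Predicted probabilities from the model using w.
#' @param p_x Predicted probabilities from the model using x.
#' @return The expected Brier score difference.
#' @export
expected_delta_brier <- function(p_w, p_x) {
  stopifnot(length(p_w) == length(p_x))
  check_probabilities(p_w)
  check_probabilities(p_x)
  mean(p_w * (1 - p_w)) - mean(p_x * (1 - p_x))
}

#' Logistic recalibration of a linear predictor
#'
#' Fits \eqn{logit P(y = 1) = a + b \cdot lp} by maximum likelihood. The
#' slope b is 1 and the intercept a is 0 when the linear predictor comes
#' from a maximum likelihood fit evaluated in its own derivation sample
#' ("weak calibration"); at external validation b < 1 flags predictions
#' that are too extreme (overfitting-like) and b > 1 predictions that are
#' too close to the event rate (underfitting-like).
#'
#' @param y_val Binary 0/1 outcomes of the validation sample.
#' @param lp Linear predictor (logit scale), non-constant.
#' @return An object of class `calibration_result` with `intercept` (a),
#'   `slope` (b) and `converged`.
#' @seealso [calibration_in_the_large()], [calibration_curve()]
#' @export
recalibrate <- function(y_val, lp) {
  if (stats::sd(lp) == 0) {
    stop("recalibration requires a non-constant linear predictor",
         call. = FALSE)
  }
  fit <- fit_logistic(y_val, matrix(lp, ncol = 1L))
  structure(
    list(intercept = fit$intercept_hat, slope = fit$coef_hat,
         converged = fit$converged),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Recalibration: intercept a = %.4f, slope b = %.4f\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Calibration-in-the-large
#'
#' Intercept of an intercept-only maximum likelihood logistic model with the
#' linear predictor as a fixed offset (a given b = 1). Zero in the
#' derivation sample; negative when predicted risks systematically exceed
#' the observed event rate.
#'
#' @inheritParams recalibrate
#' @return The calibration-in-the-large coefficient on the logit scale.
#' @export
calibration_in_the_large <- function(y_val, lp) {
  y_val <- as.numeric(y_val)
  stopifnot(length(y_val) == length(lp), all(y_val %in% c(0, 1)))
  if (sum(y_val) == 0 || sum(y_val) == length(y_val)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  fit <- withCallingHandlers(
    stats::glm.fit(matrix(1, length(y_val), 1L), y_val,
                   family = stats::binomial(), offset = lp,
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100L)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  unname(fit$coefficients[1L])
}

#' Quantile-binned calibration curve
#'
#' Groups predictions into quantile bins and reports, per bin, the mean
#' predicted probability, the observed event fraction and the bin size.
#' Quantile bins are used instead of a smoother so the curve is
#' reproducible and assumption-free; bins whose boundaries coincide (ties
#' in the predictions) are collapsed with a warning.
#'
#' @inheritParams brier_score
#' @param n_bins Number of quantile bins (default 10, i.e. deciles).
#' @return A data frame with columns `bin`, `mean_pred`, `obs_frac`, `n`.
#' @export
calibration_curve <- function(y, p, n_bins = 10L) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  check_probabilities(p)
  if (n_bins < 2L) stop("'n_bins' must be at least 2", call. = FALSE)
  breaks <- stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1L),
                            names = FALSE)
  breaks <- unique(breaks)
  if (length(breaks) < n_bins + 1L) {
    warning("tied predictions: collapsed to ", max(1L, length(breaks) - 1L),
            " usable bin(s)", call. = FALSE)
  }
  if (length(breaks) == 1L) {
    return(data.frame(bin = 1L, mean_pred = breaks, obs_frac = mean(y),
                      n = length(y)))
  }
  idx <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    bin = sort(unique(idx)),
    mean_pred = tapply(p, idx, mean),
    obs_frac = tapply(y, idx, mean),
    n = as.integer(tapply(y, idx, length))
  )
  rownames(out) <- NULL
  out
}

#' Full calibration assessment of a transported linear predictor
#'
#' Bundles the recalibration model, calibration-in-the-large and the binned
#' calibration curve for one validation.
#'
#' @inheritParams recalibrate
#' @param n_bins Bins for [calibration_curve()].
#' @return A `calibration_result` additionally carrying `citl` and `curve`.
#' @export
assess_calibration <- function(y_val, lp, n_bins = 10L) {
  res <- recalibrate(y_val, lp)
  res$citl <- calibration_in_the_large(y_val, lp)
  res$curve <- calibration_curve(y_val, stats::plogis(lp), n_bins = n_bins)
  res
}

#' Read an (outcome, prediction) table for standalone metric use
#'
#' Accepts a delimited text file whose first two columns are the binary
#' outcome and either a predicted probability or a linear predictor, and
#' returns the standard metric set.
#'
#' @param path Path to a delimited text file with a header.
#' @param scale Either `"probability"` or `"logit"`, the scale of the second
#'   column.
#' @param sep Field separator (default comma).
#' @return A one-row data frame with `c_stat`, `brier`, `brier_calibration`,
#'   `brier_refinement`, `slope`, `citl` and `n`.
#' @export
evaluate_prediction_table <- function(path, scale = c("probability", "logit"),
                                      sep = ",") {
  scale <- match.arg(scale)
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(tab) < 2L) stop("expected columns: outcome, prediction", call. = FALSE)
  y <- as.numeric(tab[[1L]])
  v <- as.numeric(tab[[2L]])
  lp <- if (scale == "probability") stats::qlogis(pmin(pmax(v, 1e-12), 1 - 1e-12)) else v
  p <- stats::plogis(lp)
  parts <- brier_decomposition(y, p)
  cal <- recalibrate(y, lp)
  data.frame(
    c_stat = concordance(y, lp),
    brier = parts$total,
    brier_calibration = parts$calibration_term,
    brier_refinement = parts$refinement_term,
    slope = cal$slope,
    citl = calibration_in_the_large(y, lp),
    n = length(y)
  )
}
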