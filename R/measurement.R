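#' Measurement error specification
#'
#' Describes how a pragmatic measurement W of a predictor relates to its
#' exact measurement X through the general linear measurement error model
#' \deqn{W = \psi_y + \theta_y X + \varepsilon_y, \quad
#'       \varepsilon_y \sim N(0, \sigma^2_{\varepsilon, y}),}
#' where every parameter may depend on the outcome class y (cases y = 1,
#' noncases y = 0). \eqn{\psi} is an additive shift, \eqn{\theta} the linear
#' association between W and X, and the error variance
#' \eqn{\sigma^2_\varepsilon} the imprecision of the measurement procedure.
#'
#' The two-argument shorthand (`psi`, `theta`, `err_var`) defines a
#' nondifferential specification; class-specific values can be supplied to
#' make the error differential. Note `err_var` is a variance, not a standard
#' deviation.
#'
#' @param psi,theta,err_var Nondifferential shorthand: values used for both
#'   outcome classes unless overridden.
#' @param psi0,psi1 Additive shift for noncases / cases.
#' @param theta0,theta1 Multiplicative association for noncases / cases.
#' @param err_var0,err_var1 Error variance (\eqn{\sigma^2_\varepsilon \ge 0})
#'   for noncases / cases.
#' @return An object of class `measurement_spec`.
#' @seealso [classify_spec()], [apply_measurement()]
#' @export
#' @examples
#' measurement_spec(err_var = 1)                  # random error
#' measurement_spec(psi = 0.25)                   # additive systematic error
#' measurement_spec(err_var0 = 1, err_var1 = 4)   # differential error
measurement_spec <- function(psi = 0, theta = 1, err_var = 0,
                             psi0 = psi, psi1 = psi,
                             theta0 = theta, theta1 = theta,
                             err_var0 = err_var, err_var1 = err_var) {
  vals <- c(psi0 = psi0, psi1 = psi1, theta0 = theta0, theta1 = theta1,
            err_var0 = err_var0, err_var1 = err_var1)
  if (!all(vapply(vals, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE))) {
    stop("all measurement parameters must be finite scalars", call. = FALSE)
  }
  if (err_var0 < 0 || err_var1 < 0) {
    stop("error variances must be non-negative", call. = FALSE)
  }
  structure(as.list(vals), class = "measurement_spec")
}

#' The identity (error-free) measurement
#' @return A `measurement_spec` with \eqn{\psi = 0}, \eqn{\theta = 1},
#'   \eqn{\sigma^2_\varepsilon = 0}, under which W equals X.
#' @export
identity_spec <- function() measurement_spec()

is_differential <- function(spec) {
  spec$psi0 != spec$psi1 || spec$theta0 != spec$theta1 ||
    spec$err_var0 != spec$err_var1
}

#' Classify a measurement specification in the error taxonomy
#'
#' A specification is *differential* if any parameter differs between cases
#' and noncases; otherwise *systematic* if \eqn{\psi \ne 0} or
#' \eqn{\theta \ne 1}; otherwise *random* (classical), which includes the
#' degenerate error-free identity.
#'
#' @param spec A [measurement_spec()].
#' @return One of `"random"`, `"systematic"`, `"differential"`.
#' @export
classify_spec <- function(spec) {
  stopifnot(inherits(spec, "measurement_spec"))
  if (is_differential(spec)) return("differential")
  if (spec$psi0 != 0 || spec$theta0 != 1) return("systematic")
  "random"
}

#' @export
print.measurement_spec <- function(x, ...) {
  type <- classify_spec(x)
  cat("Measurement spec (", type, " error model)\n", sep = "")
  if (type == "differential") {
    cat(sprintf("  noncases: W = %g + %g X + e, Var(e) = %g\n",
                x$psi0, x$theta0, x$err_var0))
    cat(sprintf("  cases:    W = %g + %g X + e, Var(e) = %g\n",
                x$psi1, x$theta1, x$err_var1))
  } else {
    cat(sprintf("  W = %g + %g X + e, Var(e) = %g\n",
                x$psi0, x$theta0, x$err_var0))
  }
  invisible(x)
}

as_spec_list <- function(specs, P) {
  if (inherits(specs, "measurement_spec")) specs <- rep(list(specs), P)
  if (!is.list(specs) || length(specs) != P ||
      !all(vapply(specs, inherits, TRUE, "measurement_spec"))) {
    stop(sprintf("'specs' must be one measurement_spec, or a list of %d", P),
         call. = FALSE)
  }
  specs
}

#' Transform exact into pragmatic measurements
#'
#' Applies the general measurement error model column-wise:
#' \eqn{w_{ij} = \psi_{y_i, j} + \theta_{y_i, j} x_{ij} + \varepsilon_{ij}}
#' with \eqn{\varepsilon_{ij} \sim N(0, \sigma^2_{\varepsilon, y_i, j})}
#' independent across cells. The exact matrix X is not modified.
#'
#' @param X Matrix of exact measurements (or a [draw_cohort()] object, in
#'   which case the returned cohort carries the pragmatic matrix in `W`).
#' @param y Binary outcome vector, one value per row of X.
#' @param specs A single [measurement_spec()] recycled over predictors, or a
#'   list with one spec per column of X.
#' @return A matrix W of the same shape as X (or the cohort with `W` set).
#' @export
#' @examples
#' X <- matrix(rnorm(200), ncol = 1)
#' y <- rbinom(100, 1, 0.5)
#' W <- apply_measurement(X, y, measurement_spec(err_var = 1))
apply_measurement <- function(X, y, specs) {
  if (inherits(X, "cohort")) {
    cohort <- X
    cohort$W <- apply_measurement(cohort$X, cohort$y, specs)
    return(cohort)
  }
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) {
    stop("'y' must have one value per row of X", call. = FALSE)
  }
  if (!all(y %in% c(0L, 1L))) stop("'y' must be binary 0/1", call. = FALSE)
  specs <- as_spec_list(specs, ncol(X))
  W <- X
  case <- y == 1L
  for (j in seq_len(ncol(X))) {
    s <- specs[[j]]
    psi <- ifelse(case, s$psi1, s$psi0)
    theta <- ifelse(case, s$theta1, s$theta0)
    sd_e <- sqrt(ifelse(case, s$err_var1, s$err_var0))
    W[, j] <- psi + theta * X[, j] + stats::rnorm(nrow(X)) * sd_e
  }
  W
}
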