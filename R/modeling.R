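#' Fit an unpenalized logistic regression by maximum likelihood
#'
#' Thin wrapper around [stats::glm.fit()] (iteratively reweighted least
#' squares) that adds an intercept column, flags non-convergence and
#' (quasi-)complete separation, and returns a light-weight object suitable
#' for large simulation loops. No shrinkage or penalization is applied: the
#' simulation design isolates measurement effects from overfitting, so the
#' plain maximum likelihood estimate is the estimand.
#'
#' @param y Binary 0/1 outcome vector containing both classes.
#' @param M Numeric matrix (or vector) of predictor measurements; an
#'   intercept is added internally.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the relative deviance change.
#' @return An object of class `fitted_logistic`: `intercept_hat`,
#'   `coef_hat`, `converged`, `separation`, `n_iterations`, `fitted`
#'   (in-sample probabilities) and `deviance`.
#' @export
#' @examples
#' X <- matrix(rnorm(500), ncol = 1)
#' y <- rbinom(500, 1, plogis(X))
#' fit <- fit_logistic(y, X)
#' c(fit$intercept_hat, fit$coef_hat)
fit_logistic <- function(y, M, max_iter = 100L, tol = 1e-10) {
  y <- as.numeric(y)
  M <- as.matrix(M)
  if (nrow(M) != length(y)) stop("'y' and 'M' sizes differ", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1", call. = FALSE)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (any(apply(M, 2L, stats::sd) == 0)) {
    stop("constant predictor column", call. = FALSE)
  }
  design <- cbind("(Intercept)" = 1, M)
  fit <- withCallingHandlers(
    stats::glm.fit(design, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  # fitted probabilities indistinguishable from 0/1 signal separation:
  # finite ML estimates cannot push a fitted value to the boundary
  sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  structure(
    list(
      intercept_hat = unname(fit$coefficients[1L]),
      coef_hat = unname(fit$coefficients[-1L]),
      converged = isTRUE(fit$converged) && !sep,
      separation = sep,
      n_iterations = fit$iter,
      fitted = fit$fitted.values,
      deviance = fit$deviance
    ),
    class = "fitted_logistic"
  )
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat(sprintf(
    "ML logistic fit: alpha = %.4f, beta = (%s); %sconverged in %d iterations%s\n",
    x$intercept_hat, paste(signif(x$coef_hat, 4), collapse = ", "),
    if (x$converged) "" else "NOT ", x$n_iterations,
    if (x$separation) " [separation detected]" else ""))
  invisible(x)
}

#' Linear predictor of a fitted logistic model on new measurements
#'
#' Computes \eqn{lp_i = \hat\alpha + \hat\beta^T m_i}. Applying the
#' derivation-sample coefficients to validation measurements yields the
#' *transported* linear predictor; refitting the model on the validation
#' measurements instead yields the *re-estimated* linear predictor.
#'
#' @param model A [fit_logistic()] object.
#' @param M Measurement matrix with one column per model coefficient.
#' @return Numeric vector of linear predictors (logit scale).
#' @export
linear_predictor <- function(model, M) {
  stopifnot(inherits(model, "fitted_logistic"))
  M <- as.matrix(M)
  if (ncol(M) != length(model$coef_hat)) {
    stop(sprintf("M has %d columns but the model has %d coefficients",
                 ncol(M), length(model$coef_hat)), call. = FALSE)
  }
  model$intercept_hat + drop(M %*% model$coef_hat)
}

#' Predicted probabilities on new measurements
#' @inheritParams linear_predictor
#' @return Vector of predicted event probabilities.
#' @export
predict_prob <- function(model, M) {
  stats::plogis(linear_predictor(model, M))
}
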