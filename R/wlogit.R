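# Weighted binomial logistic regression by iteratively reweighted least
# squares, as a small classed model with the usual accessor methods, plus
# AICc ranking of candidate fits.

#' Weighted logistic regression (IRLS engine)
#'
#' Maximizes the weighted Bernoulli log-likelihood
#' `sum(w * (y * log(p) + (1 - y) * log(1 - p)))` with `logit(p) = X beta`
#' by iteratively reweighted least squares; convergence when the sup-norm
#' change in coefficients drops below `tol`. Standard errors come from the
#' inverse of the weighted Fisher information. Diverging coefficients
#' (complete separation) raise an explicit error.
#'
#' @param X Model matrix (including the intercept column).
#' @param y Binary response (0/1).
#' @param weights Positive case weights (default 1).
#' @param tol Convergence tolerance on `max(abs(delta beta))`
#'   (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return An object of class `wlogit`.
#' @export
fit_weighted_logistic <- function(X, y, weights = rep(1, length(y)),
                                  tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  w <- as.numeric(weights)
  if (!all(is.finite(X))) stop("non-finite values in X")
  if (!all(y %in% c(0, 1))) stop("response must be 0/1")
  if (any(w <= 0)) stop("weights must be > 0")
  if (length(unique(y)) < 2) stop("degenerate response: y is constant")
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("more parameters than observations")
  beta <- numeric(k)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    W <- w * p * (1 - p)
    z <- W * eta + w * (y - p)
    XtWX <- crossprod(X, X * W)
    beta_new <- tryCatch(solve(XtWX, crossprod(X, z)),
                         error = function(e)
                           stop("singular information matrix"))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (max(abs(beta)) > 30)
      stop("perfect separation: coefficients diverging")
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("IRLS did not converge in ", max_iter, " iterations")
  eta <- drop(X %*% beta)
  p <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  ll <- sum(w * (y * log(p) + (1 - y) * log(1 - p)))
  vcov <- solve(crossprod(X, X * (w * p * (1 - p))))
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, se = sqrt(diag(vcov)), vcov = vcov,
                 loglik = ll, deviance = -2 * ll, fitted = p,
                 n = n, k = k, y = y, weights = w, X = X,
                 iterations = iter, converged = delta < tol),
            class = "wlogit")
}

#' Weighted logistic regression with a formula interface
#'
#' @param formula Model formula for a 0/1 response.
#' @param data Data frame.
#' @param weights Optional numeric vector of case weights.
#' @param ... Passed to [fit_weighted_logistic()].
#' @return A `wlogit` fit.
#' @export
#' @examples
#' d <- data.frame(y = rbinom(50, 1, 0.4), x = rnorm(50))
#' coef(wlogit(y ~ x, d))
wlogit <- function(formula, data, weights = NULL, ...) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  if (is.null(weights)) weights <- rep(1, length(y))
  fit <- fit_weighted_logistic(X, y, weights, ...)
  fit$formula <- formula
  fit
}

#' @export
print.wlogit <- function(x, ...) {
  cat("Weighted logistic regression",
      if (!is.null(x$formula)) paste0("(", deparse(x$formula), ")"), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("logLik %.3f on %d obs (%d parameters)\n",
              x$loglik, x$n, x$k))
  invisible(x)
}

#' @export
summary.wlogit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 deviance = object$deviance, n = object$n, k = object$k,
                 aicc = aicc(object$loglik, object$k, object$n),
                 formula = object$formula, converged = object$converged),
            class = "summary.wlogit")
}

#' @export
print.summary.wlogit <- function(x, ...) {
  cat("Weighted logistic regression",
      if (!is.null(x$formula)) paste0("(", deparse(x$formula), ")"), "\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("logLik %.3f  deviance %.3f  AICc %.3f  n = %d\n",
              x$loglik, x$deviance, x$aicc, x$n))
  invisible(x)
}

#' @export
coef.wlogit <- function(object, ...) object$coefficients

#' @export
vcov.wlogit <- function(object, ...) object$vcov

#' @export
logLik.wlogit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
predict.wlogit <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X
  else if (!is.null(object$formula))
    stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                        newdata)
  else as.matrix(newdata)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' @export
residuals.wlogit <- function(object, ...) {
  p <- object$fitted; y <- object$y
  sign(y - p) * sqrt(pmax(0, -2 * object$weights *
                            (y * log(p) + (1 - y) * log(1 - p))))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 ll + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate model fits by AICc
#'
#' @param fits Named list of `wlogit` fits on identical rows.
#' @return Data frame sorted by AICc with columns `model, k, loglik, AICc,
#'   dAICc, weight, deviance`; Akaike weights
#'   `w_i = exp(-d_i / 2) / sum(exp(-d_j / 2))`.
#' @export
aicc_rank <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1)
    stop("candidate models were fit on different numbers of rows")
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) f$k, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    stringsAsFactors = FALSE)
  tab$AICc <- aicc(tab$loglik, tab$k, ns[1])
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$dAICc / 2) / sum(exp(-tab$dAICc / 2))
  tab$deviance <- -2 * tab$loglik
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  tab
}
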