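# Logistic-regression engine used by the exhaustive model search.
#
# A small dedicated IRLS (Newton) fitter rather than stats::glm, because the
# search needs: warm starts across leave-one-out folds (the dominant cost of
# the exhaustive search), a deterministic ridge fallback under separation,
# and fit-count instrumentation. Agreement with stats::glm on well-behaved
# problems is asserted in the test suite.

.fit_env <- new.env(parent = emptyenv())
.fit_env$count <- 0L

#' Fit-counter instrumentation
#'
#' Counts calls to [fit_logistic()] since the last reset, so tests can
#' assert the exact number of model fits performed by a search (each
#' feature combination costs n leave-one-out fits plus one full-data fit).
#'
#' @return `fit_count()` returns the current count; `reset_fit_count()`
#'   resets it to zero and returns the previous value invisibly.
#' @export
fit_count <- function() .fit_env$count

#' @rdname fit_count
#' @export
reset_fit_count <- function() {
  old <- .fit_env$count
  .fit_env$count <- 0L
  invisible(old)
}

# Core IRLS/Newton loop on the design matrix X (intercept included as first
# column). `penalty` is the L2 weight applied to non-intercept coefficients.
.irls <- function(X, y, penalty = 0, start = NULL, max_iter = 100,
                  tol = 1e-8) {
  p <- ncol(X)
  pen <- c(0, rep(penalty, p - 1L))
  beta <- start %||% c(stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)),
                       rep(0, p - 1L))
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- stats::plogis(eta)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu)) - sum(pen * beta^2) / 2
  converged <- FALSE
  H <- NULL
  for (iter in seq_len(max_iter)) {
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w)
    diag(H) <- diag(H) + pen
    g <- drop(crossprod(X, y - mu)) - pen * beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      return(list(coef = beta, hessian = H, loglik = ll, converged = FALSE,
                  singular = TRUE, n_iter = iter))
    }
    # step-halving keeps the penalized log-likelihood non-decreasing
    for (half in 0:20) {
      beta_new <- beta + step / 2^half
      eta_new <- pmin(pmax(drop(X %*% beta_new), -30), 30)
      mu_new <- stats::plogis(eta_new)
      ll_new <- sum(y * log(mu_new) + (1 - y) * log1p(-mu_new)) -
        sum(pen * beta_new^2) / 2
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    delta <- abs(ll_new - ll)
    beta <- beta_new
    mu <- mu_new
    ll <- ll_new
    if (delta < tol * (abs(ll) + tol)) {
      converged <- TRUE
      break
    }
  }
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X, X * w)
  diag(H) <- diag(H) + pen
  list(coef = beta, hessian = H, loglik = ll, converged = converged,
       singular = FALSE, n_iter = iter, fitted = mu)
}

#' Fit a logistic-regression classifier
#'
#' Maximum-likelihood logistic regression with intercept on raw
#' (unstandardized) feature values, so that coefficients and odds ratios
#' are per original feature unit. On non-convergence or detected
#' separation (any non-intercept |coefficient| above `sep_threshold` or a
#' singular Newton system), the model is refit with a small L2 penalty
#' (`ridge_lambda`) on the non-intercept coefficients and flagged
#' `ridge_fallback`.
#'
#' @param x Numeric matrix, patients x features (no intercept column).
#' @param y Binary 0/1 outcome vector.
#' @param ridge_lambda L2 penalty used by the fallback fit (default 1e-6).
#' @param max_iter,tol IRLS controls: at most `max_iter` Newton steps,
#'   convergence when the relative change in (penalized) log-likelihood
#'   falls below `tol`.
#' @param sep_threshold Coefficient magnitude treated as evidence of
#'   separation (default 15 on the raw scale).
#' @param start Optional warm-start coefficient vector (intercept first).
#' @param allow_single_class Internal use by LOOCV: when `TRUE`, a fold
#'   whose training labels are all one class is fit directly with the ridge
#'   penalty instead of erroring.
#' @return A list of class `logistic_fit`: `coefficients` (intercept
#'   first), `se`, `z`, `p_value` (Wald), `odds_ratio`, `or_ci` (95% Wald
#'   bounds on the odds-ratio scale), `loglik`, `fitted`, `converged`,
#'   `ridge_fallback`, `n_iter`.
#' @export
fit_logistic <- function(x, y, ridge_lambda = 1e-6, max_iter = 100,
                         tol = 1e-8, sep_threshold = 15, start = NULL,
                         allow_single_class = FALSE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  single_class <- length(unique(y)) < 2L
  if (single_class && !allow_single_class) {
    stop("labels contain a single class; cannot fit a classifier",
         call. = FALSE)
  }
  .fit_env$count <- .fit_env$count + 1L
  X <- cbind(`(Intercept)` = 1, x)
  ridge_fallback <- FALSE
  if (single_class) {
    fit <- .irls(X, y, penalty = ridge_lambda, start = start,
                 max_iter = max_iter, tol = tol)
    ridge_fallback <- TRUE
  } else {
    fit <- .irls(X, y, penalty = 0, start = start, max_iter = max_iter,
                 tol = tol)
    if (fit$singular || !fit$converged ||
        (ncol(X) > 1L && max(abs(fit$coef[-1L])) > sep_threshold)) {
      fit <- .irls(X, y, penalty = ridge_lambda, start = NULL,
                   max_iter = max_iter, tol = tol)
      ridge_fallback <- TRUE
    }
  }
  beta <- stats::setNames(fit$coef, colnames(X))
  cov <- tryCatch(solve(fit$hessian), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- colnames(X)
  structure(list(coefficients = beta, se = stats::setNames(se, colnames(X)),
                 z = z, p_value = p, odds_ratio = exp(beta), or_ci = ci,
                 loglik = fit$loglik,
                 fitted = if (is.null(fit$fitted)) NULL else
                   .clamp_prob(fit$fitted),
                 converged = fit$converged, ridge_fallback = ridge_fallback,
                 n_iter = fit$n_iter),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d coefficients, loglik %.3f%s%s\n",
              length(x$coefficients), x$loglik,
              if (x$converged) "" else " (not converged)",
              if (x$ridge_fallback) " [ridge fallback]" else ""))
  print(data.frame(coef = x$coefficients, se = x$se, OR = x$odds_ratio,
                   p = x$p_value))
  invisible(x)
}

.clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

#' Leave-one-out cross-validated outcome probabilities
#'
#' Scores each record with a logistic-regression classifier trained on all
#' other records: n fits for n records. Each fit is warm-started from
#' `start` (typically the full-data coefficients) for speed; warm starts
#' cannot change the result since the fold likelihood has a unique optimum.
#' A training fold left with a single class is fit with the ridge penalty.
#'
#' @inheritParams fit_logistic
#' @param start Optional warm-start coefficients (intercept first),
#'   typically from the full-data fit.
#' @return Named numeric vector of held-out outcome probabilities in
#'   (0, 1), one per row of `x`, named by rownames.
#' @export
loocv_scores <- function(x, y, ridge_lambda = 1e-6, start = NULL,
                         max_iter = 100, tol = 1e-8, sep_threshold = 15) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(n == length(y), all(y %in% c(0, 1)))
  if (n < 3L) stop("leave-one-out requires at least 3 records",
                   call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class; cannot cross-validate",
         call. = FALSE)
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_logistic(x[-i, , drop = FALSE], y[-i],
                   ridge_lambda = ridge_lambda, start = start,
                   max_iter = max_iter, tol = tol,
                   sep_threshold = sep_threshold,
                   allow_single_class = TRUE),
      error = function(e) {
        stop("leave-one-out fold ", i, ": ", conditionMessage(e),
             call. = FALSE)
      })
    eta <- drop(c(1, x[i, ]) %*% fit$coefficients)
    scores[i] <- .clamp_prob(stats::plogis(eta))
  }
  stats::setNames(scores, rownames(x))
}
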