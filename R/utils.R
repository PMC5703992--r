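`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed
#'
#' Deterministically maps a top-level seed plus a sequence of labels (operation
#' name, task id, replicate number, ...) to an integer seed below 2^31, so that
#' independent stochastic operations driven by one user-supplied seed draw from
#' distinct, reproducible streams.
#'
#' @param seed Integer top-level seed.
#' @param ... Further labels (character or numeric) identifying the stream.
#' @return A single integer in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "bootstrap", "mortality")
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h) + 1L
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded operations do not disturb the surrounding stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
#' @examples
#' with_seed(1, rnorm(2))
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Shortest decimal representation that parses back to the identical double:
# try 15 significant digits, fall back to 17 where that loses bits. Keeps
# text round-trips bit-exact without littering files with trailing digits.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  need <- is.finite(x)
  need[need] <- as.numeric(out[need]) != x[need]
  if (any(need)) out[need] <- sprintf("%.17g", x[need])
  out[is.na(x)] <- ""
  out
}

# Multivariate normal draws via Cholesky; avoids pulling in MASS for two lines.
rmvnorm_chol <- function(n, sigma) {
  p <- ncol(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% chol(sigma)
}
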