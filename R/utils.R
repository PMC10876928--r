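# Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed and a stream label
#'
#' A small deterministic integer hash so that each logical stream of the
#' generator (covariates, factor scores, one stream per protein, one per
#' replicate) gets its own reproducible seed. Adding proteins or replicates
#' therefore never perturbs the draws of earlier streams.
#'
#' @param seed master integer seed
#' @param ... labels (character or integer) identifying the stream
#' @return an integer seed in [0, 2^31 - 1)
#' @keywords internal
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(h, b)
    # FNV-style multiply, kept in double precision then reduced mod 2^31 - 1
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k number of successes
#' @param n number of trials
#' @param conf confidence level
#' @return named numeric vector with elements `lo` and `hi`
#' @keywords internal
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

# Truncated-normal draw by rejection; bounds far in the tail so the loop
# almost never iterates more than once.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_protscan <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
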