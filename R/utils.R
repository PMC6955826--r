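#' Canonical resting-state network labels
#'
#' The ten large-scale resting-state networks (RSNs) used throughout the
#' package, in a fixed reference order.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' rsn_labels()
rsn_labels <- function() {
  c("auditory", "cerebellum", "DMN", "ECN-left", "ECN-right",
    "saliency", "sensorimotor", "visual-lateral", "visual-medial",
    "visual-occipital")
}

#' Circularly shift a series
#'
#' Delays `x` by `lag` samples with wrap-around: the output at time `t` is
#' `x[t - lag]`. Negative lags advance the series.
#'
#' @param x Numeric vector.
#' @param lag Integer number of samples.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' circular_shift(1:5, 2)
circular_shift <- function(x, lag) {
  n <- length(x)
  lag <- as.integer(lag) %% n
  if (lag == 0L) return(x)
  x[((seq_len(n) - 1L - lag) %% n) + 1L]
}

# Deterministic 31-bit seed derived from a base seed and integer indices, so
# any subject/edge is independently regenerable.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in seq_along(idx)) {
    h <- (h * 69069 + as.numeric(idx[k]) * 104729 + k * 7919) %% 2147483647
  }
  as.integer(h)
}

# Shannon entropy (nats) of an equal-width histogram with ceiling(sqrt(n))
# bins; the convention used for both spatial and temporal fingerprint
# entropies.
histogram_entropy <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || diff(range(x)) == 0) {
    abort("entropy undefined for constant input", class = "fnconn_degenerate")
  }
  nb <- ceiling(sqrt(n))
  breaks <- seq(min(x), max(x), length.out = nb + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = nb)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# Sample skewness and excess kurtosis (simple moment estimators).
moment_skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

moment_kurtosis <- function(x) {
  m <- mean(x); v <- mean((x - m)^2)
  mean((x - m)^4) / v^2 - 3
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "fnconn_invalid_argument")
  }
  invisible(as.integer(x))
}
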