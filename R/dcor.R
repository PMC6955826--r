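check_series_pair <- function(x, y) {
  if (length(x) != length(y)) {
    abort("series must have equal length", class = "fnconn_invalid_argument")
  }
  if (length(x) < 4L) {
    abort("series must have at least 4 samples",
          class = "fnconn_invalid_argument")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("series must not contain missing values",
          class = "fnconn_invalid_argument")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("distance correlation undefined for constant series",
          class = "fnconn_degenerate")
  }
  invisible(NULL)
}

#' Distance correlation between two series
#'
#' The biased V-statistic estimator of Szekely, Rizzo and Bakirov (2007):
#' pairwise absolute-difference matrices of each series are double-centered
#' (row, column and grand means removed); the squared distance covariance is
#' the mean elementwise product, and the distance correlation is
#' `dCov / sqrt(dVar_x * dVar_y)`. The result lies in `[0, 1]` (negative
#' rounding is clipped to zero) and is zero in the population only under
#' independence, which is what lets it capture nonlinear coupling between
#' RSN time-courses.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`, neither constant.
#' @return A single value in `[0, 1]`.
#' @seealso [lagged_distance_correlation()] for the circular-shift lagged
#'   version used to build FNC matrices.
#' @export
#' @examples
#' x <- rnorm(50)
#' distance_correlation(x, x^2)   # nonlinear dependence is picked up
#' distance_correlation(x, 2 * x + 1)  # exactly 1 under affine relation
distance_correlation <- function(x, y) {
  check_series_pair(x, y)
  dcor_cpp(as.numeric(x), as.numeric(y))
}

#' Distance correlation over all circular rotations
#'
#' `dcor(x, rotate(y, k))` for every rotation `k = 0 .. n-1`, where
#' `rotate(y, k)[t] = y[t + k]` (circular advance). Position `k + 1` of the
#' result therefore corresponds to testing whether `y` follows `x` by `k`
#' samples. Both the lag window maximisation and the rotation surrogate null
#' are read off this single profile.
#'
#' @inheritParams distance_correlation
#' @return Numeric vector of length `n`.
#' @export
dcor_rotation_profile <- function(x, y) {
  check_series_pair(x, y)
  as.numeric(dcor_rotation_profile_cpp(as.numeric(x), as.numeric(y)))
}

# indices (1-based) into a rotation profile for lags -L..L
profile_index <- function(lag, n) ((lag %% n) + n) %% n + 1

# order lags by |lag| then negative first: 0, -1, 1, -2, 2, ...
lag_preference <- function(lags) order(abs(lags), lags)

#' Lag-maximised (circular-shift) distance correlation
#'
#' Evaluates the distance correlation between `x` and circular shifts of `y`
#' for every lag in `-max_lag .. max_lag` and returns the maximum, the lag
#' attaining it, and the full per-lag profile. A positive `best_lag` means
#' `y` follows `x` by that many samples. Ties are broken toward smaller
#' `|lag|`, then toward the negative lag, so results are deterministic.
#'
#' @inheritParams distance_correlation
#' @param max_lag Maximum lag magnitude in samples; must be below `n / 4`.
#' @return A list of class `lagged_dcor` with elements `dcor`, `best_lag`,
#'   `per_lag` (named vector over lags) and `surrogate_p` (`NA` until a
#'   surrogate calibration is attached by [build_fnc()] or computed against
#'   [surrogate_threshold()]).
#' @export
#' @examples
#' x <- as.numeric(scale(sin(seq_len(64) / 3) + rnorm(64, sd = 0.1)))
#' r <- lagged_distance_correlation(x, circular_shift(x, 2), max_lag = 3)
#' r$best_lag  # 2
lagged_distance_correlation <- function(x, y, max_lag = 3) {
  n <- length(x)
  if (max_lag < 0 || max_lag >= n / 4) {
    abort("`max_lag` must be non-negative and below n / 4",
          class = "fnconn_invalid_argument")
  }
  prof <- dcor_rotation_profile(x, y)
  lags <- seq.int(-max_lag, max_lag)
  vals <- prof[profile_index(lags, n)]
  names(vals) <- lags
  ord <- lag_preference(lags)
  best <- ord[which.max(vals[ord])]
  structure(
    list(dcor = unname(vals[best]), best_lag = lags[best], per_lag = vals,
         surrogate_p = NA_real_),
    class = "lagged_dcor"
  )
}

#' @export
print.lagged_dcor <- function(x, ...) {
  cat(sprintf("<lagged_dcor> dcor = %.4f at lag %d%s\n", x$dcor, x$best_lag,
              if (!is.na(x$surrogate_p))
                sprintf(" (surrogate p = %.3f)", x$surrogate_p) else ""))
  invisible(x)
}

#' @describeIn lagged_distance_correlation One row per lag
#'   (`lag`, `dcor`, `is_max`).
#' @param x A `lagged_dcor` object.
#' @param ... Unused.
#' @export
tidy.lagged_dcor <- function(x, ...) {
  lags <- as.integer(names(x$per_lag))
  tibble::tibble(lag = lags, dcor = unname(x$per_lag),
                 is_max = lags == x$best_lag)
}

# Sample admissible surrogate rotations: far enough from alignment that the
# lag window around the rotation never touches the true lag-0 position.
sample_rotations <- function(n, max_lag, n_surrogates) {
  admissible <- seq.int(max_lag + 1L, n - max_lag - 1L)
  sample(admissible, n_surrogates, replace = n_surrogates > length(admissible))
}

# Null statistics for given rotations from a precomputed profile.
rotation_null_stats <- function(prof, rotations, max_lag) {
  n <- length(prof)
  vapply(rotations, function(r) {
    max(prof[profile_index(seq.int(r - max_lag, r + max_lag), n)])
  }, numeric(1))
}

#' Surrogate-based significance threshold for the lagged statistic
#'
#' Builds a null distribution for the lag-maximised distance correlation by
#' recomputing the statistic after random circular rotations of `y`
#' (rotation magnitude at least `max_lag + 1`, so the surrogate window never
#' overlaps true alignment). Circular rotation preserves the autocorrelation
#' of each series while destroying their dependence, which makes the
#' empirical `1 - alpha` quantile a calibrated edge-retention threshold.
#'
#' @inheritParams lagged_distance_correlation
#' @param n_surrogates Number of surrogate rotations (>= 20).
#' @param alpha Nominal significance level in `(0, 1]`.
#' @param seed Integer seed for the rotation draw.
#' @return The empirical `1 - alpha` quantile of the surrogate null.
#' @export
surrogate_threshold <- function(x, y, max_lag = 3, n_surrogates = 100,
                                alpha = 0.05, seed = 1) {
  if (n_surrogates < 20) {
    abort("`n_surrogates` must be at least 20",
          class = "fnconn_invalid_argument")
  }
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1]", class = "fnconn_invalid_argument")
  }
  prof <- dcor_rotation_profile(x, y)
  n <- length(prof)
  null <- withr::with_seed(seed, {
    rotation_null_stats(prof, sample_rotations(n, max_lag, n_surrogates),
                        max_lag)
  })
  unname(quantile(null, 1 - alpha, type = 1))
}
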