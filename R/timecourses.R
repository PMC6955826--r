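#' Set of RSN time-courses for one subject
#'
#' Wraps a numeric matrix (rows = time points, columns = named RSN
#' components) together with the sampling interval (seconds), per-component
#' neuronal flags, and optional provenance (group label, subject id, seed).
#' This is the unit on which a functional network connectivity matrix is
#' computed.
#'
#' @param values Numeric matrix with named columns.
#' @param sampling_interval Sampling interval (repetition time) in seconds.
#' @param neuronal Logical vector, one per column; components flagged
#'   `FALSE` are treated as artifactual and zeroed in the FNC matrix.
#' @param group,subject,seed Optional provenance fields.
#' @return An object of class `timecourse_set`.
#' @export
timecourse_set <- function(values, sampling_interval = 2,
                           neuronal = NULL, group = NA_character_,
                           subject = NA_character_, seed = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    abort("`values` must have unique column labels",
          class = "fnconn_schema_error")
  }
  if (!is.numeric(values) || anyNA(values)) {
    abort("`values` must be numeric with no missing entries",
          class = "fnconn_schema_error")
  }
  if (is.null(neuronal)) neuronal <- rep(TRUE, ncol(values))
  if (length(neuronal) != ncol(values)) {
    abort("`neuronal` must have one flag per component",
          class = "fnconn_invalid_argument")
  }
  if (sampling_interval <= 0) {
    abort("`sampling_interval` must be positive",
          class = "fnconn_invalid_argument")
  }
  structure(
    list(values = values, sampling_interval = sampling_interval,
         neuronal = setNames(as.logical(neuronal), colnames(values)),
         group = group, subject = subject, seed = seed),
    class = "timecourse_set"
  )
}

#' @export
print.timecourse_set <- function(x, ...) {
  cat(sprintf(
    "<timecourse_set> %d time points x %d components (TR = %gs)%s\n",
    nrow(x$values), ncol(x$values), x$sampling_interval,
    if (!is.na(x$group)) paste0(", group ", x$group) else ""))
  invisible(x)
}

#' @describeIn timecourse_set Long tibble (`time`, `rsn`, `value`,
#'   `neuronal`); `time` in seconds.
#' @param x A `timecourse_set`.
#' @param ... Unused.
#' @export
tidy.timecourse_set <- function(x, ...) {
  labs <- colnames(x$values)
  tibble::tibble(
    time = rep((seq_len(nrow(x$values)) - 1) * x$sampling_interval,
               times = length(labs)),
    rsn = rep(labs, each = nrow(x$values)),
    value = as.vector(x$values),
    neuronal = rep(unname(x$neuronal), each = nrow(x$values))
  )
}

# Band-limited Gaussian noise: white noise whose Fourier coefficients
# outside [band[1], band[2]] Hz are zeroed, standardised to zero mean and
# unit variance.  Consumes the current RNG stream.
band_limited_noise <- function(n, sampling_interval, band = c(0.01, 0.1)) {
  w <- rnorm(n)
  f <- fft(w)
  freqs <- seq(0, n - 1) / (n * sampling_interval)
  freqs <- pmin(freqs, 1 / sampling_interval - freqs)  # two-sided
  keep <- freqs >= band[1] & freqs <= band[2]
  f[!keep] <- 0
  x <- Re(fft(f, inverse = TRUE)) / n
  as.numeric(scale(x))
}

apply_edge_nonlinearity <- function(d, tag) {
  out <- switch(tag,
    linear = d,
    quadratic = d^2,
    monotone = d + d^3 / 3,
    abort("unknown nonlinearity tag", class = "fnconn_invalid_argument"))
  as.numeric(scale(out))
}

#' Simulate coupled RSN time-courses
#'
#' Latent-driver model: every edge (i, j) of the coupling graph owns a
#' shared band-limited (0.01--0.1 Hz by default) Gaussian driver. The driver
#' is injected into node i as-is and into node j delayed by the edge lag and
#' transformed by the edge nonlinearity, both scaled by the edge weight.
#' Independent Gaussian noise of standard deviation `noise_sd` is added per
#' node and every column is standardised to zero mean and unit variance.
#' Delays wrap circularly, matching the circular-shift convention of
#' [lagged_distance_correlation()].
#'
#' @param graph A [coupling_graph()].
#' @param n_timepoints Number of samples (>= 32); 297 mirrors a 300-volume
#'   acquisition with three dummy volumes discarded.
#' @param sampling_interval Repetition time in seconds (default 2).
#' @param noise_sd Per-node noise standard deviation (>= 0) relative to the
#'   unit-variance drivers.
#' @param band Driver pass band in Hz.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param group,subject Provenance labels stored on the result.
#' @return A [timecourse_set()] with one column per graph node.
#' @export
#' @examples
#' g <- generate_coupling_graph(10, density = 0.4, seed = 1)
#' tcs <- simulate_timecourses(g, n_timepoints = 297, seed = 2)
simulate_timecourses <- function(graph, n_timepoints = 297,
                                 sampling_interval = 2, noise_sd = 0.5,
                                 band = c(0.01, 0.1), seed = 1,
                                 group = NA_character_,
                                 subject = NA_character_) {
  if (!inherits(graph, "coupling_graph")) {
    abort("`graph` must be a coupling_graph", class = "fnconn_invalid_argument")
  }
  stopifnot_scalar_count(n_timepoints, "n_timepoints", min = 32L)
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative", class = "fnconn_invalid_argument")
  }
  n <- as.integer(n_timepoints)
  p <- length(graph$labels)
  withr::with_seed(seed, {
    X <- matrix(0, n, p, dimnames = list(NULL, graph$labels))
    for (i in seq_len(p - 1L)) {
      for (j in seq.int(i + 1L, p)) {
        w <- graph$weights[i, j]
        if (w <= 0) next
        d <- band_limited_noise(n, sampling_interval, band)
        X[, i] <- X[, i] + w * d
        dj <- circular_shift(d, graph$lags[i, j])
        X[, j] <- X[, j] + w * apply_edge_nonlinearity(dj, graph$nonlinearity[i, j])
      }
    }
    X <- X + matrix(rnorm(n * p, sd = noise_sd), n, p)
    # guard: a node with no edges and noise_sd = 0 would be constant
    const <- apply(X, 2, sd) == 0
    if (any(const)) X[, const] <- matrix(rnorm(n * sum(const)), n)
    X <- scale(X)
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    timecourse_set(X, sampling_interval = sampling_interval,
                   group = group, subject = subject, seed = seed)
  })
}

#' Generate an artifactual component time-course
#'
#' Produces the three signal signatures used to recognise artifactual
#' independent components: `"highfreq"` concentrates spectral power above
#' 0.1 Hz, `"spike"` adds abrupt large excursions (> 5 SD) to a smooth
#' baseline, and `"sawtooth"` is a periodic ramp.
#'
#' @param kind One of `"spike"`, `"sawtooth"`, `"highfreq"`.
#' @param n_timepoints Number of samples (>= 32).
#' @param sampling_interval Repetition time in seconds.
#' @param seed Integer seed.
#' @return Standardised numeric vector of length `n_timepoints`.
#' @export
#' @examples
#' x <- generate_artifact_timecourse("spike", 297, seed = 1)
generate_artifact_timecourse <- function(kind, n_timepoints = 297,
                                         sampling_interval = 2, seed = 1) {
  stopifnot_scalar_count(n_timepoints, "n_timepoints", min = 32L)
  n <- as.integer(n_timepoints)
  nyq <- 1 / (2 * sampling_interval)
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("spike", "sawtooth", "highfreq")) {
    abort("`kind` must be one of spike, sawtooth, highfreq",
          class = "fnconn_invalid_argument")
  }
  withr::with_seed(seed, {
    x <- switch(kind,
      highfreq = {
        # band-pass noise above the neuronal band
        band_limited_noise(n, sampling_interval,
                           band = c(0.11, max(0.12, nyq))) +
          0.2 * rnorm(n)
      },
      spike = {
        base <- band_limited_noise(n, sampling_interval) * 0.5 + 0.3 * rnorm(n)
        k <- max(2L, round(n / 100))
        at <- sample.int(n, k)
        base[at] <- base[at] + sample(c(-1, 1), k, replace = TRUE) *
          runif(k, 7, 10) * sd(base)
        base
      },
      sawtooth = {
        period <- max(12L, round(40 / sampling_interval))  # ~40 s ramp
        ramp <- ((seq_len(n) - 1) %% period) / (period - 1)
        ramp + 0.05 * rnorm(n)
      })
    as.numeric(scale(x))
  })
}
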