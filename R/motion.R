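check_motion_trace <- function(trace) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L || !is.numeric(trace) || anyNA(trace)) {
    abort(paste("a motion trace needs 6 numeric columns:",
                "3 translations (mm) then 3 rotations (rad)"),
          class = "fnconn_invalid_argument")
  }
  if (nrow(trace) < 2L) {
    abort("a motion trace needs at least 2 frames",
          class = "fnconn_invalid_argument")
  }
  trace
}

#' Frame-wise displacement from rigid-body motion parameters
#'
#' Power-style frame-wise displacement: the sum of absolute frame-to-frame
#' changes of the three translations (mm) plus the three rotations
#' converted to arc length on a sphere of `head_radius` mm. The first frame
#' has displacement 0 by convention.
#'
#' @param trace Matrix or data frame with 6 columns: translations x, y, z in
#'   mm, then rotations pitch, roll, yaw in radians; one row per retained
#'   volume.
#' @param head_radius Head radius in mm used for the rotation arc length
#'   (default 50).
#' @return A tibble of class `fwd_series` with columns `frame` and `fwd`
#'   (mm); the mean displacement is attached as attribute `"mean_fwd"`.
#' @seealso [flag_frames()]
#' @export
#' @examples
#' trace <- matrix(0, 10, 6)
#' trace[5, 1] <- 0.1  # a 0.1 mm x-translation step
#' framewise_displacement(trace)
framewise_displacement <- function(trace, head_radius = 50) {
  trace <- check_motion_trace(trace)
  d <- abs(diff(trace))
  fwd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
             head_radius * rowSums(d[, 4:6, drop = FALSE]))
  out <- tibble::tibble(frame = seq_len(nrow(trace)), fwd = fwd)
  class(out) <- c("fwd_series", class(out))
  attr(out, "mean_fwd") <- mean(fwd)
  out
}

#' Flag high-motion frames
#'
#' Marks frames whose frame-wise displacement exceeds `threshold` mm.
#' Flagged frames are reported, not removed; censoring is left to the
#' caller.
#'
#' @param fwd A [framewise_displacement()] result.
#' @param threshold Displacement threshold in mm (default 0.5).
#' @return The input tibble with a logical `flagged` column added.
#' @export
flag_frames <- function(fwd, threshold = 0.5) {
  if (!inherits(fwd, "fwd_series")) {
    abort("`fwd` must come from framewise_displacement()",
          class = "fnconn_invalid_argument")
  }
  dplyr::mutate(fwd, flagged = .data$fwd > threshold)
}

#' Read a 6-parameter realignment motion file
#'
#' Reads whitespace- or tab-delimited motion parameter files in the common
#' realignment dialect: six columns, translations in mm then rotations in
#' radians, one row per volume.
#'
#' @param path File path.
#' @return Numeric matrix with 6 named columns.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("motion file not found: %s", path),
          class = "fnconn_file_not_found")
  }
  m <- as.matrix(read.table(path, header = FALSE))
  m <- check_motion_trace(m)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_pitch", "rot_roll", "rot_yaw")
  m
}

#' Generate a synthetic motion trace
#'
#' Smooth low-amplitude drift plus optional abrupt displacement spikes, for
#' exercising the frame-wise displacement computation.
#'
#' @param n_frames Number of volumes.
#' @param drift_sd Standard deviation of the random-walk increments
#'   (mm for translations; rad for rotations, scaled down 100-fold).
#' @param spike_frames Integer frames (>= 2) at which a sustained
#'   `spike_size` mm translation step occurs.
#' @param spike_size Spike amplitude in mm.
#' @param seed Integer seed.
#' @return Numeric matrix with 6 columns.
#' @export
generate_motion_trace <- function(n_frames = 297, drift_sd = 0.01,
                                  spike_frames = integer(), spike_size = 1,
                                  seed = 1) {
  stopifnot_scalar_count(n_frames, "n_frames", min = 2L)
  withr::with_seed(seed, {
    steps <- cbind(matrix(rnorm(3 * n_frames, sd = drift_sd), ncol = 3),
                   matrix(rnorm(3 * n_frames, sd = drift_sd / 100), ncol = 3))
    steps[1, ] <- 0
    for (f in spike_frames) {
      steps[f, 1] <- steps[f, 1] + spike_size
    }
    trace <- apply(steps, 2, cumsum)
    colnames(trace) <- c("trans_x", "trans_y", "trans_z",
                         "rot_pitch", "rot_roll", "rot_yaw")
    trace
  })
}
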