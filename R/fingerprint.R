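#' @keywords internal
# fraction of suprathreshold voxels (|z| > z_thresh on the standardised
# map) that belong to the largest 6-connected cluster
degree_of_clustering <- function(map, z_thresh = 1.5) {
  d <- dim(map)
  z <- (map - mean(map)) / sd(map)
  supra <- which(abs(z) > z_thresh)
  if (length(supra) == 0L) return(0)
  labels <- integer(length(z))
  labels[supra] <- -1L          # -1 = suprathreshold, unvisited
  strides <- c(1L, d[1], d[1] * d[2])
  coord <- function(idx) {
    idx0 <- idx - 1L
    c(idx0 %% d[1], (idx0 %/% d[1]) %% d[2], idx0 %/% (d[1] * d[2]))
  }
  best <- 0L
  comp <- 0L
  for (s in supra) {
    if (labels[s] != -1L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    size <- 0L
    while (length(queue) > 0L) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      size <- size + 1L
      cv <- coord(v)
      for (ax in 1:3) {
        for (dir in c(-1L, 1L)) {
          if (cv[ax] + dir < 0L || cv[ax] + dir >= d[ax]) next
          nb <- v + dir * strides[ax]
          if (labels[nb] == -1L) {
            labels[nb] <- comp
            queue <- c(queue, nb)
          }
        }
      }
    }
    if (size > best) best <- size
  }
  best / length(supra)
}

# fractions of spectral power in the five canonical bands (Hz), relative to
# the total power below 0.25 Hz, from a smoothed (averaged) periodogram
band_power_fractions <- function(x, sampling_interval) {
  bands <- rbind(c(0, 0.008), c(0.008, 0.02), c(0.02, 0.05),
                 c(0.05, 0.1), c(0.1, 0.25))
  sp <- stats::spec.pgram(stats::ts(x, deltat = sampling_interval),
                          spans = 3, taper = 0, detrend = TRUE,
                          plot = FALSE)
  keep <- sp$freq <= 0.25
  f <- sp$freq[keep]; pw <- sp$spec[keep]
  total <- sum(pw)
  frac <- vapply(seq_len(nrow(bands)), function(b) {
    sum(pw[f > bands[b, 1] & f <= bands[b, 2]]) / total
  }, numeric(1))
  # include any power at exactly 0 Hz in the first band
  frac[1] <- frac[1] + sum(pw[f == 0]) / total
  names(frac) <- sprintf("bp_%g_%g", bands[, 1], bands[, 2])
  frac / sum(frac)
}

#' Fingerprint names and band edges
#'
#' The eleven fingerprint features: four spatial (degree of clustering,
#' skewness, excess kurtosis, spatial entropy) and seven temporal (one-lag
#' autocorrelation, temporal entropy, and the power fractions of five
#' frequency bands: 0--0.008, 0.008--0.02, 0.02--0.05, 0.05--0.1 and
#' 0.1--0.25 Hz).
#'
#' @return Character vector of the 11 feature names.
#' @export
fingerprint_features <- function() {
  c("degree_of_clustering", "skewness", "kurtosis", "spatial_entropy",
    "one_lag_autocorrelation", "temporal_entropy",
    "bp_0_0.008", "bp_0.008_0.02", "bp_0.02_0.05", "bp_0.05_0.1",
    "bp_0.1_0.25")
}

#' Spatio-temporal fingerprint of an independent component
#'
#' Computes the 11-element feature vector used to label components as
#' neuronal or artifactual: spatial features from the component map
#' (fraction of suprathreshold voxels in the largest 6-connected cluster,
#' skewness, excess kurtosis, histogram entropy in nats) and temporal
#' features from the associated time-course (one-lag autocorrelation,
#' histogram entropy, and the five band-power fractions, which are
#' non-negative and sum to one).
#'
#' @param time_course Numeric vector with at least 32 samples, not
#'   constant.
#' @param spatial_map Numeric array (any dimension count), not constant.
#' @param sampling_interval Sampling interval in seconds.
#' @return A one-row tibble with the columns of [fingerprint_features()].
#' @export
#' @examples
#' tmpl <- rsn_templates()
#' x <- generate_artifact_timecourse("sawtooth", 297, seed = 1)
#' compute_fingerprint(x, tmpl$masks[[1]] * 1 + 0.01, sampling_interval = 2)
compute_fingerprint <- function(time_course, spatial_map,
                                sampling_interval = 2) {
  if (length(time_course) < 32L) {
    abort("`time_course` needs at least 32 samples",
          class = "fnconn_invalid_argument")
  }
  if (sd(time_course) == 0) {
    abort("fingerprint undefined for a constant time-course",
          class = "fnconn_degenerate")
  }
  map <- as.numeric(spatial_map)
  if (sd(map) == 0) {
    abort("fingerprint undefined for a constant spatial map",
          class = "fnconn_degenerate")
  }
  if (is.null(dim(spatial_map))) {
    spatial_map <- array(map, dim = c(length(map), 1, 1))
  }
  if (length(dim(spatial_map)) == 2L) {
    spatial_map <- array(spatial_map, dim = c(dim(spatial_map), 1))
  }
  ac <- acf(time_course, lag.max = 1, plot = FALSE)$acf[2]
  bp <- band_power_fractions(time_course, sampling_interval)
  out <- tibble::tibble(
    degree_of_clustering = degree_of_clustering(spatial_map),
    skewness = moment_skewness(map),
    kurtosis = moment_kurtosis(map),
    spatial_entropy = histogram_entropy(map),
    one_lag_autocorrelation = ac,
    temporal_entropy = histogram_entropy(time_course)
  )
  for (k in seq_along(bp)) out[[fingerprint_features()[6 + k]]] <- bp[[k]]
  out
}

#' Train a neuronal-vs-artifactual component classifier
#'
#' Fits a maximum-margin linear classifier (linear-kernel support vector
#' machine with standardised features) on labelled fingerprints. The
#' original reference classifier was trained on fingerprints from
#' independently assessed healthy subjects; here any labelled fingerprint
#' table, typically synthetic, can serve as training data.
#'
#' @param fingerprints Data frame whose columns include
#'   [fingerprint_features()], one row per component.
#' @param labels Factor or character vector with values `"neuronal"` /
#'   `"artifactual"`; both classes must be present.
#' @return An object of class `neuronal_classifier`.
#' @export
train_neuronal_classifier <- function(fingerprints, labels) {
  feats <- fingerprint_features()
  if (!all(feats %in% names(fingerprints))) {
    abort("`fingerprints` must contain all 11 fingerprint features",
          class = "fnconn_invalid_argument")
  }
  y <- factor(as.character(labels), levels = c("artifactual", "neuronal"))
  if (anyNA(y) || length(unique(y)) < 2L) {
    abort("training data must contain both classes",
          class = "fnconn_invalid_argument")
  }
  X <- as.matrix(fingerprints[, feats])
  # drop constant columns from scaling to keep svm() happy
  scale_ok <- apply(X, 2, sd) > 0
  fit <- e1071::svm(X, y, kernel = "linear", scale = scale_ok,
                    cost = 1, probability = FALSE)
  structure(list(fit = fit, features = feats),
            class = "neuronal_classifier")
}

#' @export
print.neuronal_classifier <- function(x, ...) {
  cat("<neuronal_classifier> linear SVM on 11 fingerprint features\n")
  invisible(x)
}

#' Classify components as neuronal or artifactual
#'
#' @param fingerprints Data frame of fingerprints (one row per component).
#' @param model A [train_neuronal_classifier()] fit.
#' @return A tibble with columns `label` and `margin` (signed distance to
#'   the decision boundary; positive means neuronal).
#' @export
classify_neuronal <- function(fingerprints, model) {
  if (!inherits(model, "neuronal_classifier")) {
    abort("`model` must be a neuronal_classifier",
          class = "fnconn_invalid_argument")
  }
  X <- as.matrix(fingerprints[, model$features])
  pred <- stats::predict(model$fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1]
  # orient the margin so that positive = neuronal
  sign_flip <- if (grepl("^neuronal", colnames(attr(pred, "decision.values"))[1])) 1 else -1
  tibble::tibble(label = as.character(pred), margin = sign_flip * dv)
}
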