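#' Template masks for the ten canonical RSNs
#'
#' Builds a `template_set`: ten named binary masks on a common toy voxel
#' grid, each an ellipsoidal blob at a distinct location. These play the
#' role of canonical RSN spatial templates in the template-matching stage;
#' they are synthetic stand-ins on a small grid, not anatomical atlases.
#'
#' @param dim Grid dimensions (default `c(32, 32, 16)`).
#' @param radius Blob radius in voxels.
#' @return An object of class `template_set`: named list of logical arrays.
#' @export
rsn_templates <- function(dim = c(32, 32, 16), radius = 3) {
  labels <- rsn_labels()
  # fixed, well-separated centres on a 2 x 5 lattice, alternating in z
  gx <- round(seq(0.18, 0.82, length.out = 5) * dim[1])
  gy <- round(c(0.3, 0.7) * dim[2])
  gz <- round(c(0.35, 0.65) * dim[3])
  centers <- cbind(
    rep(gx, times = 2),
    rep(gy, each = 5),
    gz[rep(c(1, 2), length.out = 10)]
  )
  masks <- lapply(seq_len(10), function(k) {
    blob_mask(dim, centers[k, ], radius)
  })
  names(masks) <- labels
  structure(list(masks = masks, dim = dim, centers = centers,
                 radius = radius),
            class = "template_set")
}

blob_mask <- function(dim, center, radius) {
  coords <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                        z = seq_len(dim[3]))
  d2 <- (coords$x - center[1])^2 + (coords$y - center[2])^2 +
    (coords$z - center[3])^2
  array(d2 <= radius^2, dim = dim)
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d templates on a %s grid\n",
              length(x$masks), paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Set of spatial component maps
#'
#' Container for independent-component spatial maps sharing one voxel grid,
#' with z-like unitless amplitudes.
#'
#' @param maps Named list of numeric arrays with identical dimensions.
#' @return An object of class `spatial_component_set`.
#' @export
spatial_component_set <- function(maps) {
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1L) {
    abort("all component maps must share one grid",
          class = "fnconn_invalid_argument")
  }
  if (is.null(names(maps)) || anyDuplicated(names(maps))) {
    names(maps) <- sprintf("IC%02d", seq_along(maps))
  }
  structure(list(maps = maps, dim = dims[[1]]),
            class = "spatial_component_set")
}

#' @export
print.spatial_component_set <- function(x, ...) {
  cat(sprintf("<spatial_component_set> %d components on a %s grid\n",
              length(x$maps), paste(x$dim, collapse = "x")))
  invisible(x)
}

# integer-shift an array, zero-filling at the borders
shift_array <- function(a, shift) {
  out <- array(0, dim = dim(a))
  d <- dim(a)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) {
      src[[k]] <- seq_len(d[k] - s); dst[[k]] <- seq.int(s + 1L, d[k])
    } else {
      src[[k]] <- seq.int(-s + 1L, d[k]); dst[[k]] <- seq_len(d[k] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate synthetic spatial components
#'
#' Produces one noisy, spatially jittered copy of each template (amplitude
#' 1 inside the displaced mask) plus `n_extra` unrelated blob components,
#' emulating an ICA decomposition in which the ten RSNs hide among other
#' components. With the default `n_extra = 20` the set has 30 components,
#' the usual decomposition order. Distractor blobs are placed away from
#' every template centre (at least two radii plus the jitter), mirroring
#' the fact that non-RSN components occupy other anatomy than the
#' templates; without that exclusion a distractor could sit exactly on a
#' template and be its legitimate best match.
#'
#' @param templates A [rsn_templates()] set.
#' @param jitter Maximum absolute voxel shift applied independently per
#'   axis; must be smaller than every grid dimension.
#' @param noise_sd Standard deviation of added Gaussian voxel noise.
#' @param n_extra Number of unrelated distractor components.
#' @param seed Integer seed.
#' @return A list with `components` (a [spatial_component_set()]), and
#'   `truth`, the component id carrying each template.
#' @export
generate_spatial_components <- function(templates, jitter = 1,
                                        noise_sd = 0.1, n_extra = 20,
                                        seed = 1) {
  if (!inherits(templates, "template_set")) {
    abort("`templates` must be a template_set",
          class = "fnconn_invalid_argument")
  }
  if (any(jitter >= templates$dim)) {
    abort("`jitter` must be smaller than the grid",
          class = "fnconn_invalid_argument")
  }
  withr::with_seed(seed, {
    n_total <- length(templates$masks) + n_extra
    order_ids <- sample.int(n_total)
    maps <- vector("list", n_total)
    truth <- setNames(character(length(templates$masks)),
                      names(templates$masks))
    for (k in seq_along(templates$masks)) {
      sh <- if (jitter > 0) sample.int(2 * jitter + 1, 3, replace = TRUE) -
        jitter - 1 else c(0L, 0L, 0L)
      m <- shift_array(templates$masks[[k]] * 1, sh)
      if (noise_sd > 0) m <- m + array(rnorm(prod(templates$dim),
                                             sd = noise_sd), templates$dim)
      id <- sprintf("IC%02d", order_ids[k])
      maps[[order_ids[k]]] <- m
      truth[k] <- id
    }
    min_d2 <- (2 * templates$radius + jitter)^2
    for (k in seq_len(n_extra)) {
      repeat {
        center <- c(sample.int(templates$dim[1], 1),
                    sample.int(templates$dim[2], 1),
                    sample.int(templates$dim[3], 1))
        d2 <- colSums((t(templates$centers) - center)^2)
        if (all(d2 > min_d2)) break
      }
      m <- blob_mask(templates$dim, center, templates$radius) *
        runif(1, 0.5, 1.5)
      m <- m + array(rnorm(prod(templates$dim), sd = max(noise_sd, 0.05)),
                     templates$dim)
      maps[[order_ids[length(templates$masks) + k]]] <- m
    }
    names(maps) <- sprintf("IC%02d", seq_len(n_total))
    list(components = spatial_component_set(maps), truth = truth)
  })
}

#' Write / read component maps as NIfTI volumes
#'
#' Thin wrappers over the RNifti reader/writer for exchanging spatial
#' component maps and template masks with neuroimaging tools.
#'
#' @param x A [spatial_component_set()] or [rsn_templates()] object.
#' @param dir Output directory (created if absent).
#' @return `write_components_nifti()` returns the written paths invisibly;
#'   `read_components_nifti()` returns a [spatial_component_set()].
#' @export
write_components_nifti <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maps <- if (inherits(x, "template_set")) {
    lapply(x$masks, function(m) m * 1)
  } else if (inherits(x, "spatial_component_set")) {
    x$maps
  } else {
    abort("`x` must be a spatial_component_set or template_set",
          class = "fnconn_invalid_argument")
  }
  paths <- file.path(dir, paste0(make.names(names(maps)), ".nii.gz"))
  for (k in seq_along(maps)) {
    RNifti::writeNifti(RNifti::asNifti(maps[[k]]), paths[k])
  }
  invisible(paths)
}

#' @rdname write_components_nifti
#' @param paths NIfTI file paths to read.
#' @export
read_components_nifti <- function(paths) {
  maps <- lapply(paths, function(p) {
    a <- RNifti::readNifti(p)
    array(as.numeric(a), dim = dim(a))
  })
  names(maps) <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  spatial_component_set(maps)
}
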