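#' Tidy an FNC matrix into a long edge table
#'
#' @param x An [build_fnc()] result.
#' @param upper_only Keep each undirected pair once (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with columns `rsn_i`, `rsn_j`, `dcor`, `lag`, `retained`,
#'   `p`.
#' @export
tidy.fnc_matrix <- function(x, upper_only = TRUE, ...) {
  p <- length(x$labels)
  idx <- if (upper_only) which(upper.tri(x$weights), arr.ind = TRUE) else
    which(row(x$weights) != col(x$weights), arr.ind = TRUE)
  tibble::tibble(
    rsn_i = x$labels[idx[, 1]],
    rsn_j = x$labels[idx[, 2]],
    dcor = x$weights[idx],
    lag = x$lags[idx],
    retained = x$retained[idx],
    p = x$p[idx]
  )
}

#' Glance at an FNC matrix
#'
#' @param x An [build_fnc()] result.
#' @param ... Unused.
#' @return One-row tibble: node counts, retained edge count, mean retained
#'   weight, network averages of degree and strength.
#' @export
glance.fnc_matrix <- function(x, ...) {
  ut <- upper.tri(x$weights)
  retained <- x$retained[ut]
  tibble::tibble(
    n_nodes = length(x$labels),
    n_neuronal = sum(x$neuronal),
    n_retained = sum(retained),
    mean_retained_dcor = if (any(retained))
      mean(x$weights[ut][retained]) else NA_real_,
    avg_degree = mean(fnc_degree(x)),
    avg_strength = mean(fnc_strength(x))
  )
}
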