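#' Coupling graph between resting-state networks
#'
#' A `coupling_graph` is the generative ground truth behind a synthetic
#' cohort: a symmetric non-negative weight matrix over named RSNs, an
#' antisymmetric integer lag matrix (in samples), and a per-edge nonlinearity
#' tag (`"linear"`, `"quadratic"` or `"monotone"`) describing how the shared
#' latent driver is transformed before injection into the lagged node.
#'
#' @param weights Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @param lags Antisymmetric integer matrix (samples); `lags[i, j] = l` means
#'   node `j` receives the shared driver of edge (i, j) delayed by `l`
#'   samples relative to node `i`.
#' @param nonlinearity Character matrix (or single string, recycled) of
#'   per-edge tags in `c("linear", "quadratic", "monotone")`.
#' @param labels Node names; defaults to [rsn_labels()] when there are 10
#'   nodes.
#' @return An object of class `coupling_graph`.
#' @seealso [generate_coupling_graph()], [simulate_timecourses()]
#' @export
coupling_graph <- function(weights, lags = NULL, nonlinearity = "linear",
                           labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 2L || ncol(weights) != n) {
    abort("`weights` must be a square matrix with at least 2 nodes",
          class = "fnconn_invalid_argument")
  }
  if (max(abs(weights - t(weights))) > 1e-12) {
    abort("`weights` must be symmetric", class = "fnconn_invalid_argument")
  }
  if (any(diag(weights) != 0)) {
    abort("`weights` must have a zero diagonal",
          class = "fnconn_invalid_argument")
  }
  if (any(weights < 0)) {
    abort("`weights` must be non-negative", class = "fnconn_invalid_argument")
  }
  if (is.null(lags)) lags <- matrix(0L, n, n)
  lags <- matrix(as.integer(lags), n, n)
  if (max(abs(lags + t(lags))) != 0L) {
    abort("`lags` must be antisymmetric", class = "fnconn_invalid_argument")
  }
  if (length(nonlinearity) == 1L) {
    nonlinearity <- matrix(nonlinearity, n, n)
  }
  nonlinearity <- matrix(as.character(nonlinearity), n, n)
  if (!all(nonlinearity %in% c("linear", "quadratic", "monotone"))) {
    abort("nonlinearity tags must be linear, quadratic or monotone",
          class = "fnconn_invalid_argument")
  }
  if (is.null(labels)) {
    labels <- if (n == 10L) rsn_labels() else paste0("node", seq_len(n))
  }
  if (anyDuplicated(labels) || length(labels) != n) {
    abort("`labels` must be unique and match the number of nodes",
          class = "fnconn_invalid_argument")
  }
  dimnames(weights) <- dimnames(lags) <- dimnames(nonlinearity) <-
    list(labels, labels)
  structure(
    list(labels = labels, weights = weights, lags = lags,
         nonlinearity = nonlinearity),
    class = "coupling_graph"
  )
}

#' Generate a random coupling graph
#'
#' Draws an Erdos--Renyi-style graph over `n_nodes` RSNs: each of the
#' `n_nodes * (n_nodes - 1) / 2` undirected pairs becomes an edge with
#' probability `density`, with weight uniform in `weight_range` and a
#' structural lag uniform on `-max_lag..max_lag` samples.
#'
#' @param n_nodes Number of nodes (>= 2); 10 for the canonical RSN set.
#' @param density Edge probability in `(0, 1]`.
#' @param weight_range Length-2 interval within `(0, 1]`.
#' @param max_lag Maximum structural lag magnitude, in samples.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param nonlinearity Either a single tag applied to every edge or a named
#'   probability vector over `c(linear, quadratic, monotone)` from which
#'   per-edge tags are drawn.
#' @return A [coupling_graph()].
#' @export
#' @examples
#' g <- generate_coupling_graph(10, density = 0.4, seed = 1)
#' sum(g$weights > 0) / 2  # realised edge count
generate_coupling_graph <- function(n_nodes = 10, density = 0.4,
                                    weight_range = c(0.3, 0.8), max_lag = 3,
                                    seed = 1, nonlinearity = "linear") {
  stopifnot_scalar_count(n_nodes, "n_nodes", min = 2L)
  if (density <= 0 || density > 1) {
    abort("`density` must lie in (0, 1]", class = "fnconn_invalid_argument")
  }
  if (length(weight_range) != 2L || weight_range[1] > weight_range[2] ||
      weight_range[1] <= 0 || weight_range[2] > 1) {
    abort("`weight_range` must be an interval within (0, 1]",
          class = "fnconn_invalid_argument")
  }
  n <- as.integer(n_nodes)
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    L <- matrix(0L, n, n)
    NL <- matrix("linear", n, n)
    tags <- c("linear", "quadratic", "monotone")
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (runif(1) <= density) {
          W[i, j] <- W[j, i] <- runif(1, weight_range[1], weight_range[2])
          l <- if (max_lag > 0) sample.int(2L * max_lag + 1L, 1L) - max_lag - 1L else 0L
          L[i, j] <- l; L[j, i] <- -l
          tag <- if (length(nonlinearity) == 1L && is.null(names(nonlinearity))) {
            nonlinearity
          } else {
            p <- setNames(rep(0, 3), tags)
            p[names(nonlinearity)] <- nonlinearity
            sample(tags, 1L, prob = p)
          }
          NL[i, j] <- NL[j, i] <- tag
        }
      }
    }
    coupling_graph(W, L, NL)
  })
}

#' @export
print.coupling_graph <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<coupling_graph> %d nodes, %d edges\n",
              length(x$labels), n_edges))
  invisible(x)
}

#' @describeIn coupling_graph Edge list as a tibble
#'   (`from`, `to`, `weight`, `lag`, `nonlinearity`).
#' @param x A `coupling_graph`.
#' @param ... Unused.
#' @export
tidy.coupling_graph <- function(x, ...) {
  n <- length(x$labels)
  ut <- which(upper.tri(x$weights) & x$weights > 0, arr.ind = TRUE)
  tibble::tibble(
    from = x$labels[ut[, 1]],
    to = x$labels[ut[, 2]],
    weight = x$weights[ut],
    lag = x$lags[ut],
    nonlinearity = x$nonlinearity[ut]
  )
}
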