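#' Edge-retention rules for FNC matrices
#'
#' The distance correlation is almost surely positive in finite samples, so
#' "connected" must be operationalised by a retention rule. Two rules are
#' provided: `edge_rule_surrogate()` keeps an edge when its lag-maximised
#' statistic exceeds the per-pair circular-rotation surrogate quantile (see
#' [surrogate_threshold()]); `edge_rule_fixed()` keeps edges above a fixed
#' cut-off.
#'
#' @param alpha Nominal level of the surrogate test.
#' @param n_surrogates Surrogate rotations per pair (>= 20).
#' @param seed Integer seed for the surrogate draws (per-pair seeds are
#'   derived from it deterministically).
#' @return An object of class `fnc_edge_rule`.
#' @export
edge_rule_surrogate <- function(alpha = 0.05, n_surrogates = 100, seed = 1) {
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1]", class = "fnconn_invalid_argument")
  }
  structure(list(type = "surrogate", alpha = alpha,
                 n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed)),
            class = "fnc_edge_rule")
}

#' @rdname edge_rule_surrogate
#' @param threshold Fixed retention cut-off on the lag-maximised distance
#'   correlation.
#' @export
edge_rule_fixed <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L) {
    abort("`threshold` must be a single number",
          class = "fnconn_invalid_argument")
  }
  structure(list(type = "fixed", threshold = threshold),
            class = "fnc_edge_rule")
}

#' Build the functional network connectivity matrix of one subject
#'
#' For every pair of neuronal components, the entry `c_ij` is the
#' lag-maximised circular-shift distance correlation between the two
#' time-courses; rows and columns of components flagged non-neuronal are set
#' to zero (no interaction) and never retained. The retention mask is
#' decided by the edge rule. One rotation profile per pair feeds both the
#' lag maximisation and the surrogate null, so the rule adds essentially no
#' cost.
#'
#' @param tcs A [timecourse_set()].
#' @param max_lag Lag window half-width in samples (default 3, i.e. 6 s at a
#'   2 s repetition time).
#' @param edge_rule An [edge_rule_surrogate()] or [edge_rule_fixed()].
#' @return An object of class `fnc_matrix` with fields `labels`, `weights`
#'   (symmetric, zero diagonal), `lags` (best lag per pair), `retained`
#'   (logical mask), `p` (surrogate exceedance probabilities, `NA` under a
#'   fixed rule), `neuronal`, and the provenance fields of `tcs`.
#' @export
#' @examples
#' g <- generate_coupling_graph(10, density = 0.4, seed = 1)
#' tcs <- simulate_timecourses(g, seed = 2)
#' fnc <- build_fnc(tcs, edge_rule = edge_rule_surrogate(seed = 3))
#' fnc_degree(fnc)
build_fnc <- function(tcs, max_lag = 3,
                      edge_rule = edge_rule_surrogate()) {
  if (!inherits(tcs, "timecourse_set")) {
    abort("`tcs` must be a timecourse_set", class = "fnconn_invalid_argument")
  }
  if (!inherits(edge_rule, "fnc_edge_rule")) {
    abort("`edge_rule` must be an fnc_edge_rule",
          class = "fnconn_invalid_argument")
  }
  X <- tcs$values
  labels <- colnames(X)
  p <- ncol(X)
  n <- nrow(X)
  neuronal <- tcs$neuronal
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  L <- matrix(0L, p, p, dimnames = list(labels, labels))
  R <- matrix(FALSE, p, p, dimnames = list(labels, labels))
  P <- matrix(NA_real_, p, p, dimnames = list(labels, labels))
  lags <- seq.int(-max_lag, max_lag)
  ord <- lag_preference(lags)
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      if (!neuronal[i] || !neuronal[j]) next
      prof <- dcor_rotation_profile(X[, i], X[, j])
      vals <- prof[profile_index(lags, n)]
      best <- ord[which.max(vals[ord])]
      obs <- vals[best]
      W[i, j] <- W[j, i] <- obs
      L[i, j] <- best_lag <- lags[best]
      L[j, i] <- -best_lag
      if (edge_rule$type == "surrogate") {
        null <- withr::with_seed(derive_seed(edge_rule$seed, i, j), {
          rotation_null_stats(
            prof, sample_rotations(n, max_lag, edge_rule$n_surrogates),
            max_lag)
        })
        P[i, j] <- P[j, i] <- mean(null >= obs)
        thr <- unname(quantile(null, 1 - edge_rule$alpha, type = 1))
        R[i, j] <- R[j, i] <- obs > thr
      } else {
        R[i, j] <- R[j, i] <- obs > edge_rule$threshold
      }
    }
  }
  structure(
    list(labels = labels, weights = W, lags = L, retained = R, p = P,
         neuronal = neuronal, max_lag = max_lag, edge_rule = edge_rule,
         group = tcs$group, subject = tcs$subject),
    class = "fnc_matrix"
  )
}

#' @export
print.fnc_matrix <- function(x, ...) {
  cat(sprintf("<fnc_matrix> %d nodes (%d neuronal), %d retained edges\n",
              length(x$labels), sum(x$neuronal),
              sum(x$retained[upper.tri(x$retained)])))
  invisible(x)
}

check_fnc <- function(fnc) {
  if (!inherits(fnc, "fnc_matrix")) {
    abort("expected an fnc_matrix", class = "fnconn_invalid_argument")
  }
  invisible(fnc)
}

#' Nodal degree of an FNC matrix
#'
#' The number of retained edges incident to each RSN, an integration
#' measure: how many other networks a node keeps a detectable interaction
#' with.
#'
#' @param fnc An [build_fnc()] result.
#' @return Named integer vector over the 10 RSNs.
#' @export
fnc_degree <- function(fnc) {
  check_fnc(fnc)
  colSums(fnc$retained)
}

#' Nodal strength of an FNC matrix
#'
#' The sum of retained edge weights at each node; integration weighted by
#' the robustness of each interaction.
#'
#' @inheritParams fnc_degree
#' @return Named numeric vector.
#' @export
fnc_strength <- function(fnc) {
  check_fnc(fnc)
  colSums(fnc$weights * fnc$retained)
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Segregation measure: for node i with retained degree `k_i >= 2`,
#' `C_i = sum_{j != h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))` over
#' retained edges, with raw weights (already bounded by 1 as distance
#' correlations). Nodes with degree below 2 score 0.
#'
#' @inheritParams fnc_degree
#' @return Named numeric vector in `[0, 1]`.
#' @export
fnc_clustering <- function(fnc) {
  check_fnc(fnc)
  W <- (fnc$weights * fnc$retained)^(1 / 3)
  k <- colSums(fnc$retained)
  tri <- diag(W %*% W %*% W)
  out <- ifelse(k >= 2, tri / (k * pmax(k - 1, 1)), 0)
  setNames(out, fnc$labels)
}

# All-pairs shortest paths with geodesic counting (Floyd-Warshall on edge
# lengths 1/w).  Returns list(dist, sigma); unreachable pairs have Inf
# distance and zero count.  Tolerance guards float ties.
shortest_path_counts <- function(len, tol = 1e-12) {
  n <- nrow(len)
  d <- len
  sigma <- ifelse(is.finite(len) & len > 0, 1, 0)
  diag(d) <- 0
  diag(sigma) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == k || !is.finite(d[i, k])) next
      alt <- d[i, k] + d[k, ]
      shorter <- alt < d[i, ] - tol
      equal <- !shorter & is.finite(alt) & abs(alt - d[i, ]) <= tol *
        pmax(1, abs(alt))
      shorter[c(i, k)] <- FALSE
      equal[c(i, k)] <- FALSE
      d[i, shorter] <- alt[shorter]
      sigma[i, shorter] <- sigma[i, k] * sigma[k, shorter]
      sigma[i, equal] <- sigma[i, equal] + sigma[i, k] * sigma[k, equal]
    }
  }
  list(dist = d, sigma = sigma)
}

#' Betweenness centrality of an FNC matrix
#'
#' Shortest paths are computed on edge lengths `1 / w` over retained edges
#' (stronger coupling = shorter functional distance). A node's betweenness
#' is the number of source--target geodesics passing through it, with
#' fractional credit when geodesics tie, normalised by
#' `(n - 1)(n - 2) / 2` where `n` is the number of neuronal nodes, so values
#' lie in `[0, 1]`. Non-neuronal and isolated nodes score 0.
#'
#' @inheritParams fnc_degree
#' @return Named numeric vector in `[0, 1]`.
#' @export
fnc_betweenness <- function(fnc) {
  check_fnc(fnc)
  p <- length(fnc$labels)
  W <- fnc$weights * fnc$retained
  len <- ifelse(W > 0, 1 / W, Inf)
  diag(len) <- 0
  sp <- shortest_path_counts(len)
  bc <- numeric(p)
  tol <- 1e-12
  for (v in seq_len(p)) {
    for (s in seq_len(p - 1L)) {
      if (s == v) next
      for (t in seq.int(s + 1L, p)) {
        if (t == v || sp$sigma[s, t] == 0) next
        through <- sp$dist[s, v] + sp$dist[v, t]
        if (is.finite(through) &&
            abs(through - sp$dist[s, t]) <= tol * max(1, through)) {
          bc[v] <- bc[v] + sp$sigma[s, v] * sp$sigma[v, t] / sp$sigma[s, t]
        }
      }
    }
  }
  n_neuronal <- sum(fnc$neuronal)
  denom <- (n_neuronal - 1) * (n_neuronal - 2) / 2
  out <- if (denom > 0) bc / denom else bc * 0
  setNames(out, fnc$labels)
}

#' Eigenvector centrality of an FNC matrix
#'
#' The leading eigenvector of the retained weighted adjacency restricted to
#' neuronal nodes, oriented non-negative and scaled to unit Euclidean norm.
#' Computed by power iteration on `A + I` (the shift makes the dominant
#' eigenvalue strictly separated even for bipartite components) to a
#' relative tolerance of 1e-10. An entirely empty network yields all-zero
#' centralities with a warning.
#'
#' @inheritParams fnc_degree
#' @return Named numeric vector; unit Euclidean norm over neuronal nodes
#'   unless the retained network is empty.
#' @export
fnc_eigencentrality <- function(fnc) {
  check_fnc(fnc)
  p <- length(fnc$labels)
  out <- setNames(numeric(p), fnc$labels)
  idx <- which(fnc$neuronal)
  A <- (fnc$weights * fnc$retained)[idx, idx, drop = FALSE]
  if (length(idx) == 0L || max(A) == 0) {
    warn("retained network is empty; eigenvector centrality is all zero")
    return(out)
  }
  m <- nrow(A)
  v <- rep(1 / sqrt(m), m)
  for (iter in seq_len(100000L)) {
    v_new <- A %*% v + v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) <= 1e-10 * max(abs(v_new))) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- as.numeric(v)
  if (v[which.max(abs(v))] < 0) v <- -v
  v[abs(v) < 1e-14] <- 0
  out[idx] <- v
  out
}

#' Nodal network measures of an FNC matrix
#'
#' Computes the five per-RSN measures (degree, strength, clustering
#' coefficient, betweenness and eigenvector centrality) characterising
#' integration, segregation and centrality of the functional network.
#'
#' @inheritParams fnc_degree
#' @return A tibble with one row per RSN and columns `rsn`, `degree`,
#'   `strength`, `clustering`, `betweenness`, `eigencentrality`, plus
#'   `subject` and `group` provenance columns when present.
#' @seealso [network_summary()] for the network averages,
#'   [cohort_metrics()] for whole-cohort tables.
#' @export
nodal_metrics <- function(fnc) {
  check_fnc(fnc)
  tibble::tibble(
    subject = fnc$subject,
    group = fnc$group,
    rsn = fnc$labels,
    degree = as.numeric(fnc_degree(fnc)),
    strength = as.numeric(fnc_strength(fnc)),
    clustering = as.numeric(fnc_clustering(fnc)),
    betweenness = as.numeric(fnc_betweenness(fnc)),
    eigencentrality = as.numeric(fnc_eigencentrality(fnc))
  )
}

#' Network averages of the nodal measures
#'
#' Arithmetic mean of each nodal measure over all nodes, including
#' non-neuronal nodes whose zeroed rows indicate absent interaction; the
#' global summary of communication quality in the network.
#'
#' @param metrics A [nodal_metrics()] tibble (possibly covering several
#'   subjects).
#' @return A tibble with one row per subject and columns `degree`,
#'   `strength`, `clustering`, `betweenness`, `eigencentrality`.
#' @export
network_summary <- function(metrics) {
  measures <- c("degree", "strength", "clustering", "betweenness",
                "eigencentrality")
  if (!all(measures %in% names(metrics))) {
    abort("`metrics` must contain the five nodal measure columns",
          class = "fnconn_invalid_argument")
  }
  metrics |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("subject", "group")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(measures), mean),
                     .groups = "drop")
}

#' Nodal and average measures for a whole cohort
#'
#' Runs [build_fnc()] and [nodal_metrics()] for every subject of a
#' generated cohort and stacks the results in the long format consumed by
#' [compare_groups()]: one row per (subject, group, rsn, measure), with the
#' network averages included as pseudo-node `"average"`.
#'
#' @param cohort Named list of groups, each a list of [timecourse_set()]
#'   objects (as returned by [generate_cohort()]).
#' @param max_lag,edge_rule Passed to [build_fnc()].
#' @return A long tibble with columns `subject`, `group`, `rsn`, `measure`,
#'   `value`.
#' @export
cohort_metrics <- function(cohort, max_lag = 3,
                           edge_rule = edge_rule_surrogate()) {
  measures <- c("degree", "strength", "clustering", "betweenness",
                "eigencentrality")
  rows <- purrr::map(unlist(cohort, recursive = FALSE), function(tcs) {
    m <- nodal_metrics(build_fnc(tcs, max_lag = max_lag,
                                 edge_rule = edge_rule))
    avg <- network_summary(m)
    avg$rsn <- "average"
    dplyr::bind_rows(m, avg)
  })
  dplyr::bind_rows(rows) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value") |>
    dplyr::arrange(.data$group, .data$subject, .data$measure)
}
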