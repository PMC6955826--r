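# Independent reference implementations used as oracles.  These are kept
# deliberately naive (explicit loops, full enumeration) and separate from
# the package's vectorised / FFT / Floyd-Warshall code paths.

# Distance correlation by literal double-centering with explicit loops.
oracle_dcor <- function(x, y) {
  n <- length(x)
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- abs(x[i] - x[j])
    B[i, j] <- abs(y[i] - y[j])
  }
  center <- function(M) {
    out <- matrix(0, n, n)
    rm <- numeric(n); cm <- numeric(n)
    for (i in 1:n) rm[i] <- mean(M[i, ])
    for (j in 1:n) cm[j] <- mean(M[, j])
    gm <- mean(M)
    for (i in 1:n) for (j in 1:n) out[i, j] <- M[i, j] - rm[i] - cm[j] + gm
    out
  }
  A <- center(A); B <- center(B)
  dcov2 <- 0; vx <- 0; vy <- 0
  for (i in 1:n) for (j in 1:n) {
    dcov2 <- dcov2 + A[i, j] * B[i, j]
    vx <- vx + A[i, j]^2
    vy <- vy + B[i, j]^2
  }
  dcov2 <- dcov2 / n^2; vx <- vx / n^2; vy <- vy / n^2
  sqrt(max(dcov2, 0)) / (vx * vy)^(1 / 4)
}

# Betweenness by exhaustive enumeration of all simple paths (lengths 1/w),
# fractional credit across tied geodesics.  Feasible for <= 8 nodes.
oracle_betweenness <- function(W, retained, neuronal = rep(TRUE, nrow(W))) {
  n <- nrow(W)
  len <- ifelse(W * retained > 0, 1 / W, Inf)
  bc <- numeric(n)
  tol <- 1e-9
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      paths <- list()
      lens <- numeric(0)
      walk <- function(v, visited, acc) {
        if (v == t) {
          paths[[length(paths) + 1]] <<- visited
          lens[length(lens) + 1] <<- acc
          return(invisible())
        }
        for (w in seq_len(n)) {
          if (w %in% visited || !is.finite(len[v, w])) next
          walk(w, c(visited, w), acc + len[v, w])
        }
      }
      walk(s, s, 0)
      if (length(lens) == 0) next
      dmin <- min(lens)
      geo <- which(lens <= dmin + tol * max(1, dmin))
      for (g in geo) {
        interior <- setdiff(paths[[g]], c(s, t))
        bc[interior] <- bc[interior] + 1 / length(geo)
      }
    }
  }
  m <- sum(neuronal)
  denom <- (m - 1) * (m - 2) / 2
  if (denom > 0) bc / denom else bc * 0
}

# Leading eigenvector via dense eigendecomposition.
oracle_eigencentrality <- function(W, retained, neuronal = rep(TRUE, nrow(W))) {
  n <- nrow(W)
  out <- numeric(n)
  idx <- which(neuronal)
  A <- (W * retained)[idx, idx, drop = FALSE]
  if (length(idx) == 0 || max(A) == 0) return(out)
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (v[which.max(abs(v))] < 0) v <- -v
  out[idx] <- v
  out
}

# Construct an fnc_matrix object directly from a weight matrix and mask,
# bypassing time-course estimation, for exercising the graph measures.
make_fnc <- function(weights, retained = weights > 0,
                     neuronal = rep(TRUE, nrow(weights)),
                     labels = NULL) {
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- if (n == 10) fnconn::rsn_labels() else paste0("n", seq_len(n))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  retained <- retained & t(retained) & weights > 0
  diag(retained) <- FALSE
  weights[!neuronal, ] <- 0; weights[, !neuronal] <- 0
  retained[!neuronal, ] <- FALSE; retained[, !neuronal] <- FALSE
  dimnames(weights) <- dimnames(retained) <- list(labels, labels)
  structure(
    list(labels = labels, weights = weights,
         lags = matrix(0L, n, n, dimnames = list(labels, labels)),
         retained = retained, p = matrix(NA_real_, n, n),
         neuronal = setNames(neuronal, labels), max_lag = 0,
         edge_rule = fnconn::edge_rule_fixed(0),
         group = NA_character_, subject = NA_character_),
    class = "fnc_matrix"
  )
}

# Random symmetric weighted graph for property tests.
random_weight_matrix <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < density]
  W[on] <- runif(length(on), 0.1, 1)
  W + t(W)
}

# Exhaustive best assignment of templates (rows) to components (columns).
oracle_assignment <- function(score) {
  n <- nrow(score); m <- ncol(score)
  perms <- gtools_permutations(m, n)
  best <- NULL; best_val <- -Inf
  for (k in seq_len(nrow(perms))) {
    val <- sum(score[cbind(seq_len(n), perms[k, ])])
    if (val > best_val + 1e-12) { best_val <- val; best <- perms[k, ] }
  }
  list(assignment = best, value = best_val)
}

# all injective k-permutations of 1..m (small m only)
gtools_permutations <- function(m, k) {
  if (k == 1) return(matrix(seq_len(m), ncol = 1))
  out <- NULL
  for (i in seq_len(m)) {
    sub <- gtools_permutations(m, k - 1)
    sub <- sub[apply(sub != i, 1, all), , drop = FALSE]
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}
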