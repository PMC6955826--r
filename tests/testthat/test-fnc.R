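test_that("non-neuronal components are zeroed and never retained", {
  g <- generate_coupling_graph(10, 1, c(0.6, 0.9), 0, seed = 1)
  tcs <- simulate_timecourses(g, 128, seed = 2)
  tcs$neuronal[3] <- FALSE
  fnc <- build_fnc(tcs, edge_rule = edge_rule_fixed(0.1))
  expect_true(all(fnc$weights[3, ] == 0))
  expect_true(all(fnc$weights[, 3] == 0))
  expect_false(any(fnc$retained[3, ]))
  expect_equal(fnc_degree(fnc)[[3]], 0)
  expect_equal(fnc_strength(fnc)[[3]], 0)
})

test_that("an extreme fixed threshold suppresses every edge", {
  tcs <- withr::with_seed(4, {
    timecourse_set(matrix(rnorm(128 * 10), 128, 10,
                          dimnames = list(NULL, rsn_labels())))
  })
  fnc <- build_fnc(tcs, edge_rule = edge_rule_fixed(0.99))
  expect_equal(unname(fnc_degree(fnc)), rep(0, 10))
  expect_warning(fnc_eigencentrality(fnc), "empty")
})

test_that("coupled edges at moderate weight and noise are recovered", {
  # sensitivity of the surrogate rule at weight 0.7, noise_sd 0.5
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 0.7
  L <- matrix(0L, 4, 4); L[1, 2] <- 2L; L[2, 1] <- -2L
  g <- coupling_graph(W, L)
  kept <- vapply(1:50, function(s) {
    tcs <- simulate_timecourses(g, 297, noise_sd = 0.5, seed = s)
    obs <- lagged_distance_correlation(tcs$values[, 1], tcs$values[, 2],
                                       max_lag = 3)$dcor
    thr <- surrogate_threshold(tcs$values[, 1], tcs$values[, 2],
                               max_lag = 3, n_surrogates = 100,
                               alpha = 0.05, seed = 500 + s)
    obs > thr
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("a strongly coupled pair is retained in the assembled matrix", {
  W <- matrix(0, 10, 10); W[1, 2] <- W[2, 1] <- 0.9
  L <- matrix(0L, 10, 10); L[1, 2] <- 2L; L[2, 1] <- -2L
  g <- coupling_graph(W, L)
  kept <- vapply(1:10, function(s) {
    tcs <- simulate_timecourses(g, 297, seed = s)
    fnc <- build_fnc(tcs, edge_rule = edge_rule_surrogate(seed = s))
    fnc$retained[1, 2]
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("degree and strength equal masked row sums", {
  withr::with_seed(6, {
    for (rep in 1:10) {
      W <- random_weight_matrix(10, 0.5)
      R <- W > 0 & matrix(runif(100), 10) > 0.3
      R <- R & t(R)
      fnc <- make_fnc(W, R)
      expect_equal(unname(fnc_degree(fnc)),
                   unname(rowSums(fnc$retained)))
      expect_equal(unname(fnc_strength(fnc)),
                   unname(rowSums(fnc$weights * fnc$retained)))
    }
  })
})

test_that("clustering matches closed forms on canonical motifs", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1
  expect_equal(unname(fnc_clustering(make_fnc(tri + t(tri)))), rep(1, 3))
  tri05 <- matrix(0, 3, 3); tri05[upper.tri(tri05)] <- 0.5
  expect_equal(unname(fnc_clustering(make_fnc(tri05 + t(tri05)))),
               rep(0.5, 3))
  star <- matrix(0, 5, 5); star[1, 2:5] <- 0.8; star <- star + t(star)
  expect_equal(unname(fnc_clustering(make_fnc(star))), rep(0, 5))
})

test_that("betweenness matches closed forms and the exhaustive oracle", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 0.5
  fnc <- make_fnc(path3 + t(path3))
  expect_equal(unname(fnc_betweenness(fnc)), c(0, 1, 0))
  comp <- matrix(0.7, 6, 6); diag(comp) <- 0
  expect_equal(unname(fnc_betweenness(make_fnc(comp))), rep(0, 6))
  withr::with_seed(21, {
    for (rep in 1:30) {
      n <- sample(4:8, 1)
      W <- random_weight_matrix(n, runif(1, 0.3, 0.9))
      fnc <- make_fnc(W)
      expect_equal(unname(fnc_betweenness(fnc)),
                   oracle_betweenness(fnc$weights, fnc$retained),
                   tolerance = 1e-8)
    }
  })
})

test_that("eigenvector centrality matches closed forms and dense eigen", {
  comp3 <- matrix(0.4, 3, 3); diag(comp3) <- 0
  expect_equal(unname(fnc_eigencentrality(make_fnc(comp3))),
               rep(1 / sqrt(3), 3), tolerance = 1e-9)
  single <- matrix(0, 4, 4); single[1, 2] <- single[2, 1] <- 0.6
  expect_equal(unname(fnc_eigencentrality(make_fnc(single))),
               c(1 / sqrt(2), 1 / sqrt(2), 0, 0), tolerance = 1e-9)
  withr::with_seed(22, {
    for (rep in 1:30) {
      n <- sample(4:8, 1)
      W <- random_weight_matrix(n, runif(1, 0.4, 1))
      fnc <- make_fnc(W)
      got <- unname(fnc_eigencentrality(fnc))
      want <- oracle_eigencentrality(fnc$weights, fnc$retained)
      expect_equal(got, want, tolerance = 1e-7)
    }
  })
})

test_that("relabelling nodes permutes every nodal measure identically", {
  withr::with_seed(23, {
    W <- random_weight_matrix(8, 0.6)
    fnc <- make_fnc(W)
    perm <- sample(8)
    fnc_p <- make_fnc(W[perm, perm])
    for (f in list(fnc_degree, fnc_strength, fnc_clustering,
                   fnc_betweenness)) {
      expect_equal(unname(f(fnc_p)), unname(f(fnc))[perm], tolerance = 1e-9)
    }
    expect_equal(unname(fnc_eigencentrality(fnc_p)),
                 unname(fnc_eigencentrality(fnc))[perm], tolerance = 1e-7)
  })
})

test_that("raising a fixed threshold never increases degree", {
  tcs <- simulate_timecourses(
    generate_coupling_graph(10, 0.5, c(0.3, 0.8), 2, seed = 31), 128,
    seed = 32)
  thresholds <- c(0.1, 0.25, 0.4, 0.6, 0.9)
  degs <- sapply(thresholds, function(th) {
    fnc_degree(build_fnc(tcs, edge_rule = edge_rule_fixed(th)))
  })
  expect_true(all(diff(t(degs)) <= 0))
})

test_that("strength is bounded by degree through the weight range", {
  withr::with_seed(24, {
    W <- random_weight_matrix(10, 0.5)
    fnc <- make_fnc(W)
    k <- fnc_degree(fnc); s <- fnc_strength(fnc)
    wmin <- min(fnc$weights[fnc$retained])
    expect_true(all(s >= wmin * k - 1e-12))
    expect_true(all(s <= k + 1e-12))
  })
})

test_that("network averages are plain means over all ten nodes", {
  W <- matrix(0, 10, 10); W[1, 2:10] <- 0.5; W <- W + t(W)
  fnc <- make_fnc(W)
  m <- nodal_metrics(fnc)
  avg <- network_summary(m)
  expect_equal(avg$degree, mean(m$degree))
  expect_equal(avg$degree, (9 + 9 * 1) / 10)  # hub 9, leaves 1 each
  expect_equal(avg$strength, mean(m$strength))
})

test_that("fnc tidiers expose the edge table and summary", {
  g <- generate_coupling_graph(10, 0.4, c(0.4, 0.8), 2, seed = 41)
  tcs <- simulate_timecourses(g, 128, seed = 42)
  fnc <- build_fnc(tcs, edge_rule = edge_rule_surrogate(seed = 43,
                                                        n_surrogates = 40))
  td <- tidy(fnc)
  expect_equal(nrow(td), 45)
  expect_true(all(td$dcor >= 0 & td$dcor <= 1))
  expect_true(all(td$p >= 0 & td$p <= 1))
  gl <- glance(fnc)
  expect_equal(gl$n_retained, sum(td$retained))
  expect_equal(gl$avg_degree, mean(fnc_degree(fnc)))
})
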