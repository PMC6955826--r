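test_that("distance correlation matches the loop-based oracle", {
  # the small printed example first
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  expect_equal(distance_correlation(x, y), oracle_dcor(x, y),
               tolerance = 1e-12)
  withr::with_seed(11, {
    for (k in 1:20) {
      n <- sample(5:50, 1)
      x <- rnorm(n)
      y <- switch(k %% 3 + 1, rnorm(n), x^2 + rnorm(n, sd = 0.2),
                  exp(x) + rnorm(n, sd = 0.5))
      expect_equal(distance_correlation(x, y), oracle_dcor(x, y),
                   tolerance = 1e-10)
    }
  })
})

test_that("distance correlation has its defining algebraic properties", {
  withr::with_seed(3, {
    x <- rnorm(40); y <- rnorm(40)
    expect_equal(distance_correlation(x, x), 1)
    expect_equal(distance_correlation(x, 2 * x + 1), 1)
    expect_equal(distance_correlation(x, y), distance_correlation(y, x),
                 tolerance = 1e-12)
    # translation / positive-scaling invariance of both arguments
    expect_equal(distance_correlation(x, y),
                 distance_correlation(3 * x - 2, 0.5 * y + 7),
                 tolerance = 1e-12)
    expect_gte(distance_correlation(x, y), 0)
    expect_lte(distance_correlation(x, y), 1)
  })
})

test_that("degenerate and malformed inputs are rejected", {
  expect_error(distance_correlation(rep(1, 10), rnorm(10)),
               class = "fnconn_degenerate")
  expect_error(distance_correlation(rnorm(10), rnorm(9)),
               class = "fnconn_invalid_argument")
  expect_error(distance_correlation(rnorm(3), rnorm(3)),
               class = "fnconn_invalid_argument")
})

test_that("rotation profile agrees with direct evaluation at every shift", {
  withr::with_seed(5, {
    x <- rnorm(60); y <- rnorm(60)
    prof <- dcor_rotation_profile(x, y)
    for (k in c(0, 1, 2, 7, 30, 59)) {
      expect_equal(prof[k + 1],
                   distance_correlation(x, circular_shift(y, -k)),
                   tolerance = 1e-12)
    }
  })
})

test_that("lag maximisation recovers an exact circular shift", {
  withr::with_seed(8, {
    x <- as.numeric(scale(cumsum(rnorm(100))))
    r <- lagged_distance_correlation(x, circular_shift(x, 2), max_lag = 3)
    expect_equal(r$dcor, 1)
    expect_identical(r$best_lag, 2L)
    r2 <- lagged_distance_correlation(x, circular_shift(x, -3), max_lag = 3)
    expect_identical(r2$best_lag, -3L)
  })
})

test_that("max_lag = 0 reduces to the plain statistic", {
  withr::with_seed(9, {
    x <- rnorm(50); y <- rnorm(50)
    r <- lagged_distance_correlation(x, y, max_lag = 0)
    expect_equal(r$dcor, distance_correlation(x, y), tolerance = 1e-12)
    expect_identical(r$best_lag, 0L)
  })
})

test_that("the lagged maximum is non-decreasing in the window size", {
  withr::with_seed(10, {
    for (rep in 1:10) {
      x <- rnorm(80); y <- rnorm(80)
      vals <- vapply(0:6, function(L) {
        lagged_distance_correlation(x, y, max_lag = L)$dcor
      }, numeric(1))
      expect_true(all(diff(vals) >= -1e-12))
    }
  })
})

test_that("lag ties break toward smaller magnitude, then negative", {
  # constant profile: every lag ties; convention picks 0
  x <- rep(c(1, 2), 20) + seq(0, 0.39, 0.01)
  r <- lagged_distance_correlation(x, x, max_lag = 0)
  expect_identical(r$best_lag, 0L)
  vals <- setNames(c(0.3, 0.5, 0.4, 0.5, 0.3), -2:2)
  ord <- fnconn:::lag_preference(-2:2)
  expect_identical((-2:2)[ord][which.max(vals[ord])], -1L)
})

test_that("surrogate threshold edge cases and determinism", {
  withr::with_seed(2, {
    x <- rnorm(100); y <- rnorm(100)
  })
  t1 <- surrogate_threshold(x, y, max_lag = 3, n_surrogates = 50,
                            alpha = 0.05, seed = 4)
  t2 <- surrogate_threshold(x, y, max_lag = 3, n_surrogates = 50,
                            alpha = 0.05, seed = 4)
  expect_identical(t1, t2)
  # alpha = 1 returns the minimum of the null sample
  prof <- dcor_rotation_profile(x, y)
  null <- withr::with_seed(4, {
    fnconn:::rotation_null_stats(
      prof, fnconn:::sample_rotations(100, 3, 50), 3)
  })
  expect_equal(surrogate_threshold(x, y, 3, 50, alpha = 1, seed = 4),
               min(null))
  expect_error(surrogate_threshold(x, y, 3, 10, 0.05, 1),
               class = "fnconn_invalid_argument")
  expect_error(surrogate_threshold(x, y, 3, 50, 0, 1),
               class = "fnconn_invalid_argument")
})

test_that("surrogate test is calibrated on independent pairs", {
  # type-I error of the lag-maximised statistic at alpha = 0.05
  rejections <- vapply(1:200, function(s) {
    xy <- withr::with_seed(1000 + s, {
      list(x = band_limited_pair(), y = band_limited_pair())
    })
    obs <- lagged_distance_correlation(xy$x, xy$y, max_lag = 3)$dcor
    thr <- surrogate_threshold(xy$x, xy$y, max_lag = 3, n_surrogates = 60,
                               alpha = 0.05, seed = s)
    obs > thr
  }, logical(1))
  rate <- mean(rejections)
  # binomial(200, 0.05) central 99.9% interval is roughly [0.01, 0.105]
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)
})
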