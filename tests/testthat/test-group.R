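# build a sample with exactly the requested mean and sample SD
sample_with_moments <- function(m, s, n, seed = 1) {
  z <- withr::with_seed(seed, rnorm(n))
  z <- as.numeric(scale(z))
  m + s * z
}

test_that("welch_t on raw samples agrees with the summary formulas", {
  for (k in 1:5) {
    a <- sample_with_moments(1 + k, 0.5 * k, 20 + k, seed = k)
    b <- sample_with_moments(k, 0.3 * k, 15 + k, seed = 100 + k)
    raw <- welch_t(a, b)
    summ <- welch_t_from_summary(mean(a), sd(a), length(a),
                                 mean(b), sd(b), length(b))
    expect_equal(raw$t, summ$t, tolerance = 1e-9)
    expect_equal(raw$df, summ$df, tolerance = 1e-9)
    expect_equal(raw$p, summ$p, tolerance = 1e-9)
  }
})

test_that("welch_t is antisymmetric and null on identical samples", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 4, 6, 7)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(welch_t_from_summary(2, 1, 10, 2, 1, 10)$t, 0)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(welch_t(rep(1, 5), rep(2, 6)), class = "fnconn_degenerate")
  expect_error(welch_t(1, c(1, 2)), class = "fnconn_invalid_argument")
  expect_error(welch_t_from_summary(1, 0, 10, 2, 0, 10),
               class = "fnconn_degenerate")
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 10),
               class = "fnconn_invalid_argument")
})

# minimal long metrics table for two groups and one measure
toy_metrics <- function(a, b, rsn = "average", measure = "degree",
                        groups = c("HC", "UWS")) {
  tibble::tibble(
    subject = c(sprintf("a%02d", seq_along(a)),
                sprintf("b%02d", seq_along(b))),
    group = rep(groups, c(length(a), length(b))),
    rsn = rsn, measure = measure,
    value = c(a, b)
  )
}

test_that("compare_groups on a single pair equals a direct welch_t call", {
  a <- sample_with_moments(3.8, 2.1, 27, seed = 5)
  b <- sample_with_moments(1.7, 2.6, 24, seed = 6)
  cmp <- compare_groups(toy_metrics(a, b), pairs = "HC-UWS")
  direct <- welch_t(a, b)
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$t, direct$t, tolerance = 1e-12)
  expect_equal(cmp$p, direct$p, tolerance = 1e-12)
})

test_that("the DOC pair pools MCS and UWS subjects", {
  a <- sample_with_moments(2, 1, 10, seed = 1)
  b <- sample_with_moments(1, 1, 8, seed = 2)
  c3 <- sample_with_moments(0.5, 1, 9, seed = 3)
  metrics <- dplyr::bind_rows(
    toy_metrics(a, b, groups = c("HC", "MCS")),
    toy_metrics(numeric(0), c3, groups = c("HC", "UWS"))
  )
  cmp <- compare_groups(metrics, pairs = "HC-DOC")
  direct <- welch_t(a, c(b, c3))
  expect_equal(cmp$t, direct$t, tolerance = 1e-12)
  expect_error(compare_groups(metrics, pairs = "HC-XYZ"),
               class = "fnconn_invalid_argument")
})

test_that("nodal tests use the Bonferroni family, averages do not", {
  withr::with_seed(9, {
    nodal <- dplyr::bind_rows(lapply(rsn_labels(), function(r) {
      toy_metrics(rnorm(20), rnorm(20), rsn = r)
    }))
  })
  # inject one strong nodal effect with borderline p: corrected at 0.005
  strong <- toy_metrics(rnorm(20, 2), rnorm(20), rsn = "DMN")
  nodal$value[nodal$rsn == "DMN"] <- strong$value
  cmp <- compare_groups(nodal, pairs = "HC-UWS", alpha = 0.05, family = 10)
  expect_true(all(cmp$significant == (cmp$p < 0.005)))
  avg <- compare_groups(toy_metrics(rnorm(20, 1), rnorm(20)),
                        pairs = "HC-UWS")
  expect_true(all(avg$significant == (avg$p < 0.05)))
})

test_that("corrected nodal family keeps its type-I error under the null", {
  withr::with_seed(77, {
    sig <- replicate(500, {
      metrics <- dplyr::bind_rows(lapply(paste0("r", 1:10), function(r) {
        toy_metrics(rnorm(15), rnorm(15), rsn = r)
      }))
      cmp <- compare_groups(metrics, pairs = "HC-UWS", alpha = 0.05,
                            family = 10)
      any(cmp$significant)
    })
  })
  # family-wise rate should be at most ~alpha; binomial(500, 0.05)
  # upper 99.9% bound is about 0.082
  expect_lte(mean(sig), 0.085)
})

test_that("glance summarises a comparison table", {
  cmp <- compare_groups(toy_metrics(sample_with_moments(5, 1, 12, 1),
                                    sample_with_moments(0, 1, 12, 2)),
                        pairs = "HC-UWS")
  gl <- glance(cmp)
  expect_equal(gl$n_tests, 1)
  expect_equal(gl$n_significant, 1)
})
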