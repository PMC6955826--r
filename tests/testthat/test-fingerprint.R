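blob_with_noise <- function(noise_sd = 0.3, dim = c(16, 16, 8), seed = 1) {
  tmpl <- rsn_templates(dim = dim)
  withr::with_seed(seed, {
    tmpl$masks[[sample(10, 1)]] * 1 +
      array(rnorm(prod(dim), sd = noise_sd), dim)
  })
}

test_that("fingerprints have eleven well-formed features", {
  x <- withr::with_seed(1, band_limited_pair())
  fp <- compute_fingerprint(x, blob_with_noise(), 2)
  expect_identical(names(fp), fingerprint_features())
  bp <- as.numeric(fp[1, 7:11])
  expect_true(all(bp >= 0))
  expect_equal(sum(bp), 1, tolerance = 1e-9)
  expect_true(abs(fp$one_lag_autocorrelation) <= 1)
})

test_that("band powers concentrate where the signal lives", {
  t_sec <- (0:296) * 2
  sine <- sin(2 * pi * 0.03 * t_sec) + rnorm(297, sd = 1e-3)
  fp <- compute_fingerprint(sine, blob_with_noise(), 2)
  bp <- as.numeric(fp[1, 7:11])
  expect_equal(which.max(bp), 3)  # 0.02-0.05 Hz band
  hf <- generate_artifact_timecourse("highfreq", 297, 2, seed = 2)
  fp_hf <- compute_fingerprint(hf, blob_with_noise(), 2)
  expect_equal(which.max(as.numeric(fp_hf[1, 7:11])), 5)
})

test_that("band powers are invariant to positive scaling of the series", {
  x <- withr::with_seed(3, band_limited_pair())
  fp1 <- compute_fingerprint(x, blob_with_noise(), 2)
  fp2 <- compute_fingerprint(5 * x, blob_with_noise(), 2)
  expect_equal(as.numeric(fp1[1, 7:11]), as.numeric(fp2[1, 7:11]),
               tolerance = 1e-12)
})

test_that("spatial skewness of pure noise is near zero", {
  n_vox <- 16 * 16 * 8
  se <- sqrt(6 / n_vox)
  skews <- vapply(1:10, function(s) {
    map <- withr::with_seed(100 + s, array(rnorm(n_vox), c(16, 16, 8)))
    x <- withr::with_seed(200 + s, band_limited_pair())
    compute_fingerprint(x, map, 2)$skewness
  }, numeric(1))
  expect_true(all(abs(skews) < 3 * se + 0.05))
  expect_lt(abs(mean(skews)), 3 * se)
})

test_that("sawtooth fixtures show strong one-lag autocorrelation", {
  saw <- generate_artifact_timecourse("sawtooth", 297, 2, seed = 4)
  fp <- compute_fingerprint(saw, blob_with_noise(), 2)
  expect_gt(fp$one_lag_autocorrelation, 0.5)
})

test_that("degenerate fingerprint inputs raise errors", {
  expect_error(compute_fingerprint(rep(1, 100), blob_with_noise(), 2),
               class = "fnconn_degenerate")
  expect_error(compute_fingerprint(rnorm(100),
                                   array(2, c(4, 4, 4)), 2),
               class = "fnconn_degenerate")
  expect_error(compute_fingerprint(rnorm(10), blob_with_noise(), 2),
               class = "fnconn_invalid_argument")
})

test_that("degree of clustering separates blobs from scattered noise", {
  blob <- blob_with_noise(noise_sd = 0.15, seed = 6)
  noise <- withr::with_seed(7, array(rnorm(16 * 16 * 8), c(16, 16, 8)))
  x <- withr::with_seed(8, band_limited_pair())
  doc_blob <- compute_fingerprint(x, blob, 2)$degree_of_clustering
  doc_noise <- compute_fingerprint(x, noise, 2)$degree_of_clustering
  expect_gt(doc_blob, doc_noise)
})

# labelled fingerprint bank: neuronal = band-limited course + blob map,
# artifactual = one of the three artifact signatures + scattered map
fingerprint_bank <- function(n_each, seed) {
  kinds <- c("highfreq", "spike", "sawtooth")
  withr::with_seed(seed, {
    rows <- list()
    for (k in seq_len(n_each)) {
      x <- band_limited_pair()
      rows[[length(rows) + 1]] <- cbind(
        compute_fingerprint(x, blob_with_noise(0.2, seed = 1000 + k), 2),
        label = "neuronal")
      kind <- kinds[(k %% 3) + 1]
      a <- generate_artifact_timecourse(kind, 297, 2,
                                        seed = sample.int(1e6, 1))
      map <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
      rows[[length(rows) + 1]] <- cbind(
        compute_fingerprint(a, map, 2), label = "artifactual")
    }
    dplyr::bind_rows(rows)
  })
}

test_that("the linear classifier separates neuronal from artifactual", {
  train <- fingerprint_bank(60, seed = 31)
  test <- fingerprint_bank(40, seed = 32)
  model <- train_neuronal_classifier(train, train$label)
  pred <- classify_neuronal(test, model)
  acc <- mean(pred$label == test$label)
  expect_gte(acc, 0.9)
  # margins are oriented: positive for neuronal calls
  expect_true(all((pred$margin > 0) == (pred$label == "neuronal")))
})

test_that("confident training exemplars keep their own label", {
  train <- fingerprint_bank(40, seed = 33)
  model <- train_neuronal_classifier(train, train$label)
  pred <- classify_neuronal(train, model)
  confident <- abs(pred$margin) > 1
  expect_true(all(pred$label[confident] == train$label[confident]))
  expect_gt(mean(pred$label == train$label), 0.95)
})

test_that("a spike component is called artifactual", {
  train <- fingerprint_bank(50, seed = 34)
  model <- train_neuronal_classifier(train, train$label)
  spike_course <- generate_artifact_timecourse("spike", 297, 2, seed = 35)
  expect_gt(fnconn:::moment_kurtosis(spike_course), 3)
  spike_fp <- compute_fingerprint(
    spike_course,
    withr::with_seed(36, array(rnorm(16 * 16 * 8), c(16, 16, 8))), 2)
  expect_identical(classify_neuronal(spike_fp, model)$label, "artifactual")
})

test_that("single-class training data is rejected", {
  bank <- fingerprint_bank(5, seed = 37)
  neu <- bank[bank$label == "neuronal", ]
  expect_error(train_neuronal_classifier(neu, neu$label),
               class = "fnconn_invalid_argument")
})
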