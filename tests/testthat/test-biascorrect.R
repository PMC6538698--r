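test_that("end features one-hot encode the first and last three bases", {
  pool <- reference_pool("m", "GTAAACT")
  x <- encode_end_features(pool)
  on <- colnames(x)[x[1, ] == 1]
  expect_setequal(on, c("+1.G", "+2.T", "+3.A", "-3.A", "-2.C", "-1.T"))
  expect_equal(ncol(x), 24)

  pool2 <- simulate_pool(40, seed = 1)
  x2 <- encode_end_features(pool2)
  expect_true(all(rowSums(x2) == 6))
  for (p in c("\\+1\\.", "-1\\.")) {
    block <- x2[, grepl(p, colnames(x2))]
    expect_true(all(rowSums(block) == 1))
  }
  expect_error(encode_end_features(reference_pool("s", "ACGTAC"),
                                   positions = c(1:3, -7L)), "outside")
  expect_error(reference_pool("s", "ACGTA"), "shorter")
})

test_that("a model fitted on zero errors predicts zero", {
  pool <- simulate_pool(60, seed = 2)
  feats <- encode_end_features(pool)
  zero <- stats::setNames(rep(0, 60), pool$ids)
  expect_warning(m <- fit_bias_model(feats, zero), "constant")
  expect_true(all(abs(predict(m, feats)) < 1e-6))
})

test_that("fitting is deterministic given the seed", {
  pool <- simulate_pool(80, seed = 5)
  sim <- simulate_counts(pool, bias_spec(study_bias_effects(), seed = 5))
  err <- measurement_errors(cpm_normalize(sim$counts), 1e6 / 80)
  feats <- encode_end_features(pool)
  m1 <- fit_bias_model(feats, err, seed = 77)
  m2 <- fit_bias_model(feats, err, seed = 77)
  expect_identical(predict(m1, feats), predict(m2, feats))
  m3 <- fit_bias_model(feats, err, seed = 78)
  expect_false(identical(predict(m1, feats), predict(m3, feats)))
})

test_that("a single -1 effect of +/-0.5 log10 is recovered to ~1.0 spread", {
  pool <- simulate_pool(300, seed = 6)
  sim <- simulate_counts(pool, bias_spec(list("-1" = c(G = 0.5, T = -0.5)),
                                         depth = 1e6, seed = 6))
  err <- measurement_errors(cpm_normalize(sim$counts), 1e6 / 300)
  feats <- encode_end_features(pool)
  m <- fit_bias_model(feats, err)
  pred <- predict(m, feats)
  last <- substring(pool$sequences, nchar(pool$sequences))
  gap <- mean(pred[last == "G"]) - mean(pred[last == "T"])
  expect_equal(gap, 1.0, tolerance = 0.15)
  # species identical in all six terminal bases predict identically
  key <- paste(substr(pool$sequences, 1, 3),
               substring(pool$sequences, nchar(pool$sequences) - 2))
  dup <- split(pred, key)
  expect_true(all(vapply(dup, function(v) diff(range(v)) == 0, logical(1))))
})

test_that("correction subtracts the predicted error on the log10 scale", {
  pool <- simulate_pool(60, seed = 3)
  feats <- encode_end_features(pool)
  ones <- stats::setNames(rep(1, 60), pool$ids)
  expect_warning(m1 <- fit_bias_model(feats, ones), "constant")
  ab <- cpm_normalize(count_table(
    matrix(10395, 60, 1, dimnames = list(pool$ids, "s"))))
  # uniform columns renormalise to 1e6/60 CPM; force the worked value
  ab[] <- 10395
  corrected <- correct_counts(ab, m1, pool)
  expect_equal(unname(corrected[1, 1]), 1039.5, tolerance = 0.1)

  # a zero model is the exact identity at pc = 0
  zero <- stats::setNames(rep(0, 60), pool$ids)
  expect_warning(m0 <- fit_bias_model(feats, zero), "constant")
  expect_equal(correct_counts(ab, m0, pool, pc = 0), ab)
})

test_that("in-sample correction shrinks the error distribution", {
  pool <- simulate_pool(250, seed = 10)
  sim <- simulate_counts(pool, bias_spec(study_bias_effects(), seed = 10))
  ab <- cpm_normalize(sim$counts)
  err <- measurement_errors(ab, 1e6 / 250)
  m <- fit_bias_model(encode_end_features(pool), err)
  corrected <- correct_counts(ab, m, pool, renormalize = TRUE)
  err2 <- measurement_errors(corrected, 1e6 / 250)
  expect_lt(abs(mean(err2)), abs(mean(err)) + 0.02)
  expect_lt(sd(err2), sd(err))
})

test_that("cross-validation partitions every species exactly once", {
  pool <- simulate_pool(120, seed = 12)
  sim <- simulate_counts(pool, bias_spec(study_bias_effects(), seed = 12))
  err <- measurement_errors(cpm_normalize(sim$counts), 1e6 / 120)
  feats <- encode_end_features(pool)
  cv <- cross_validate_bias_model(feats, err, k = 8, seed = 1)
  expect_identical(sort(names(cv$folds)), sort(pool$ids))
  expect_equal(length(cv$fold_r2), 8)
  expect_true(all(table(cv$folds) >= 1))
  expect_gt(cv$mean_r2, 0.5)
  expect_error(cross_validate_bias_model(feats, err, k = 121), "folds")
})

test_that("cross-validated fit finds nothing to learn in unbiased data", {
  pool <- simulate_pool(150, seed = 13)
  sim <- simulate_counts(pool, bias_spec(seed = 13))
  err <- measurement_errors(cpm_normalize(sim$counts), 1e6 / 150)
  cv <- cross_validate_bias_model(encode_end_features(pool), err,
                                  k = 8, seed = 2)
  # no positive out-of-fold skill; negative values reflect regressor
  # variance on pure noise and are expected
  expect_lte(cv$mean_r2, 0.1)
})

test_that("positional importances are a distribution dominated by the true position", {
  pool <- simulate_pool(300, seed = 6)
  sim <- simulate_counts(pool, bias_spec(list("-1" = c(G = 0.5, T = -0.5)),
                                         seed = 6))
  err <- measurement_errors(cpm_normalize(sim$counts), 1e6 / 300)
  m <- fit_bias_model(encode_end_features(pool), err)
  pi <- positional_importance(m)
  expect_equal(sum(pi$per_position), 1)
  expect_equal(pi$five_prime_share + pi$three_prime_share, 1)
  expect_identical(names(which.max(pi$per_position)), "-1")
  expect_gt(pi$per_position[["-1"]], 0.5)
})

test_that("trinucleotide reweighting restores 5' trinucleotide frequencies", {
  # four species sharing a 3' trinucleotide; one 5' trinucleotide doubly
  # over-sampled
  pool <- reference_pool(paste0("m", 1:4),
                         c("AAAGGCTA", "CCCGGCTA", "GGGGGCTA", "TTTGGCTA"))
  ab <- count_table(matrix(c(200, 100, 100, 100), 4, 1,
                           dimnames = list(pool$ids, "s")))
  out <- trinucleotide_reweight(ab, pool)
  t5 <- substr(pool$sequences, 1, 3)
  f_after <- tapply(out[, 1], t5, sum) / sum(out[, 1])
  expect_equal(as.numeric(f_after), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(sum(out), sum(ab))

  # unbiased input is a fixpoint
  even <- count_table(matrix(50, 4, 1, dimnames = list(pool$ids, "s")))
  expect_equal(trinucleotide_reweight(even, pool), even)
})
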