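test_that("saturation curves are nondecreasing and plateau correctly", {
  one <- count_table(matrix(400, 1, 1, dimnames = list("a", "s")))
  sc <- saturation_curve(one, bin_size = 200, threshold = 10, seed = 1)
  expect_equal(sc$detected[1], 1)      # 10th read falls in the first bin
  expect_true(all(sc$detected == 1))

  two <- count_table(matrix(c(10, 10), 2, 1,
                            dimnames = list(c("a", "b"), "s")))
  sc2 <- saturation_curve(two, bin_size = 20, threshold = 10, seed = 3)
  expect_equal(sc2$detected[1], 2)     # any shuffle of 20 reads detects both

  set.seed(7)
  tab <- count_table(matrix(rpois(30, 30), 30, 1,
                            dimnames = list(paste0("m", 1:30), "s")))
  sc3 <- saturation_curve(tab, bin_size = 50, threshold = 10, seed = 7)
  expect_true(all(diff(sc3$detected) >= 0))
  expect_lte(max(sc3$detected), 30)
  expect_equal(max(sc3$detected), sum(rowSums(tab) >= 10))
  sc3b <- saturation_curve(tab, bin_size = 50, threshold = 10, seed = 7)
  expect_identical(sc3, sc3b)
  expect_error(saturation_curve(tab, threshold = 0), "threshold")
})

test_that("abundance summaries match sort-based quantiles on a toy vector", {
  vals <- c(3, 1, 4, 1, 5, 9, 2)
  ab <- set_scale_for_test(matrix(vals, 7, 1,
                                  dimnames = list(paste0("m", 1:7), "s")))
  s <- abundance_summary(ab, expected = 4)
  srt <- sort(vals)
  # type-7 quantile: x[1 + (n-1)p] with linear interpolation
  q7 <- function(p) {
    h <- 1 + (length(srt) - 1) * p
    lo <- floor(h)
    srt[lo] + (h - lo) * (srt[min(lo + 1, length(srt))] - srt[lo])
  }
  expect_equal(s$q1, q7(0.25))
  expect_equal(s$median, q7(0.5))
  expect_equal(s$q3, q7(0.75))
  expect_equal(s$median_deviation, q7(0.5) - 4)

  # median deviation invariant under permuting species, zero at uniform
  perm <- ab[sample(7), , drop = FALSE]
  attr(perm, "scale") <- "cpm"
  expect_equal(abundance_summary(perm, 4)$median_deviation,
               s$median_deviation)
  unif <- set_scale_for_test(matrix(1039.5, 962, 1,
                                    dimnames = list(paste0("m", 1:962), "s")))
  expect_equal(abundance_summary(unif, 1039.5)$median_deviation, 0)
})

test_that("replicate correlations match the rank-based formula", {
  dup <- count_table(matrix(c(1, 5, 3, 9, 1, 5, 3, 9), 4, 2,
                            dimnames = list(letters[1:4], c("r1", "r2"))))
  expect_equal(replicate_correlation(dup)["r1", "r2"], 1)

  rev <- count_table(matrix(c(1, 2, 3, 4, 40, 30, 20, 10), 4, 2,
                            dimnames = list(letters[1:4], c("r1", "r2"))))
  expect_equal(replicate_correlation(rev)["r1", "r2"], -1)

  x <- c(12, 2, 45, 8, 30)
  y <- c(9, 3, 30, 31, 22)
  tab <- count_table(matrix(c(x, y), 5, 2,
                            dimnames = list(paste0("m", 1:5), c("r1", "r2"))))
  expect_equal(replicate_correlation(tab)["r1", "r2"],
               cor(rank(x), rank(y)))  # Pearson on ranks as the oracle

  const <- count_table(matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
                              dimnames = list(letters[1:3], c("r1", "r2"))))
  expect_warning(m <- replicate_correlation(const), "constant")
  expect_true(is.na(m["r1", "r2"]))
})

test_that("self-fold proxy equals exhaustive enumeration on short sequences", {
  expect_equal(self_fold("AAAAAAA")$pairs, 0)
  gf <- self_fold("GGGAAACCC")
  expect_equal(gf$pairs, 3)
  expect_equal(gf$free5, 0)
  expect_equal(gf$free3, 0)
  expect_equal(gf$pairs, enumerate_max_pairs("GGGAAACCC"))

  fixed <- c("GCGCAAAGCGC", "AUGGCAAAUU", "ACGUACGUAC", "GGGGAAAACC",
             "UUUUAAAGGG")
  set.seed(17)
  random <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "U"), sample(6:10, 1), replace = TRUE),
          collapse = ""), character(1))
  for (s in c(fixed, random)) {
    expect_equal(self_fold(s)$pairs, enumerate_max_pairs(s), info = s)
  }
})

test_that("sequence factors are computed per species with valid ranges", {
  pool <- reference_pool(c("gc", "at"), c("GGCCGG", "AATTAA"))
  f <- sequence_factors(pool, adapter_seq = "GATCGGAAGAGC")
  expect_equal(f$gc, c(1, 0))
  expect_equal(f$length, c(6, 6))
  expect_true(all(f$free5 <= f$length & f$free3 <= f$length))
  expect_true(all(is.finite(f$self_fold)))
  expect_true(all(is.finite(f$co_fold)))
  f2 <- sequence_factors(pool)
  expect_true(all(is.na(f2$co_fold)))
})

test_that("co-fold scores the longest complementary adapter/cDNA duplex", {
  # species GGGGGAAAAA has cDNA TTTTTCCCCC: the adapter's GGGGG can form a
  # 5-bp duplex with the cDNA's CCCCC
  expect_equal(co_fold("GGGGG", "GGGGGAAAAA"), 5)
  expect_equal(co_fold("AAAAA", "GGGGGGGGGG"), 0)
  # attaching a second adapter (revcomp joins the cDNA) can create a duplex
  expect_equal(co_fold("GGGGG", "AAAAAAAAAA", r2r_seq = "GGGGG"), 5)
})

test_that("rank-sum p-values match exact enumeration on small groups", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  y <- c(2.1, 2.9, 4.4, 6.1, 8.3, 9.0)
  expect_equal(wilcox.test(x, y, exact = TRUE)$p.value,
               exact_ranksum_p(x, y), tolerance = 1e-12)

  x2 <- c(10, 11, 12)
  y2 <- c(1, 2, 3, 4, 5)
  expect_equal(wilcox.test(x2, y2, exact = TRUE)$p.value,
               exact_ranksum_p(x2, y2), tolerance = 1e-12)
})

test_that("outlier factor tests flag shifted factors and spare exchangeable ones", {
  pool <- simulate_pool(60, seed = 41)
  f <- sequence_factors(pool, adapter_seq = "GATCGGAAGAGC")
  err <- stats::setNames(rnorm(60, sd = 0.1), pool$ids)
  # force a clean over/under split
  err[1:5] <- 2
  err[6:12] <- -2
  labels <- classify_representation(err, 1)
  # shift the lengths of the over group far away
  f$length[match(pool$ids[1:5], f$id)] <- f$length[1:5] + 100
  res <- outlier_factor_test(f, labels)
  expect_setequal(unique(res$factor),
                  c("length", "gc", "self_fold", "co_fold", "free5", "free3"))
  expect_setequal(unique(res$contrast), c("over_vs_rest", "under_vs_rest"))
  p_len <- res$p_value[res$factor == "length" &
                       res$contrast == "over_vs_rest"]
  expect_lt(p_len, 0.01)

  # identical groups are not significant
  f2 <- f
  f2$gc <- rep(c(0.4, 0.5), 30)
  p_gc <- outlier_factor_test(f2, labels)
  expect_gte(p_gc$p_value[p_gc$factor == "gc" &
                          p_gc$contrast == "under_vs_rest"], 0.5)
})

test_that("length regression recovers exact and simulated slopes", {
  pool <- simulate_pool(200, seed = 51)
  lens <- nchar(pool$sequences)
  exact <- set_scale_for_test(
    matrix(10^(0.09 * lens + 0.9), 200, 1,
           dimnames = list(pool$ids, "s")))
  fit <- length_abundance_fit(exact, pool, pc = 0)
  expect_equal(fit$slope, 0.09, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- set_scale_for_test(
    matrix(1000, 200, 1, dimnames = list(pool$ids, "s")))
  fit0 <- length_abundance_fit(flat, pool, pc = 0)
  expect_equal(fit0$slope, 0, tolerance = 1e-12)

  sim <- simulate_counts(pool, bias_spec(length_slope = 0.09, depth = 1e7,
                                         seed = 51))
  fit_sim <- length_abundance_fit(cpm_normalize(sim$counts), pool)
  expect_lt(abs(fit_sim$slope - 0.09), 0.01)
})
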