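test_that("chi-squared allele test matches the hand-evaluated Pearson formula", {
  none <- chisq_test_counts(c(10, 10), c(10, 10))
  expect_equal(none$statistic, 0)
  expect_equal(none$pvalue, 1)
  # hand evaluation: X2 = N (ad - bc)^2 / (r1 r2 c1 c2) = 60*300^2/30^4...
  res <- chisq_test_counts(c(20, 10), c(10, 20))
  x2_hand <- 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  expect_equal(res$statistic, x2_hand) # = 6.666...
  expect_equal(res$pvalue, 0.00983, tolerance = 1e-3)
  # symmetric in time direction
  expect_equal(chisq_test_counts(c(10, 20), c(20, 10))$statistic, res$statistic)
  # zero marginal: no test
  expect_true(is.na(chisq_test_counts(c(0, 0), c(10, 20))$pvalue))
})

test_that("CMH test combines replicate strata and reduces to the 2x2 case", {
  flat <- cmh_test_counts(list(rbind(c(10, 10), c(10, 10)),
                               rbind(c(10, 10), c(10, 10))),
                          continuity = FALSE)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$pvalue, 1)
  # one stratum with continuity correction equals the corrected chi-squared
  tab <- rbind(c(20, 10), c(10, 20))
  one <- cmh_test_counts(list(tab), continuity = TRUE)
  ref <- stats::chisq.test(tab, correct = TRUE)
  expect_equal(one$statistic, unname(ref$statistic))
  expect_equal(one$pvalue, ref$p.value)
  # doubling all counts roughly doubles the statistic
  k2 <- cmh_test_counts(list(tab, tab), continuity = FALSE)
  k1 <- cmh_test_counts(list(tab), continuity = FALSE)
  expect_equal(k2$statistic / k1$statistic, 2, tolerance = 0.05)
  # degenerate strata give no test
  degen <- cmh_test_counts(list(rbind(c(0, 0), c(0, 0))))
  expect_true(is.na(degen$pvalue))
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.01, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("BH rejection controls the empirical FDR in a known-truth simulation", {
  set.seed(501)
  n_null <- 4000; n_alt <- 1000
  p <- c(runif(n_null), rbeta(n_alt, 0.1, 1))
  is_null <- rep(c(TRUE, FALSE), c(n_null, n_alt))
  q <- bh_adjust(p)
  rej <- q <= 0.1
  expect_gt(sum(rej), 0)
  fdr <- sum(rej & is_null) / max(1, sum(rej))
  expect_lte(fdr, 0.1 + 0.03) # alpha + Monte-Carlo margin
})

test_that("neighbour support filter keeps only outliers with a nearby outlier", {
  chrom <- c("I", "I", "I", "II", "II", "I")
  pos <- c(1000, 1999, 5000, 1000, 1500, 10000)
  out <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  keep <- neighbor_support_filter(chrom, pos, out, window = 1000)
  # 1000 and 1999 support each other (999 bp); 5000 and 10000 are isolated;
  # II:1000 has no outlier neighbour (II:1500 is not an outlier)
  expect_identical(keep, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # exact boundary: 1001 bp apart is not support
  expect_identical(neighbor_support_filter(c("I", "I"), c(1, 1002),
                                           c(TRUE, TRUE)),
                   c(FALSE, FALSE))
  expect_identical(neighbor_support_filter(c("I", "I"), c(1, 1001),
                                           c(TRUE, TRUE)),
                   c(TRUE, TRUE))
  # different chromosomes never support each other
  expect_identical(neighbor_support_filter(c("I", "II"), c(1, 500),
                                           c(TRUE, TRUE)),
                   c(FALSE, FALSE))
})

test_that("neutrality test returns sensible p-values at the extremes", {
  d <- sim_design(Ne = 300, replicates = 2, coverage = 80)
  tr <- simulate_locus(0.3, sel_params(0), d, noise = TRUE, seed = 502)
  expect_warning(res <- neutrality_test(tr, d, observed_s = -5, n_sims = 50,
                                        seed = 503),
                 "coarse")
  expect_gt(res$pvalue, 0.9) # every null estimate beats a huge negative s
  # strongly selected locus: small p-value
  tr2 <- simulate_locus(0.3, sel_params(0.2), d, noise = TRUE, seed = 504)
  res2 <- neutrality_test(tr2, d, n_sims = 200, seed = 505)
  expect_lt(res2$pvalue, 0.02)
  # add-one pseudo-count keeps p strictly positive
  expect_gte(res2$pvalue, 1 / 201)
})
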