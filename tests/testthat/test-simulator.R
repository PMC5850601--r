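test_that("one Wright-Fisher generation has binomial moments and absorbing bounds", {
  set.seed(101)
  expect_identical(wf_generation(rep(0, 50), sel_params(0.3), Ne = 100),
                   rep(0, 50))
  expect_identical(wf_generation(rep(1, 50), sel_params(0.3), Ne = 100),
                   rep(1, 50))
  # neutral diploid at Ne = 300: mean p, variance p(1-p)/600
  x <- wf_generation(rep(0.5, 1e4), sel_params(0), Ne = 300)
  expect_equal(mean(x), 0.5, tolerance = 0.005)
  expect_equal(var(x), 0.25 / 600, tolerance = 0.1)
  # large-Ne limit converges to the deterministic update
  y <- wf_generation(rep(0.5, 100), sel_params(0.1, ploidy = "haploid"),
                     Ne = 1e7)
  expect_equal(mean(y), 0.55 / 1.05, tolerance = 1e-3)
})

test_that("neutral drift matches the exact Markov-chain oracle at Ne = 50", {
  ng <- 100L # 2 Ne allele copies
  d <- sim_design(Ne = 50, generations = 60, interval = 10, replicates = 1,
                  coverage = 80)
  set.seed(102)
  n <- 2e4
  sim <- simulate_dataset(n, p0 = 0.5, s = 0, design = d, noise = FALSE)
  # variance after 20 generations
  v_obs <- var(sim$pop_freq[, 3L])
  v_exact <- wf_exact_var(0.5, ng, 20L)
  expect_equal(v_obs, v_exact, tolerance = 0.05)
  # and against the standard drift-variance formula p0 q0 (1 - (1-1/ng)^t)
  expect_equal(v_exact, 0.25 * (1 - (1 - 1 / ng)^20), tolerance = 1e-6)
  # loss probability of a 5% allele after 60 generations
  sim2 <- simulate_dataset(n, p0 = 0.05, s = 0, design = d, noise = FALSE)
  loss_obs <- mean(sim2$pop_freq[, 7L] == 0)
  loss_exact <- wf_exact_loss_prob(0.05, ng, 60L)
  expect_equal(loss_obs, loss_exact,
               tolerance = 5 * sqrt(loss_exact * (1 - loss_exact) / n) / loss_exact)
})

test_that("strong selection fixes almost every replicate by generation 60", {
  d <- sim_design(Ne = 300, generations = 60, replicates = 1)
  set.seed(103)
  sim <- simulate_dataset(2000, p0 = 0.5, s = 0.3, design = d, noise = FALSE)
  expect_gte(mean(sim$pop_freq[, 7L] > 0.9), 0.99)
  expect_gte(mean(sim$pop_freq[, 7L] > 0.99), 0.95)
})

test_that("drift is negligible at very large Ne", {
  d <- sim_design(Ne = 1e6, generations = 60, replicates = 2, coverage = 80)
  sim <- simulate_dataset(20, p0 = 0.37, s = 0, design = d, noise = FALSE,
                          seed = 104)
  expect_lt(max(abs(sim$pop_freq - 0.37)), 0.01)
})

test_that("Pool-Seq sampling is unbiased with Poisson-binomial variance", {
  set.seed(105)
  n <- 5e4
  ps <- poolseq_sample(rep(0.5, n), coverage = 80)
  ok <- !is.na(ps$freq)
  expect_equal(mean(ps$freq[ok]), 0.5, tolerance = 0.002)
  expect_equal(var(ps$freq[ok]), mean(1 / ps$coverage[ok]) * 0.25,
               tolerance = 0.05)
  # boundaries are deterministic given coverage > 0
  expect_true(all(poolseq_sample(rep(0, 100), 80)$alt_count == 0))
  p1 <- poolseq_sample(rep(1, 100), 20)
  expect_true(all(p1$freq[!is.na(p1$freq)] == 1))
  # zero coverage marks the sample missing
  set.seed(106)
  lowc <- poolseq_sample(rep(0.5, 2000), coverage = 0.5)
  expect_true(anyNA(lowc$freq))
  expect_true(all(is.na(lowc$freq) == (lowc$coverage == 0)))
  # pool_size stage adds the finite-pool variance component
  set.seed(107)
  pp <- poolseq_sample(rep(0.5, n), coverage = 80, pool_size = 100)
  expect_equal(var(pp$freq, na.rm = TRUE),
               0.25 / 100 + mean(1 / pp$coverage, na.rm = TRUE) * 0.25 * (1 - 1 / 100),
               tolerance = 0.05)
})

test_that("simulated datasets are reproducible and respect the parameter specs", {
  d <- sim_design(Ne = 300, replicates = 3, coverage = 60)
  a <- simulate_dataset(50, p0 = c(0.1, 0.9), s = c(0, 0.3), design = d, seed = 108)
  b <- simulate_dataset(50, p0 = c(0.1, 0.9), s = c(0, 0.3), design = d, seed = 108)
  expect_identical(a, b)
  expect_true(all(a$truth$p0 >= 0.1 & a$truth$p0 <= 0.9))
  expect_true(all(a$truth$s >= 0 & a$truth$s <= 0.3))
  # empty dataset
  e <- simulate_dataset(0, p0 = 0.5, s = 0.1, design = d)
  expect_identical(nrow(e$truth), 0L)
  expect_identical(nrow(e$freq), 0L)
  # neutral expectation of the mean final frequency
  set.seed(109)
  sneut <- simulate_dataset(3000, p0 = 0.25, s = 0, design = d, noise = FALSE)
  expect_equal(mean(sneut$pop_freq[, 7L]), 0.25, tolerance = 0.02)
  # uniform s has mean 0.15 (se ~ 0.012 at 50 loci)
  expect_lt(abs(mean(a$truth$s) - 0.15), 0.05)
})

test_that("locus extraction returns the matching replicate block", {
  d <- sim_design(Ne = 300, replicates = 4, coverage = 50)
  sim <- simulate_dataset(10, p0 = 0.3, s = 0.1, design = d, seed = 110)
  tr <- get_locus(sim, 7)
  expect_s3_class(tr, "sel_traj")
  rows <- 6 * 4 + 1:4
  expect_identical(tr$freq, sim$freq[rows, ])
  expect_identical(tr$cov, sim$cov[rows, ])
})
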