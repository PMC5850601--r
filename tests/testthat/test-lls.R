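test_that("LLS recovers s and p0 exactly from noise-free continuous-model data", {
  tt <- seq(0, 60, 10)
  f <- traj_continuous(0.1, 0.1, tt, "diploid")
  est <- lls_estimate(f, tt, "diploid")
  expect_equal(est$s, 0.1, tolerance = 1e-12)
  expect_equal(est$p0, 0.1, tolerance = 1e-12)
  fh <- traj_continuous(0.3, 0.05, tt, "haploid")
  esth <- lls_estimate(fh, tt, "haploid")
  expect_equal(esth$s, 0.05, tolerance = 1e-12)
})

test_that("LLS agrees with hand-computed OLS on arbitrary points", {
  # three collinear logits: slope 0.1, intercept -2
  est <- lls_estimate(inv_logit(c(-2, -1, 0)), c(0, 10, 20), "haploid")
  expect_equal(est$s, 0.1)
  expect_equal(est$p0, inv_logit(-2))
  # non-collinear data against an independent normal-equations solve
  set.seed(201)
  tt <- c(0, 10, 20, 30, 40)
  f <- inv_logit(-1 + 0.03 * tt + rnorm(5, 0, 0.2))
  o <- ols_slope_intercept(tt, logit(f))
  est <- lls_estimate(f, tt, "diploid")
  expect_equal(est$slope, unname(o["slope"]))
  expect_equal(est$intercept, unname(o["intercept"]))
  expect_equal(est$s, 2 * unname(o["slope"])) # diploid slope is s/2
})

test_that("weighted LLS matches an independent weighted normal-equations solve", {
  set.seed(202)
  tt <- c(0, 10, 20, 30, 40, 50)
  f <- inv_logit(-0.5 + 0.02 * tt + rnorm(6, 0, 0.3))
  w <- c(40, 90, 70, 120, 55, 80)
  o <- ols_slope_intercept(tt, logit(f), w)
  est <- lls_estimate(f, tt, "haploid", weights = w)
  expect_equal(est$slope, unname(o["slope"]))
  expect_equal(est$intercept, unname(o["intercept"]))
})

test_that("LLS handles degenerate inputs", {
  tt <- c(0, 10, 20)
  expect_equal(lls_estimate(rep(0.3, 3), tt)$s, 0) # constant: zero slope
  expect_true(is.na(lls_estimate(c(1, 1, 1), tt)$s)) # monomorphic
  expect_true(is.na(lls_estimate(c(0.5, 1, 1), tt)$s)) # a single interior point
  # two interior points: exact line through them
  est <- lls_estimate(c(0.2, 0.4), c(0, 10), "haploid")
  expect_equal(est$slope, (logit(0.4) - logit(0.2)) / 10)
  # boundary points are dropped, not propagated
  est2 <- lls_estimate(c(0.2, 0.4, 1), c(0, 10, 20), "haploid")
  expect_equal(est2$n_points, 2)
  expect_equal(est2$slope, (logit(0.4) - logit(0.2)) / 10)
})

test_that("bias correction vanishes for weak selection and is exact at its fixed point", {
  tt <- seq(0, 60, 10)
  expect_equal(bias_correct(0, 0.3, tt)$s, 0)
  # weak selection: correction below 1e-4
  for (p0 in c(0.1, 0.5, 0.9)) {
    est <- lls_estimate(wf_traj_det(p0, sel_params(0.001), tt), tt)
    expect_lt(abs(bias_correct(est$s, est$p0, tt)$s - est$s), 1e-4)
  }
  # self-consistency: discrete truth at s = 0.3 is recovered within 1e-3
  f <- wf_traj_det(0.1, sel_params(0.3), tt)
  est <- lls_estimate(f, tt)
  bc <- bias_correct(est$s, est$p0, tt)
  expect_true(bc$applied)
  expect_lt(abs(est$s - 0.3), 0.1) # uncorrected LLS is visibly biased ...
  expect_lt(abs(bc$s - 0.3), 1e-3) # ... and the correction removes it
  # haploid case too
  fh <- wf_traj_det(0.2, sel_params(0.25, ploidy = "haploid"), tt)
  esth <- lls_estimate(fh, tt, "haploid")
  expect_lt(abs(bias_correct(esth$s, esth$p0, tt, "haploid")$s - 0.25), 1e-3)
})

test_that("bias correction is skipped when the deterministic trajectory is uninformative", {
  tt <- seq(0, 60, 10)
  bc <- bias_correct(0.5, 1, tt) # p0 at the boundary: nothing to re-fit
  expect_false(bc$applied)
  expect_equal(bc$s, 0.5)
  bc2 <- bias_correct(NA_real_, 0.5, tt)
  expect_false(bc2$applied)
})
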