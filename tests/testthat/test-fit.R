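test_that("fit_selection recovers parameters exactly from noise-free data", {
  tt <- seq(0, 60, 10)
  f <- traj_continuous(0.1, 0.1, tt, "diploid")
  fit <- fit_selection(sel_traj(f, tt), method = "lls",
                       bias_correction = FALSE)
  expect_s3_class(fit, "sel_fit")
  expect_equal(fit$s, 0.1, tolerance = 1e-10)
  expect_equal(fit$p0, 0.1, tolerance = 1e-10)
  expect_identical(fit$method, "LLS")
  expect_identical(fit$h, 0.5) # assumed, not estimated
})

test_that("automatic switching picks NLS only when curvature demands it", {
  tt <- seq(0, 60, 10)
  # codominant continuous-model data: exactly linear logits, stay with LLS
  f05 <- traj_continuous(0.25, 0.2, tt)
  fit05 <- fit_selection(sel_traj(f05, tt), method = "auto")
  expect_identical(fit05$method, "LLS")
  # recessive data: curvature detected, switch to NLS and recover h
  f0 <- wf_traj_det(0.25, sel_params(0.2, h = 0), tt)
  fit0 <- fit_selection(sel_traj(f0, tt), method = "auto")
  expect_identical(fit0$method, "NLS")
  expect_equal(fit0$s, 0.2, tolerance = 1e-2)
  expect_equal(fit0$h, 0, tolerance = 0.05)
  # p_threshold = 0 disables switching entirely
  fit_thr <- fit_selection(sel_traj(f0, tt), method = "auto", p_threshold = 0)
  expect_identical(fit_thr$method, "LLS")
})

test_that("switching has good specificity and sensitivity on simulated data", {
  d <- std_design()
  sim05 <- simulate_dataset(150, p0 = c(0.05, 0.7), s = c(0.05, 0.3), h = 0.5,
                            design = d, seed = 801)
  ea05 <- estimate_dataset(sim05, method = "auto")
  expect_gt(mean(ea05$method == "LLS"), 0.6) # codominant: mostly LLS
  sim0 <- simulate_dataset(150, p0 = 0.25, s = 0.2, h = 0, design = d,
                           seed = 802)
  ea0 <- estimate_dataset(sim0, method = "auto")
  expect_gt(mean(ea0$method == "NLS"), 0.5) # recessive: mostly NLS
})

test_that("degenerate trajectories yield a flagged no-estimate result", {
  tt <- c(0, 10, 20)
  expect_warning(fit <- fit_selection(sel_traj(rep(1, 3), tt)),
                 "no estimate")
  expect_true(is.na(fit$s))
  expect_identical(fit$flags, "insufficient_data")
})

test_that("model methods are coherent with the fitted parameters", {
  tt <- seq(0, 60, 10)
  f <- traj_continuous(0.2, 0.15, tt)
  fit <- fit_selection(sel_traj(f, tt), method = "lls",
                       bias_correction = FALSE)
  expect_named(coef(fit), c("s", "p0", "h"))
  expect_equal(unname(coef(fit)["s"]), 0.15, tolerance = 1e-10)
  expect_equal(predict(fit), f, tolerance = 1e-10)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-10)
  expect_output(print(fit), "Selection estimate")
  expect_output(print(summary(fit)), "curvature p-value")
  # plot executes without error on a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  # simulate() draws from the fitted parameters under a design
  d <- sim_design(Ne = 300, replicates = 2, coverage = 60)
  sims <- simulate(fit, nsim = 3, seed = 803, design = d)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "sel_traj")
  expect_identical(nrow(sims[[1]]$freq), 2L)
})

test_that("coverage weighting changes the fit as inverse-variance weights would", {
  tt <- seq(0, 40, 10)
  f <- rbind(c(0.2, 0.3, 0.35, 0.5, 0.6))
  cov <- rbind(c(100L, 10L, 10L, 10L, 100L))
  alt <- matrix(as.integer(round(f * cov)), 1)
  tr <- sel_traj(f, tt, alt = alt, cov = cov)
  fw <- fit_selection(tr, method = "lls", weights = "coverage",
                      bias_correction = FALSE)
  fu <- fit_selection(tr, method = "lls", bias_correction = FALSE)
  o <- ols_slope_intercept(tt, logit(f[1, ]), w = as.numeric(cov))
  expect_equal(fw$s, 2 * unname(o["slope"]), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(fw$s, fu$s)))
})

test_that("survival conditioning is triggered for rare alleles in auto mode", {
  d <- sim_design(Ne = 300, replicates = 4, coverage = 100)
  tr <- simulate_locus(0.02, sel_params(0.1), d, noise = TRUE, seed = 804)
  fit <- fit_selection(tr, method = "lls", condition = "auto", design = d,
                       n_condition_sims = 300, seed = 805)
  expect_true("survival_conditioned" %in% fit$flags)
  # common allele: not triggered
  tr2 <- simulate_locus(0.5, sel_params(0.1), d, noise = TRUE, seed = 806)
  fit2 <- fit_selection(tr2, method = "lls", condition = "auto", design = d,
                        n_condition_sims = 300, seed = 807)
  expect_false("survival_conditioned" %in% fit2$flags)
})
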