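#' Relative root-mean-squared error of selection estimates
#'
#' \deqn{\mathrm{rRMSE} = \frac{\sqrt{\frac{1}{n}\sum_i (\hat{s}_i - s_i)^2}}
#'   {\bar{s}},}
#' where \eqn{\bar{s}} is the mean true selection coefficient of the \eqn{n}
#' loci. Being scaled by the mean truth, it captures both bias and variance
#' on a scale comparable across selection strengths.
#'
#' @param estimates estimated selection coefficients.
#' @param truths true selection coefficients (same length).
#' @param na.rm drop loci with a missing estimate (default \code{TRUE}); the
#'   truths of dropped loci do not enter \eqn{\bar{s}} either.
#' @return The rRMSE (non-negative), or \code{NA} if no loci remain.
#' @examples
#' rrmse(c(0.2, 0.1), c(0.1, 0.2)) # 0.1 / 0.15
#' @export
rrmse <- function(estimates, truths, na.rm = TRUE) {
  stopifnot(length(estimates) == length(truths))
  if (na.rm) {
    keep <- is.finite(estimates) & is.finite(truths)
    estimates <- estimates[keep]
    truths <- truths[keep]
  }
  if (!length(truths)) return(NA_real_)
  sbar <- mean(truths)
  if (sbar == 0) stop("mean true selection coefficient is 0; rRMSE undefined")
  sqrt(mean((estimates - truths)^2)) / sbar
}

#' Clip selection estimates to a fixed range
#'
#' Projects estimates onto \eqn{[lo, hi]} (default \eqn{[-0.2, 1]}), the
#' range used when comparing against prior-bounded estimators whose output
#' cannot leave their prior support.
#'
#' @param estimates numeric vector.
#' @param lo,hi range limits.
#' @return Clipped estimates.
#' @export
clip_estimates <- function(estimates, lo = -0.2, hi = 1.0) {
  if (lo > hi) stop("'lo' must not exceed 'hi'")
  pmin(pmax(estimates, lo), hi)
}

#' Binned accuracy map over the (p0, s) parameter space
#'
#' Bins loci into an equal-width grid over starting frequency and selection
#' coefficient and computes the rRMSE of the estimates within each bin,
#' optionally with percentile bootstrap confidence intervals (resampling loci
#' within each bin).
#'
#' @param p0,s true starting frequencies and selection coefficients.
#' @param s_hat estimated selection coefficients (\code{NA} allowed).
#' @param p0_bins,s_bins number of equal-width bins (default 10 x 10).
#' @param p0_range,s_range ranges partitioned by the bins.
#' @param boot bootstrap resamples per bin for confidence intervals (0 =
#'   none).
#' @param conf confidence level of the percentile interval.
#' @return An object of class \code{"accuracy_grid"}: matrices \code{rrmse}
#'   and \code{n} (p0 bins in rows, s bins in columns; \code{NA} for empty
#'   bins or bins with zero mean truth), bin edges, and \code{lo}/\code{hi}
#'   CI matrices when \code{boot > 0}.
#' @export
accuracy_grid <- function(p0, s, s_hat, p0_bins = 10, s_bins = 10,
                          p0_range = c(0, 1), s_range = c(0, 0.3),
                          boot = 0, conf = 0.95) {
  stopifnot(length(p0) == length(s), length(s) == length(s_hat))
  p0_edges <- seq(p0_range[1L], p0_range[2L], length.out = p0_bins + 1L)
  s_edges <- seq(s_range[1L], s_range[2L], length.out = s_bins + 1L)
  bi <- findInterval(p0, p0_edges, rightmost.closed = TRUE, all.inside = TRUE)
  bj <- findInterval(s, s_edges, rightmost.closed = TRUE, all.inside = TRUE)
  rr <- nn <- lo <- hi <- matrix(NA_real_, p0_bins, s_bins)
  alpha <- (1 - conf) / 2
  for (i in seq_len(p0_bins)) for (j in seq_len(s_bins)) {
    k <- which(bi == i & bj == j)
    nn[i, j] <- length(k)
    if (!length(k) || mean(s[k]) == 0) next
    rr[i, j] <- rrmse(s_hat[k], s[k])
    if (boot > 0 && length(k) > 1L) {
      bs <- vapply(seq_len(boot), function(b) {
        kk <- sample(k, length(k), replace = TRUE)
        rrmse(s_hat[kk], s[kk])
      }, numeric(1))
      q <- stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE)
      lo[i, j] <- q[1L]; hi[i, j] <- q[2L]
    }
  }
  structure(list(rrmse = rr, n = nn, p0_edges = p0_edges, s_edges = s_edges,
                 lo = if (boot > 0) lo, hi = if (boot > 0) hi),
            class = "accuracy_grid")
}

#' @export
print.accuracy_grid <- function(x, digits = 3, ...) {
  cat("Accuracy grid:", nrow(x$rrmse), "p0 bins x", ncol(x$rrmse),
      "s bins;", sum(x$n), "loci\n")
  fin <- is.finite(x$rrmse)
  cat("  bins with rRMSE < 0.3:", sum(x$rrmse < 0.3, na.rm = TRUE), "/",
      sum(fin), "\n")
  cat("  median rRMSE:", format(stats::median(x$rrmse[fin]), digits = digits),
      "\n")
  invisible(x)
}

#' Power of the neutrality test over a (s, p0) grid
#'
#' For each combination of selection coefficient and starting frequency,
#' simulates loci under the design, runs the bias-corrected LLS estimator and
#' the parametric-bootstrap neutrality test, and reports the fraction of loci
#' significant at level \code{alpha}.
#'
#' @param design a [sim_design].
#' @param s,p0 vectors of selection coefficients and starting frequencies
#'   (the full grid of combinations is evaluated).
#' @param alpha significance level (default 0.01).
#' @param n_loci simulated loci per grid cell.
#' @param n_sims neutral bootstrap simulations per locus.
#' @param h dominance of the simulated loci.
#' @param seed optional integer seed.
#' @return A data frame with \code{s}, \code{p0}, \code{power} and
#'   \code{n_loci}.
#' @export
power_experiment <- function(design, s, p0, alpha = 0.01, n_loci = 500,
                             n_sims = 1000, h = 0.5, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  grid <- expand.grid(s = s, p0 = p0)
  with_seed(seed, function() {
    grid$power <- vapply(seq_len(nrow(grid)), function(i) {
      sim <- simulate_dataset(n_loci, p0 = grid$p0[i], s = grid$s[i], h = h,
                              design = design)
      sc <- neutrality_scan(sim, n_sims = n_sims)
      # loci without a usable estimate count as not significant
      sum(sc$pvalue < alpha, na.rm = TRUE) / n_loci
    }, numeric(1))
    grid$n_loci <- n_loci
    grid
  })
}

#' Sensitivity of estimation accuracy to one design parameter
#'
#' Varies a single experimental parameter (measurement interval, coverage,
#' total generations, \eqn{N_e} or the number of replicates) around a base
#' design and reports the percent change in rRMSE of bias-corrected LLS
#' estimates for a fixed \code{(p0, s, h)} scenario, relative to the base
#' design.
#'
#' @param base_design the reference [sim_design].
#' @param parameter one of \code{"interval"}, \code{"coverage"},
#'   \code{"generations"}, \code{"Ne"}, \code{"replicates"}.
#' @param values values of the varied parameter.
#' @param p0,s,h the simulated scenario.
#' @param n_loci simulated loci per design point.
#' @param seed optional integer seed.
#' @return A data frame with \code{value}, \code{rrmse} and
#'   \code{pct_change} (percent change relative to the base design, 0 at the
#'   base value).
#' @export
design_sweep <- function(base_design, parameter = c("interval", "coverage",
                                                    "generations", "Ne",
                                                    "replicates"),
                         values, p0, s, h = 0.5, n_loci = 1000, seed = NULL) {
  stopifnot(inherits(base_design, "sim_design"))
  parameter <- match.arg(parameter)
  modify <- function(v) {
    d <- base_design
    switch(parameter,
           interval = sim_design(d$Ne, d$generations, interval = v,
                                 replicates = d$replicates,
                                 coverage = d$coverage,
                                 pool_size = d$pool_size, ploidy = d$ploidy),
           generations = sim_design(d$Ne, v,
                                    interval = diff(d$sampling_times[1:2]),
                                    replicates = d$replicates,
                                    coverage = d$coverage,
                                    pool_size = d$pool_size,
                                    ploidy = d$ploidy),
           coverage = { d$coverage <- v; d },
           Ne = { d$Ne <- as.integer(v); d },
           replicates = { d$replicates <- as.integer(v); d })
  }
  one <- function(d) {
    sim <- simulate_dataset(n_loci, p0 = p0, s = s, h = h, design = d)
    est <- estimate_dataset(sim, method = "lls")
    rrmse(est$s_hat, sim$truth$s)
  }
  with_seed(seed, function() {
    base_rr <- one(base_design)
    rr <- vapply(values, function(v) {
      d <- modify(v)
      if (identical(unclass(d), unclass(base_design))) base_rr else one(d)
    }, numeric(1))
    data.frame(value = values, rrmse = rr,
               pct_change = 100 * (rr - base_rr) / base_rr)
  })
}
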