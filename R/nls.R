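# deterministic discrete trajectory started mid-experiment: p given at
# times[1], iterated forward to the remaining (absolute) times
det_from <- function(p_start, s, h, ploidy, times) {
  rel <- times - times[1L]
  drop(traj_det_batch(p_start, s, h, ploidy, rel))
}

#' Nonlinear least squares (NLS) co-estimation of s and h
#'
#' Fits the discrete deterministic selection trajectory to an observed
#' consensus trajectory by minimising the frequency-scale sum of squared
#' deviations over \code{(s, h)}. The starting frequency is fixed at the
#' first usable consensus value rather than co-estimated; with three or more
#' informative time points this leaves the two selection parameters
#' identifiable. The search is bounded (\code{s} in \eqn{[-0.5, 1.5]},
#' \code{h} in \eqn{[-1, 2]}) and starts from the LLS estimate with
#' \code{h = 0.5}; on non-convergence one random restart inside the bounds is
#' attempted before giving up.
#'
#' @param freq consensus allele frequencies (one per time point, \code{NA} =
#'   dropped).
#' @param times generations aligned with \code{freq}.
#' @param ploidy \code{"diploid"} or \code{"haploid"} (for haploids \code{h}
#'   is not identifiable and is returned as \code{NA}).
#' @param start optional starting values \code{c(s, h)}.
#' @param lower,upper box bounds for \code{c(s, h)}.
#' @return A list with \code{s}, \code{h}, \code{p0} (the fixed starting
#'   frequency), \code{converged}, \code{n_points} and the residual sum of
#'   squares \code{rss}.
#' @examples
#' tt <- seq(0, 60, 10)
#' f <- wf_traj_det(0.1, sel_params(0.1, h = 0), tt)
#' nls_estimate(f, tt)  # recovers s = 0.1, h = 0
#' @export
nls_estimate <- function(freq, times, ploidy = c("diploid", "haploid"),
                         start = NULL, lower = c(-0.5, -1), upper = c(1.5, 2)) {
  ploidy <- match.arg(ploidy)
  stopifnot(length(freq) == length(times))
  times <- as.integer(times)
  ok <- is.finite(freq) & freq > 0 & freq < 1
  res <- list(s = NA_real_, h = NA_real_, p0 = NA_real_, converged = FALSE,
              n_points = sum(ok), rss = NA_real_)
  if (sum(ok) < 3L) return(res)
  ft <- freq[ok]
  tt <- times[ok]
  p0_fix <- ft[1L]
  res$p0 <- p0_fix
  if (stats::var(ft) == 0) { # flat trajectory: s = 0, h unidentifiable
    res$s <- 0; res$converged <- TRUE
    return(res)
  }
  obj <- function(par)
    sum((ft - det_from(p0_fix, par[1L], par[2L], ploidy, tt))^2)
  if (is.null(start)) {
    s0 <- lls_estimate(ft, tt, ploidy)$s
    start <- c(min(max(if (is.finite(s0)) s0 else 0, lower[1L]), upper[1L]), 0.5)
  }
  # frequency-scale SSE is tiny (<< 1); tighten the relative-reduction
  # stopping rule and scale the parameters or L-BFGS-B stops prematurely
  ctrl <- list(factr = 1e3, parscale = c(0.1, 0.5), maxit = 200L)
  run <- function(par0)
    tryCatch(stats::optim(par0, obj, method = "L-BFGS-B",
                          lower = lower, upper = upper, control = ctrl),
             error = function(e) NULL)
  fit <- run(start)
  if (is.null(fit) || fit$convergence != 0) { # one random restart
    fit2 <- run(c(stats::runif(1, lower[1L], upper[1L]),
                  stats::runif(1, lower[2L], upper[2L])))
    if (!is.null(fit2) && (is.null(fit) || fit2$value < fit$value)) fit <- fit2
  }
  if (is.null(fit)) return(res)
  res$s <- fit$par[1L]
  res$h <- if (ploidy == "haploid") NA_real_ else fit$par[2L]
  res$converged <- fit$convergence == 0
  res$rss <- fit$value
  res
}

#' Test for curvature in the logit trajectory (deviation from codominance)
#'
#' Under codominance (\eqn{h = 0.5}) the logit-transformed trajectory is
#' linear in time; dominance or recessivity bends it. This test adds a
#' quadratic term to the linear regression of logit frequencies on
#' generations and returns the two-sided p-value of the quadratic
#' coefficient. It drives the automatic LLS/NLS switching rule in
#' [fit_selection()]: small p-values indicate that the codominant linear
#' model is inadequate and the more flexible NLS fit should be used.
#'
#' @param freq consensus allele frequencies.
#' @param times generations aligned with \code{freq}.
#' @return The p-value, or \code{NA} if fewer than four interior time points
#'   are available (the quadratic model would be saturated).
#' @export
quadratic_term_test <- function(freq, times) {
  stopifnot(length(freq) == length(times))
  ok <- is.finite(freq) & freq > 0 & freq < 1
  if (sum(ok) < 4L) return(NA_real_)
  y <- stats::qlogis(freq[ok])
  t1 <- times[ok]
  fit <- stats::lm(y ~ t1 + I(t1^2))
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  if (!"I(t1^2)" %in% rownames(co)) return(NA_real_) # collinear design
  est <- co["I(t1^2)", "Estimate"]
  # (numerically) zero residual variance: the quadratic model fits exactly,
  # so the p-value degenerates to whether any curvature is present at all
  if (sm$sigma < 1e-8 * max(1, stats::sd(y)))
    return(if (abs(est) < 1e-8) 1 else 0)
  p <- co["I(t1^2)", "Pr(>|t|)"]
  if (!is.finite(p)) p <- 1
  p
}
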