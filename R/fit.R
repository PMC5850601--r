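#' Estimate selection parameters from a replicated trajectory
#'
#' The central fitting function: estimates the selection coefficient
#' \eqn{s} (and, with NLS, the dominance \eqn{h}) of one locus from a
#' replicated allele-frequency time series. The pipeline is
#' \enumerate{
#'   \item consensus construction across replicates with loss masking
#'     ([combine_replicates]);
#'   \item optionally, the survival-conditioning correction for low starting
#'     frequencies ([condition_on_survival]);
#'   \item the curvature test for deviation from codominance
#'     ([quadratic_term_test]);
#'   \item \emph{LLS}: linear regression of logit frequencies on generations
#'     ([lls_estimate]) with the discrete-generation bias correction
#'     ([bias_correct]), assuming \eqn{h = 0.5}; or \emph{NLS}: bounded
#'     nonlinear least squares co-estimating \eqn{(s, h)}
#'     ([nls_estimate]).
#' }
#' With \code{method = "auto"} the NLS fit is used when the curvature
#' p-value falls below \code{p_threshold} (default 0.1), combining the
#' precision of LLS with the robustness of NLS to non-codominant loci; a
#' non-converged NLS falls back to LLS.
#'
#' @param traj a [sel_traj] object (or a numeric matrix, replicates x times,
#'   together with \code{times}).
#' @param times generations, only needed when \code{traj} is a bare matrix.
#' @param ploidy \code{"diploid"} or \code{"haploid"}; a user declaration
#'   (e.g. yeast E&R populations are analysed as haploid).
#' @param method \code{"auto"} (default), \code{"lls"} or \code{"nls"}.
#' @param p_threshold p-value threshold of the curvature test below which NLS
#'   replaces LLS under \code{method = "auto"}.
#' @param bias_correction apply the discrete-generation bias correction to
#'   LLS estimates (default \code{TRUE}; the correction vanishes as
#'   \eqn{\hat{s} \to 0}, so it is applied unconditionally).
#' @param condition survival-conditioning correction: \code{"auto"} applies
#'   it when the starting consensus times the gamete count is below 30 or a
#'   small neutral probe shows more than 1\% allele loss by the final
#'   sampling time, \code{"always"}/\code{"never"} force it. Requires
#'   \code{design}.
#' @param design a [sim_design] of the experiment; required for
#'   \code{condition != "never"}.
#' @param n_condition_sims neutral simulations used by the conditioning
#'   correction.
#' @param weights \code{"none"} (ordinary least squares, default) or
#'   \code{"coverage"} (weight time points by their summed sequencing
#'   coverage, i.e. inverse sampling variance).
#' @param seed optional integer seed for the conditioning simulations.
#' @return An object of class \code{"sel_fit"} with components \code{s},
#'   \code{p0}, \code{h} (0.5 by assumption for LLS), \code{method},
#'   \code{quad_pvalue}, \code{converged}, \code{n_points},
#'   \code{consensus}, and flags; it supports \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{residuals}, \code{plot} and
#'   \code{simulate}.
#' @examples
#' d <- sim_design(Ne = 300, replicates = 6)
#' tr <- simulate_locus(0.2, sel_params(0.1), d, noise = TRUE, seed = 2)
#' fit <- fit_selection(tr)
#' coef(fit)
#' @export
fit_selection <- function(traj, times = NULL,
                          ploidy = c("diploid", "haploid"),
                          method = c("auto", "lls", "nls"),
                          p_threshold = 0.1, bias_correction = TRUE,
                          condition = c("never", "auto", "always"),
                          design = NULL, n_condition_sims = 1000,
                          weights = c("none", "coverage"), seed = NULL) {
  ploidy <- match.arg(ploidy)
  method <- match.arg(method)
  condition <- match.arg(condition)
  weights <- match.arg(weights)
  if (!inherits(traj, "sel_traj")) traj <- sel_traj(traj, times)
  if (condition != "never" && is.null(design))
    stop("'design' is required for the survival-conditioning correction")
  cl <- match.call()
  flags <- character(0)

  cons <- combine_replicates(traj)
  out <- structure(list(s = NA_real_, p0 = NA_real_, h = NA_real_,
                        method = NA_character_, quad_pvalue = NA_real_,
                        converged = NA, n_points = 0L, consensus = cons,
                        traj = traj, ploidy = ploidy, flags = flags,
                        call = cl),
                   class = "sel_fit")
  interior <- sum(cons$freq > 0 & cons$freq < 1)
  if (nrow(cons) < 2L || interior < 2L) {
    out$flags <- "insufficient_data"
    warning("fewer than 2 informative time points; no estimate")
    return(out)
  }

  # survival-conditioning correction
  apply_cond <- FALSE
  if (condition != "never" && cons$time[1L] == 0L && cons$freq[1L] > 0) {
    ng <- n_gametes(design$Ne, design$ploidy)
    if (condition == "always") apply_cond <- TRUE
    else if (cons$freq[1L] * ng < 30) apply_cond <- TRUE
    else {
      probe <- with_seed(seed, function()
        wf_chains_batch(rep(cons$freq[1L], 200L), 0, 0.5, design$ploidy,
                        design$Ne, c(0L, max(design$sampling_times))))
      if (mean(probe[, 2L] == 0) > 0.01) apply_cond <- TRUE
    }
    if (apply_cond) {
      cons <- condition_on_survival(traj, design, n_condition_sims, seed = seed)
      out$consensus <- cons
      flags <- c(flags, "survival_conditioned")
    }
  }

  qp <- quadratic_term_test(cons$freq, cons$time)
  out$quad_pvalue <- qp
  use_nls <- switch(method,
                    lls = FALSE,
                    nls = TRUE,
                    auto = is.finite(qp) && qp < p_threshold)

  w <- NULL
  if (weights == "coverage" && !is.null(traj$cov)) {
    use <- mask_lost(traj$freq)
    wt <- colSums(traj$cov * use, na.rm = TRUE)
    w <- wt[match(cons$time, traj$times)]
  }

  if (use_nls) {
    nf <- nls_estimate(cons$freq, cons$time, ploidy)
    if (nf$converged) {
      out$s <- nf$s; out$h <- nf$h; out$p0 <- nf$p0
      out$method <- "NLS"; out$converged <- TRUE
      out$n_points <- nf$n_points
      out$flags <- flags
      return(out)
    }
    flags <- c(flags, "nls_fallback") # non-convergence: fall back to LLS
  }

  lf <- lls_estimate(cons$freq, cons$time, ploidy, weights = w)
  out$method <- "LLS"
  out$h <- 0.5
  out$p0 <- lf$p0
  out$n_points <- lf$n_points
  out$converged <- is.finite(lf$s)
  if (is.finite(lf$s) && bias_correction) {
    bc <- bias_correct(lf$s, lf$p0, traj$times, ploidy)
    out$s <- bc$s
    if (!bc$applied) flags <- c(flags, "bias_correction_skipped")
  } else out$s <- lf$s
  out$flags <- flags
  out
}

#' @export
print.sel_fit <- function(x, digits = 4, ...) {
  cat("Selection estimate (", x$method, ", ", x$ploidy, ")\n", sep = "")
  cat("  s =", format(x$s, digits = digits),
      "  p0 =", format(x$p0, digits = digits),
      "  h =", format(x$h, digits = digits),
      if (identical(x$method, "LLS")) "(assumed)", "\n")
  invisible(x)
}

#' @export
summary.sel_fit <- function(object, ...) {
  structure(object, class = c("summary.sel_fit", "sel_fit"))
}

#' @export
print.summary.sel_fit <- function(x, digits = 4, ...) {
  print.sel_fit(x, digits = digits)
  cat("  time points used:", x$n_points,
      " curvature p-value:", format(x$quad_pvalue, digits = digits), "\n")
  cat("  converged:", x$converged,
      if (length(x$flags)) paste(" flags:", paste(x$flags, collapse = ", ")),
      "\n")
  cat("  consensus trajectory:\n")
  print(cbind(round(x$consensus, digits)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.sel_fit <- function(object, ...) {
  c(s = object$s, p0 = object$p0, h = object$h)
}

#' Predicted allele-frequency trajectory of a fitted model
#'
#' For an LLS fit the fitted continuous-time (logistic) trajectory is
#' returned; for an NLS fit the fitted discrete deterministic trajectory.
#'
#' @param object a \code{"sel_fit"} object.
#' @param times generations at which to predict (defaults to the observed
#'   sampling times).
#' @param ... unused.
#' @return Numeric vector of predicted frequencies.
#' @export
predict.sel_fit <- function(object, times = object$traj$times, ...) {
  if (!is.finite(object$s)) return(rep(NA_real_, length(times)))
  if (identical(object$method, "NLS")) {
    t0 <- object$consensus$time[which(is.finite(object$consensus$freq) &
                                        object$consensus$freq > 0 &
                                        object$consensus$freq < 1)][1L]
    det_from(object$p0, object$s, object$h, object$ploidy,
             as.integer(c(t0, times[times > t0])))[-1L]
  } else {
    traj_continuous(object$p0, object$s, times, object$ploidy)
  }
}

#' @export
residuals.sel_fit <- function(object, ...) {
  cons <- object$consensus
  cons$freq - predict(object, times = cons$time)
}

#' Plot a fitted selection trajectory
#'
#' Shows per-replicate observed frequencies (grey), the consensus trajectory
#' (points) and the fitted model curve.
#'
#' @param x a \code{"sel_fit"} object.
#' @param ... passed to \code{plot}.
#' @export
plot.sel_fit <- function(x, ...) {
  traj <- x$traj
  graphics::matplot(traj$times, t(traj$freq), type = "l", lty = 1,
                    col = "grey70", ylim = c(0, 1),
                    xlab = "generation", ylab = "allele frequency", ...)
  graphics::points(x$consensus$time, x$consensus$freq, pch = 19)
  if (is.finite(x$s)) {
    tt <- seq(min(traj$times), max(traj$times), length.out = 101)
    graphics::lines(tt, predict(x, times = tt), col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Simulate trajectories from a fitted selection model
#'
#' Draws new replicated Wright-Fisher + Pool-Seq trajectories at the fitted
#' \code{(s, h, p0)} under a given design, e.g. for posterior-predictive
#' style checks.
#'
#' @param object a \code{"sel_fit"} object.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param design a [sim_design]; required.
#' @param ... unused.
#' @return A list of [sel_traj] objects of length \code{nsim}.
#' @export
simulate.sel_fit <- function(object, nsim = 1, seed = NULL, design, ...) {
  stopifnot(is.finite(object$s), inherits(design, "sim_design"))
  h <- if (is.finite(object$h)) object$h else 0.5
  params <- sel_params(object$s, h, ploidy = design$ploidy)
  with_seed(seed, function()
    lapply(seq_len(nsim), function(i)
      simulate_locus(object$p0, params, design, noise = TRUE)))
}
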