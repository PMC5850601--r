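# ---- closed-form (weighted) OLS over batches of consensus trajectories ------
#
# cons: units x T matrix of consensus frequencies (NA = dropped time point);
# points at 0 or 1 carry no logit information and are excluded from the fit.
# Returns slope/intercept of logit(freq) ~ time per unit, plus the derived
# selection-model quantities. w: optional units x T weight matrix.
lls_batch <- function(cons, times, ploidy, w = NULL) {
  U <- nrow(cons)
  T_ <- ncol(cons)
  valid <- is.finite(cons) & cons > 0 & cons < 1
  if (is.null(w)) w <- matrix(1, U, T_) else w <- w * 1
  w[!valid] <- 0
  y <- cons
  y[!valid] <- 0.5 # placeholder, weight 0
  y <- matrix(stats::qlogis(y), U, T_)
  x <- matrix(times, U, T_, byrow = TRUE)
  sw <- rowSums(w)
  sx <- rowSums(w * x)
  sy <- rowSums(w * y)
  sxx <- rowSums(w * x * x)
  sxy <- rowSums(w * x * y)
  den <- sw * sxx - sx * sx
  slope <- (sw * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / sw
  npt <- rowSums(valid)
  bad <- npt < 2L | den <= 0 | !is.finite(slope)
  slope[bad] <- NA_real_
  intercept[bad] <- NA_real_
  list(s = if (ploidy == "haploid") slope else 2 * slope,
       slope = slope, intercept = intercept,
       p0 = stats::plogis(intercept), n_points = npt)
}

#' Linear least squares (LLS) estimate of the selection coefficient
#'
#' Fits an ordinary least squares line to logit-transformed allele
#' frequencies against generations. Under the continuous-time selection model
#' the logit trajectory is exactly linear with slope \eqn{s} (haploid) or
#' \eqn{s/2} (diploid, codominant), so the slope yields the selection
#' coefficient and the intercept the starting frequency
#' \code{p0 = inv_logit(intercept)}. Frequencies at exactly 0 or 1 carry no
#' logit information and are excluded; at least two interior points are
#' required.
#'
#' @param freq consensus allele frequencies (one value per time point;
#'   \code{NA} = dropped).
#' @param times generations, aligned with \code{freq}.
#' @param ploidy \code{"diploid"} or \code{"haploid"}.
#' @param weights optional regression weights (e.g. sequencing coverages, to
#'   down-weight noisier time points).
#' @return A list with \code{s}, \code{p0}, \code{slope}, \code{intercept}
#'   and \code{n_points}; \code{s} is \code{NA} when fewer than two interior
#'   points are available.
#' @examples
#' f <- traj_continuous(0.1, s = 0.1, times = seq(0, 60, 10))
#' lls_estimate(f, seq(0, 60, 10))  # recovers s = 0.1, p0 = 0.1 exactly
#' @export
lls_estimate <- function(freq, times, ploidy = c("diploid", "haploid"),
                         weights = NULL) {
  ploidy <- match.arg(ploidy)
  stopifnot(length(freq) == length(times))
  w <- if (is.null(weights)) NULL else matrix(weights, 1L)
  out <- lls_batch(matrix(freq, 1L), times, ploidy, w)
  lapply(out, drop)
}

# ---- discrete-generation bias correction ------------------------------------
#
# LLS targets the continuous-time model; populations evolving in discrete
# generations drift away from it as s grows, biasing the slope. The corrected
# estimate solves LLS(discrete_trajectory(p0_hat, s)) = s_hat for s by
# fixed-point iteration; the first iterate, s_hat + (s_hat - s_re), is the
# simple additive correction and subsequent iterates remove the residual
# second-order error.
bias_correct_batch <- function(s_hat, p0_hat, times, ploidy, h = 0.5,
                               max_iter = 25L, tol = 1e-8) {
  cur <- s_hat
  active <- is.finite(s_hat) & is.finite(p0_hat) & p0_hat > 0 & p0_hat < 1 &
    s_hat > -0.999
  applied <- active & FALSE
  for (k in seq_len(max_iter)) {
    idx <- which(active)
    if (!length(idx)) break
    det <- traj_det_batch(p0_hat[idx], cur[idx], h, ploidy, times)
    re <- lls_batch(det, times, ploidy)$s
    upd <- is.finite(re)
    new <- s_hat[idx] + (cur[idx] - re)
    ok <- upd & is.finite(new) & new > -0.999
    cur_idx <- cur[idx]
    delta <- abs(new - cur_idx)
    cur_idx[ok] <- new[ok]
    cur[idx] <- cur_idx
    applied[idx[ok]] <- TRUE
    act <- active[idx]
    act[!ok] <- FALSE                # monomorphic / invalid: freeze
    act[ok & delta < tol] <- FALSE   # converged
    active[idx] <- act
  }
  list(s = cur, applied = applied)
}

#' Discrete-generation bias correction of an LLS estimate
#'
#' Corrects the systematic deviation between the continuous-time model
#' underlying LLS and discrete-generation dynamics: a deterministic discrete
#' trajectory is computed from the estimated \code{(p0, s)}, the selection
#' coefficient is re-estimated from it with LLS, and the difference between
#' the input coefficient and its re-estimate is added back. The step is
#' iterated to its fixed point, at which the corrected coefficient's discrete
#' trajectory reproduces the originally estimated slope exactly; the
#' correction vanishes as \eqn{\hat{s} \to 0}. Loci whose deterministic
#' trajectory is monomorphic at (almost) all sampled times are returned
#' uncorrected with \code{applied = FALSE}.
#'
#' @param s_hat,p0_hat LLS estimates (vectorised).
#' @param times sampling generations of the underlying fit.
#' @param ploidy \code{"diploid"} or \code{"haploid"}.
#' @param h dominance assumed for the deterministic trajectory (0.5, the LLS
#'   assumption, by default).
#' @return A list with the corrected \code{s} and a logical \code{applied}.
#' @examples
#' tt <- seq(0, 60, 10)
#' f <- wf_traj_det(0.1, sel_params(0.3), tt)   # discrete truth, s = 0.3
#' est <- lls_estimate(f, tt)                   # biased: ~0.25
#' bias_correct(est$s, est$p0, tt)$s            # ~0.3
#' @export
bias_correct <- function(s_hat, p0_hat, times,
                         ploidy = c("diploid", "haploid"), h = 0.5) {
  ploidy <- match.arg(ploidy)
  out <- bias_correct_batch(s_hat, p0_hat, as.integer(times), ploidy, h)
  out
}
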