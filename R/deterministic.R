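#' Logit and inverse-logit transforms
#'
#' \code{logit(p)} is \eqn{\ln(p / (1 - p))}; \code{inv_logit} is its exact
#' inverse. Under the continuous-time selection model the logit of the
#' selected-allele frequency is linear in time, which is the basis of the LLS
#' estimator.
#'
#' @param p allele frequency strictly inside (0, 1).
#' @param x real number.
#' @return \code{logit}: a real number; \code{inv_logit}: a frequency in (0, 1).
#' @examples
#' logit(0.5)            # 0
#' inv_logit(logit(0.2)) # 0.2
#' @export
logit <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("logit is undefined at 0 and 1; frequencies must lie strictly inside (0, 1)")
  stats::qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

# vectorised deterministic one-generation update; s, h may be vectors
step_det <- function(p, s, h, ploidy) {
  if (ploidy == "haploid") {
    (1 + s) * p / ((1 + s) * p + (1 - p))
  } else {
    wAA <- 1 + s
    wAa <- 1 + h * s
    q <- 1 - p
    (wAA * p^2 + wAa * p * q) / (wAA * p^2 + wAa * 2 * p * q + q^2)
  }
}

#' One generation of deterministic selection
#'
#' Expected allele frequency after one generation of selection in an infinite
#' population: \eqn{p' = w_A p / (w_A p + w_a (1-p))} for haploids and the
#' Hardy-Weinberg genotype-weighted analogue for diploids. The boundaries
#' \code{p = 0} and \code{p = 1} are absorbing.
#'
#' @param p allele frequency (vectorised) in \eqn{[0, 1]}.
#' @param params a [sel_params] object.
#' @return Allele frequency after selection.
#' @examples
#' wf_step(0.5, sel_params(s = 0.1, ploidy = "haploid")) # 0.55/1.05
#' @export
wf_step <- function(p, params) {
  stopifnot(inherits(params, "sel_params"))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("allele frequencies must lie in [0, 1]")
  step_det(p, params$s, params$h, params$ploidy)
}

#' Deterministic allele-frequency trajectory (discrete generations)
#'
#' Iterates [wf_step] over discrete non-overlapping generations and records
#' the frequency at the requested generations.
#'
#' @param p0 starting allele frequency in \eqn{[0, 1]}.
#' @param params a [sel_params] object.
#' @param times non-negative integer generations, starting at 0, strictly
#'   increasing.
#' @return Numeric vector of frequencies aligned with \code{times}.
#' @examples
#' wf_traj_det(0.5, sel_params(0.1, ploidy = "haploid"), times = 0:2)
#' @export
wf_traj_det <- function(p0, params, times) {
  stopifnot(inherits(params, "sel_params"))
  if (any(p0 < 0 | p0 > 1)) stop("'p0' must lie in [0, 1]")
  times <- as.integer(times)
  if (times[1L] < 0L || any(diff(times) <= 0L))
    stop("'times' must be non-negative and strictly increasing")
  drop(traj_det_batch(p0, params$s, params$h, params$ploidy, times))
}

# batch deterministic trajectories: p0, s, h vectors of equal length (recycled),
# returns length(p0) x length(times) matrix
traj_det_batch <- function(p0, s, h, ploidy, times) {
  n <- max(length(p0), length(s), length(h))
  p <- rep_len(p0, n)
  s <- rep_len(s, n)
  h <- rep_len(h, n)
  out <- matrix(NA_real_, n, length(times))
  ti <- 1L
  if (times[1L] == 0L) { out[, 1L] <- p; ti <- 2L }
  if (ti > length(times)) return(out)
  for (t in seq_len(max(times))) {
    p <- step_det(p, s, h, ploidy)
    if (t == times[ti]) {
      out[, ti] <- p
      ti <- ti + 1L
      if (ti > length(times)) break
    }
  }
  out
}

#' Continuous-time (logistic) allele-frequency trajectory
#'
#' Closed-form trajectory of a selected allele under the continuous-time
#' approximation with overlapping generations and weak selection, assuming
#' codominance (\eqn{h = 0.5}) in the diploid case:
#' \deqn{p_t = \frac{1}{1 + \frac{1-p_0}{p_0} e^{-st}}}
#' for haploids, with \eqn{s} replaced by \eqn{s/2} in the exponent for
#' diploids. Equivalently, \code{logit(p_t)} is linear in \code{t} with slope
#' \eqn{s} (haploid) or \eqn{s/2} (diploid) and intercept \code{logit(p0)}.
#'
#' @param p0 starting allele frequency strictly inside (0, 1).
#' @param s selection coefficient.
#' @param times generations (vectorised, need not be integer).
#' @param ploidy \code{"diploid"} or \code{"haploid"}.
#' @return Frequencies aligned with \code{times}.
#' @examples
#' traj_continuous(0.5, 0.1, times = 10, ploidy = "haploid") # 1/(1 + exp(-1))
#' @export
traj_continuous <- function(p0, s, times, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  if (any(p0 <= 0 | p0 >= 1))
    stop("'p0' must lie strictly inside (0, 1) for the continuous model")
  rate <- if (ploidy == "haploid") s else s / 2
  inv_logit(logit(p0) + rate * times)
}
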