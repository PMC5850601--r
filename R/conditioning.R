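# mean neutral consensus per time for a batch of loci: p0 is a vector of
# observed starting frequencies; coverage is redrawn from the design unless a
# per-locus coverage block (L*R x T, replicate fastest) is supplied.
null_consensus_mean <- function(p0, design, n_sims, cov = NULL) {
  L <- length(p0)
  R <- design$replicates
  T_ <- length(design$sampling_times)
  pop <- wf_chains_batch(rep(p0, each = n_sims * R), 0, 0.5,
                         design$ploidy, design$Ne, design$sampling_times)
  cov_chains <- NULL
  if (!is.null(cov)) { # reuse the observed coverage of (locus, replicate)
    u <- rep(seq_len(L), each = n_sims * R)
    r <- rep(rep(seq_len(R), times = n_sims), times = L)
    cov_chains <- cov[(u - 1L) * R + r, , drop = FALSE]
  }
  ns <- pool_noise_batch(pop,
                         lambda = if (is.null(cov)) design$coverage,
                         cov = cov_chains,
                         pool_size = design$pool_size)
  cb <- consensus_batch(ns$freq, R) # (L * n_sims) x T consensus
  cons <- cb$freq
  avail <- is.finite(cons)
  cons[!avail] <- 0
  dim(cons) <- c(n_sims, L * T_)
  dim(avail) <- c(n_sims, L * T_)
  m <- .colSums(cons, n_sims, L * T_) / .colSums(avail, n_sims, L * T_)
  matrix(m, L, T_)
}

#' Correct a consensus trajectory for conditioning on allele survival
#'
#' When the starting allele frequency is low relative to \eqn{N_e}, many
#' replicates lose the allele; excluding lost replicates conditions the
#' consensus on survival, which inflates it upwards even under neutrality.
#' This correction simulates neutral replicates from the observed starting
#' frequency under the same design, builds their consensus with the identical
#' loss-masking rule, and subtracts the per-time-point mean neutral excess
#' (conditioned neutral consensus minus \eqn{p_0}) from the observed
#' consensus; the result is clipped to \eqn{[0, 1]}.
#'
#' @param traj a [sel_traj] object.
#' @param design a [sim_design] describing the experiment (supplies
#'   \eqn{N_e}, replicates, sampling times and the coverage model).
#' @param n_sims number of neutral simulations (default 1000).
#' @param seed optional integer seed.
#' @return A data frame like [combine_replicates()]'s, with an additional
#'   column \code{excess} holding the subtracted neutral excess.
#' @export
condition_on_survival <- function(traj, design, n_sims = 1000, seed = NULL) {
  stopifnot(inherits(traj, "sel_traj"), inherits(design, "sim_design"))
  cons <- combine_replicates(traj)
  if (!nrow(cons) || cons$time[1L] != 0L || cons$freq[1L] <= 0)
    stop("observed starting consensus frequency is 0 or missing; cannot condition")
  p0 <- cons$freq[1L]
  with_seed(seed, function() {
    nm <- null_consensus_mean(p0, design, n_sims,
                              cov = if (!is.null(traj$cov)) traj$cov)
    excess <- drop(nm) - p0
    idx <- match(cons$time, design$sampling_times)
    ex <- ifelse(is.finite(excess[idx]), excess[idx], 0)
    cons$freq <- pmin(pmax(cons$freq - ex, 0), 1)
    cons$excess <- ex
    cons
  })
}
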