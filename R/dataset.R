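#' Estimate selection coefficients for every locus of a simulated dataset
#'
#' Vectorised estimation across all loci of a [simulate_dataset()] result.
#' \code{method = "lls"} runs the closed-form logit regression (with optional
#' bias correction) in one batch; \code{"nls"} and \code{"auto"} run the
#' per-locus nonlinear machinery of [fit_selection()].
#'
#' @param sim a \code{"sel_sim"} object.
#' @param method \code{"lls"} (default), \code{"nls"} or \code{"auto"}.
#' @param bias_correction apply the discrete-generation bias correction
#'   (LLS-based estimates).
#' @param p_threshold curvature-test threshold for \code{method = "auto"}.
#' @return A data frame with one row per locus: \code{locus}, \code{s_hat},
#'   \code{p0_hat}, \code{h_hat}, \code{method}, \code{n_points} and, for
#'   \code{"auto"}, \code{quad_pvalue}.
#' @examples
#' d <- sim_design(Ne = 300, replicates = 6)
#' sim <- simulate_dataset(20, p0 = 0.2, s = 0.1, design = d, seed = 5)
#' head(estimate_dataset(sim))
#' @export
estimate_dataset <- function(sim, method = c("lls", "nls", "auto"),
                             bias_correction = TRUE, p_threshold = 0.1) {
  stopifnot(inherits(sim, "sel_sim"))
  method <- match.arg(method)
  design <- sim$design
  R <- design$replicates
  L <- nrow(sim$truth)
  tt <- design$sampling_times
  cb <- consensus_batch(sim$freq, R)

  if (method == "lls") {
    est <- lls_batch(cb$freq, tt, design$ploidy)
    s <- est$s
    if (bias_correction)
      s <- bias_correct_batch(s, est$p0, tt, design$ploidy)$s
    return(data.frame(locus = seq_len(L), s_hat = s, p0_hat = est$p0,
                      h_hat = 0.5, method = "LLS", n_points = est$n_points))
  }

  lls0 <- lls_batch(cb$freq, tt, design$ploidy)
  rows <- lapply(seq_len(L), function(i) {
    f <- cb$freq[i, ]
    qp <- if (method == "auto") quadratic_term_test(f, tt) else NA_real_
    use_nls <- method == "nls" || (is.finite(qp) && qp < p_threshold)
    if (use_nls) {
      st <- if (is.finite(lls0$s[i]))
        c(min(max(lls0$s[i], -0.5), 1.5), 0.5) else NULL
      nf <- nls_estimate(f, tt, design$ploidy, start = st)
      if (nf$converged)
        return(data.frame(locus = i, s_hat = nf$s, p0_hat = nf$p0,
                          h_hat = nf$h, method = "NLS",
                          n_points = nf$n_points, quad_pvalue = qp))
    }
    s <- lls0$s[i]
    if (is.finite(s) && bias_correction)
      s <- bias_correct_batch(s, lls0$p0[i], tt, design$ploidy)$s
    data.frame(locus = i, s_hat = s, p0_hat = lls0$p0[i], h_hat = 0.5,
               method = "LLS", n_points = lls0$n_points[i], quad_pvalue = qp)
  })
  do.call(rbind, rows)
}

#' Neutrality p-values for every locus of a simulated dataset
#'
#' Runs the parametric-bootstrap neutrality test ([neutrality_test]) over all
#' loci of a [simulate_dataset()] result, sharing the vectorised null engine
#' across loci in batches. Null simulations are matched per locus to the
#' observed starting consensus frequency and reuse the locus's observed
#' coverages.
#'
#' @param sim a \code{"sel_sim"} object.
#' @param estimates optional data frame from [estimate_dataset()] (computed
#'   with bias-corrected LLS if missing).
#' @param n_sims neutral simulations per locus (default 1000).
#' @param bias_correction apply the bias correction in the null pipeline.
#' @param pseudo_count use the add-one p-value (see [neutrality_test]).
#' @param batch_size loci per internal batch (memory/speed trade-off).
#' @param seed optional integer seed.
#' @return A data frame with \code{locus}, \code{s_hat} and \code{pvalue}
#'   (\code{NA} where no estimate or no valid null was available).
#' @export
neutrality_scan <- function(sim, estimates = NULL, n_sims = 1000,
                            bias_correction = TRUE, pseudo_count = TRUE,
                            batch_size = 200, seed = NULL) {
  stopifnot(inherits(sim, "sel_sim"))
  design <- sim$design
  R <- design$replicates
  L <- nrow(sim$truth)
  if (is.null(estimates))
    estimates <- estimate_dataset(sim, method = "lls",
                                  bias_correction = bias_correction)
  cb <- consensus_batch(sim$freq, R)
  p0 <- cb$freq[, 1L] # observed starting consensus (NA if all replicates 0)
  s_obs <- estimates$s_hat
  pv <- rep(NA_real_, L)
  with_seed(seed, function() {
    for (start in seq(1L, L, by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, L)
      ok <- idx[is.finite(p0[idx]) & p0[idx] > 0 & p0[idx] < 1 &
                  is.finite(s_obs[idx])]
      if (!length(ok)) next
      cov_blk <- NULL
      if (!is.null(sim$cov)) {
        rows <- rep((ok - 1L) * R, each = R) + seq_len(R)
        cov_blk <- sim$cov[rows, , drop = FALSE]
      }
      s_null <- null_s_batch(p0[ok], design, n_sims, cov = cov_blk,
                             bias_correction = bias_correction)
      pv[ok] <<- pval_from_null(s_obs[ok], s_null, pseudo_count)
    }
  })
  data.frame(locus = seq_len(L), s_hat = s_obs, pvalue = pv)
}
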