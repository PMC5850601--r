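# shared engine: null distribution of LLS selection estimates for a batch of
# loci. p0: vector (length L) of observed starting consensus frequencies;
# cov: optional (L*R) x T observed coverage block (replicate fastest),
# reused for every null simulation of the corresponding locus.
# Returns an L x n_sims matrix of null s estimates (NA = estimation failed).
null_s_batch <- function(p0, design, n_sims, cov = NULL,
                         bias_correction = TRUE) {
  L <- length(p0)
  R <- design$replicates
  pop <- wf_chains_batch(rep(p0, each = n_sims * R), 0, 0.5,
                         design$ploidy, design$Ne, design$sampling_times)
  cov_chains <- NULL
  if (!is.null(cov)) {
    u <- rep(seq_len(L), each = n_sims * R)
    r <- rep(rep(seq_len(R), times = n_sims), times = L)
    cov_chains <- cov[(u - 1L) * R + r, , drop = FALSE]
  }
  ns <- pool_noise_batch(pop,
                         lambda = if (is.null(cov)) design$coverage,
                         cov = cov_chains, pool_size = design$pool_size)
  cb <- consensus_batch(ns$freq, R)
  est <- lls_batch(cb$freq, design$sampling_times, design$ploidy)
  s <- est$s
  if (bias_correction)
    s <- bias_correct_batch(s, est$p0, design$sampling_times, design$ploidy)$s
  matrix(s, n_sims, L) |> t()
}

# one-sided bootstrap p-values: fraction of null estimates at least as large
pval_from_null <- function(s_obs, s_null, pseudo_count = TRUE,
                           alternative = "greater") {
  vapply(seq_along(s_obs), function(i) {
    if (!is.finite(s_obs[i])) return(NA_real_)
    sn <- s_null[i, ]
    sn <- sn[is.finite(sn)]
    if (!length(sn)) return(NA_real_)
    hits <- if (alternative == "greater") sum(sn >= s_obs[i])
            else sum(abs(sn) >= abs(s_obs[i]))
    if (pseudo_count) (1 + hits) / (1 + length(sn)) else hits / length(sn)
  }, numeric(1))
}

#' Parametric-bootstrap test of neutrality
#'
#' Tests the null hypothesis that an observed selection-coefficient estimate
#' arose from random genetic drift alone. Neutral (\eqn{s = 0}) datasets are
#' simulated under the same design, matched to the locus in starting
#' frequency (the observed starting consensus) and sequencing coverage (the
#' observed coverages are reused), and \eqn{s} is estimated on each with the
#' same LLS pipeline. The p-value is the fraction of null estimates at least
#' as large as the observed one (one-sided, for positive selection), with an
#' add-one pseudo-count by default so that p is never exactly 0.
#'
#' @param traj a [sel_traj] object.
#' @param design a [sim_design] (supplies \eqn{N_e}, replicates, sampling
#'   times and the coverage model for the null simulations).
#' @param observed_s the selection estimate under test; computed with the
#'   bias-corrected LLS pipeline from \code{traj} if missing.
#' @param n_sims number of neutral simulations (default 1000; fewer than 100
#'   gives a coarse p-value and triggers a warning).
#' @param bias_correction apply the discrete-generation bias correction in
#'   the null pipeline (should match how \code{observed_s} was obtained).
#' @param pseudo_count use \eqn{(1 + k)/(1 + n)} instead of the plain
#'   fraction \eqn{k/n}.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}
#'   (compares absolute estimates).
#' @param seed optional integer seed.
#' @return An object of class \code{"sel_test"} with \code{statistic} (the
#'   observed estimate), \code{pvalue} and \code{n_null_sims}.
#' @examples
#' d <- sim_design(Ne = 300, replicates = 6)
#' tr <- simulate_locus(0.2, sel_params(0.1), d, noise = TRUE, seed = 3)
#' neutrality_test(tr, d, n_sims = 200, seed = 4)
#' @export
neutrality_test <- function(traj, design, observed_s = NULL, n_sims = 1000,
                            bias_correction = TRUE, pseudo_count = TRUE,
                            alternative = c("greater", "two.sided"),
                            seed = NULL) {
  stopifnot(inherits(traj, "sel_traj"), inherits(design, "sim_design"))
  alternative <- match.arg(alternative)
  if (n_sims < 100) warning("n_sims < 100 gives a very coarse p-value")
  if (is.null(observed_s))
    observed_s <- suppressWarnings(
      fit_selection(traj, ploidy = design$ploidy, method = "lls",
                    bias_correction = bias_correction))$s
  cons <- combine_replicates(traj)
  p0 <- if (nrow(cons) && cons$time[1L] == 0L) cons$freq[1L] else NA_real_
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1 || !is.finite(observed_s))
    return(structure(list(statistic = observed_s, pvalue = NA_real_,
                          n_null_sims = 0L, alternative = alternative),
                     class = "sel_test"))
  s_null <- with_seed(seed, function()
    null_s_batch(p0, design, n_sims, cov = traj$cov,
                 bias_correction = bias_correction))
  pv <- pval_from_null(observed_s, s_null, pseudo_count, alternative)
  structure(list(statistic = observed_s, pvalue = pv,
                 n_null_sims = sum(is.finite(s_null)),
                 alternative = alternative),
            class = "sel_test")
}

#' @export
print.sel_test <- function(x, digits = 4, ...) {
  cat("Test result\n  statistic =", format(x$statistic, digits = digits),
      "  p-value =", format(x$pvalue, digits = digits), "\n")
  if (!is.null(x$n_null_sims) && x$n_null_sims > 0)
    cat("  null simulations:", x$n_null_sims, "\n")
  invisible(x)
}

#' Chi-squared test for allele-frequency change between two time points
#'
#' Pearson's chi-squared test (1 df, no continuity correction) on the 2x2
#' table of allele counts at two time points.
#'
#' @param counts_t0,counts_t1 length-2 integer vectors \code{c(A, a)} of
#'   allele counts at the two time points.
#' @return A \code{"sel_test"} object; \code{pvalue} is \code{NA} when a
#'   marginal of the table is zero.
#' @examples
#' chisq_test_counts(c(20, 10), c(10, 20))
#' @export
chisq_test_counts <- function(counts_t0, counts_t1) {
  stopifnot(length(counts_t0) == 2L, length(counts_t1) == 2L)
  tab <- rbind(counts_t0, counts_t1)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(structure(list(statistic = NA_real_, pvalue = NA_real_),
                     class = "sel_test"))
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), pvalue = ct$p.value,
                 df = unname(ct$parameter)),
            class = "sel_test")
}

#' Cochran-Mantel-Haenszel test across replicates
#'
#' CMH test (1 df) of allele-frequency change with replicates as strata. The
#' conventional 0.5 continuity correction is applied by default and can be
#' switched off.
#'
#' @param tables a list of 2x2 allele-count tables (rows = time points,
#'   columns = alleles), one per replicate, or a 2x2xK array.
#' @param continuity apply the continuity correction (default \code{TRUE}).
#' @return A \code{"sel_test"} object; \code{pvalue} is \code{NA} when all
#'   strata are degenerate.
#' @examples
#' cmh_test_counts(list(rbind(c(20, 10), c(10, 20)),
#'                      rbind(c(18, 12), c(9, 21))))
#' @export
cmh_test_counts <- function(tables, continuity = TRUE) {
  if (is.list(tables))
    tables <- array(unlist(tables), dim = c(2L, 2L, length(tables)))
  stopifnot(length(dim(tables)) == 3L, all(dim(tables)[1:2] == 2L))
  res <- if (dim(tables)[3L] == 1L) # one stratum: plain chi-squared test
    tryCatch(stats::chisq.test(tables[, , 1L], correct = continuity),
             error = function(e) NULL)
  else
    tryCatch(stats::mantelhaen.test(tables, correct = continuity),
             error = function(e) NULL)
  if (is.null(res))
    return(structure(list(statistic = NA_real_, pvalue = NA_real_),
                     class = "sel_test"))
  structure(list(statistic = unname(res$statistic), pvalue = res$p.value,
                 df = unname(res$parameter)),
            class = "sel_test")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' \code{\link[stats]{p.adjust}(method = "BH")}.
#'
#' @param pvalues numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Positional support filter for outlier SNPs
#'
#' Retains only those outlier SNPs that are supported by at least one other
#' outlier SNP within \code{window} base pairs on the same chromosome,
#' removing isolated (likely spurious) hits.
#'
#' @param chrom chromosome of each SNP.
#' @param pos 1-based position of each SNP.
#' @param is_outlier logical; which SNPs are outliers before filtering.
#' @param window supporting-neighbour window in bp (default 1000).
#' @return Logical vector: \code{TRUE} for outliers that are retained.
#' @export
neighbor_support_filter <- function(chrom, pos, is_outlier, window = 1000) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(is_outlier))
  keep <- rep(FALSE, length(pos))
  idx <- which(is_outlier)
  for (ch in unique(chrom[idx])) {
    i <- idx[chrom[idx] == ch]
    if (length(i) < 2L) next
    p <- sort(pos[i])
    supported <- (c(diff(p), Inf) <= window) | (c(Inf, diff(p)) <= window)
    keep[i[match(pos[i], p)]] <- supported[match(pos[i], p)]
  }
  keep
}
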