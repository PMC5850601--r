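# ---- vectorised Wright-Fisher engine ----------------------------------------
#
# All simulation entry points funnel into wf_chains_batch(), which advances
# many independent chains (loci x replicates x bootstrap draws) in lock-step:
# one deterministic selection update followed by one binomial resampling of
# the gamete pool per generation. This keeps genome-scale simulation and the
# parametric bootstrap affordable in plain R.

# p0, s, h: vectors (recycled to a common length n); returns n x length(times)
wf_chains_batch <- function(p0, s, h, ploidy, Ne, times) {
  n <- max(length(p0), length(s), length(h))
  p <- rep_len(as.numeric(p0), n)
  s <- rep_len(as.numeric(s), n)
  h <- rep_len(as.numeric(h), n)
  ng <- n_gametes(Ne, ploidy)
  neutral <- all(s == 0)
  out <- matrix(NA_real_, n, length(times))
  ti <- 1L
  if (times[1L] == 0L) { out[, 1L] <- p; ti <- 2L }
  if (ti > length(times)) return(out)
  for (t in seq_len(max(times))) {
    if (!neutral) p <- step_det(p, s, h, ploidy)
    p <- stats::rbinom(n, ng, p) / ng
    if (t == times[ti]) {
      out[, ti] <- p
      ti <- ti + 1L
      if (ti > length(times)) break
    }
  }
  out
}

# Pool-Seq noise for a matrix of population frequencies. Coverage is drawn
# from Poisson(lambda) unless a coverage matrix is supplied (reused, e.g. in
# the parametric bootstrap). Zero-coverage samples are missing (NA frequency).
pool_noise_batch <- function(freq, lambda = NULL, cov = NULL, pool_size = NULL) {
  n <- length(freq)
  if (is.null(cov)) cov <- array(stats::rpois(n, lambda), dim(freq))
  pf <- freq
  if (!is.null(pool_size))
    pf <- array(stats::rbinom(n, pool_size, freq) / pool_size, dim(freq))
  alt <- array(stats::rbinom(n, cov, pf), dim(freq))
  fhat <- alt / cov
  fhat[cov == 0L] <- NA_real_
  list(alt = alt, cov = cov, freq = fhat)
}

# run fn with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fn()
}

# ---- public simulator --------------------------------------------------------

#' One generation of Wright-Fisher reproduction with selection
#'
#' Applies deterministic selection ([wf_step]) and then resamples the gamete
#' pool binomially: the new frequency is \eqn{X / n_g} with
#' \eqn{X \sim \mathrm{Binomial}(n_g, p')}, where \eqn{n_g} is \code{Ne}
#' allele copies for haploids and \code{2 Ne} for diploids. 0 and 1 are
#' absorbing.
#'
#' @param p allele frequency (vectorised).
#' @param params a [sel_params] object.
#' @param Ne effective population size.
#' @return Allele frequency in the next generation.
#' @export
wf_generation <- function(p, params, Ne) {
  stopifnot(inherits(params, "sel_params"), Ne >= 1)
  ng <- n_gametes(Ne, params$ploidy)
  stats::rbinom(length(p), ng, wf_step(p, params)) / ng
}

#' Pool-Seq sampling of an allele frequency
#'
#' Mimics pooled sequencing: coverage is drawn from a Poisson distribution
#' with mean \code{coverage}, then the focal-allele read count is drawn
#' binomially at the (pool) allele frequency. If \code{pool_size} is given, an
#' intermediate pool frequency is first drawn as
#' \eqn{\mathrm{Binomial}(\mathrm{pool\_size}, p)/\mathrm{pool\_size}},
#' modelling the finite number of pooled individuals. Samples whose drawn
#' coverage is 0 are marked missing.
#'
#' @param p population allele frequency (vectorised).
#' @param coverage mean sequencing coverage (Poisson mean).
#' @param pool_size optional number of pooled allele copies.
#' @return A data frame with columns \code{coverage}, \code{alt_count} and
#'   \code{freq} (\code{NA} when coverage is 0).
#' @examples
#' set.seed(1)
#' poolseq_sample(rep(0.5, 3), coverage = 80)
#' @export
poolseq_sample <- function(p, coverage, pool_size = NULL) {
  stopifnot(coverage > 0, all(p >= 0 & p <= 1))
  ns <- pool_noise_batch(matrix(p, length(p), 1L), lambda = coverage,
                         pool_size = pool_size)
  data.frame(coverage = as.integer(ns$cov), alt_count = as.integer(ns$alt),
             freq = as.numeric(ns$freq))
}

#' Simulate the trajectory of one locus
#'
#' Simulates independent replicate Wright-Fisher populations from a common
#' starting frequency under a shared experimental design, recording population
#' allele frequencies at the design's sampling times and, optionally, adding
#' Pool-Seq sequencing noise.
#'
#' @param p0 starting allele frequency.
#' @param params a [sel_params] object (its ploidy must match the design's).
#' @param design a [sim_design] object.
#' @param noise if \code{TRUE}, return Pool-Seq observations (counts and
#'   observed frequencies); if \code{FALSE} (default), return the true
#'   population frequencies.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return A [sel_traj] object.
#' @examples
#' d <- sim_design(Ne = 300, replicates = 6)
#' simulate_locus(0.1, sel_params(0.1), d, seed = 1)
#' @export
simulate_locus <- function(p0, params, design, noise = FALSE, seed = NULL) {
  stopifnot(inherits(params, "sel_params"), inherits(design, "sim_design"))
  if (params$ploidy != design$ploidy)
    stop("ploidy of 'params' and 'design' differ")
  with_seed(seed, function() {
    f <- wf_chains_batch(rep(p0, design$replicates), params$s, params$h,
                         design$ploidy, design$Ne, design$sampling_times)
    if (!noise) return(sel_traj(f, design$sampling_times))
    ns <- pool_noise_batch(f, lambda = design$coverage,
                           pool_size = design$pool_size)
    sel_traj(ns$freq, design$sampling_times, alt = ns$alt, cov = ns$cov)
  })
}

#' Simulate a dataset of unlinked loci
#'
#' Simulates \code{n_loci} independent loci under a common design, drawing
#' per-locus starting frequencies and selection coefficients from fixed
#' values or uniform ranges, and recording both the simulated truth and the
#' Pool-Seq observations. This is the workhorse behind all power and accuracy
#' experiments.
#'
#' @param n_loci number of loci.
#' @param p0,s either a single fixed value, a length-2 numeric \code{c(lo,
#'   hi)} interpreted as a uniform range, or a vector of length \code{n_loci}.
#' @param h dominance parameter (single value, shared by all loci).
#' @param design a [sim_design] object.
#' @param noise add Pool-Seq noise (default \code{TRUE}).
#' @param seed optional integer seed.
#' @return An object of class \code{"sel_sim"}: a list with the \code{design},
#'   a \code{truth} data frame (\code{locus}, \code{p0}, \code{s}, \code{h}),
#'   and chains-by-times matrices \code{freq} (observed frequencies),
#'   \code{alt}, \code{cov} and \code{pop_freq} (true population frequencies);
#'   chain rows are ordered with the replicate index fastest. Use
#'   [get_locus()] to extract a single locus as a [sel_traj].
#' @examples
#' d <- sim_design(Ne = 300, replicates = 2, coverage = 60)
#' sim <- simulate_dataset(5, p0 = c(0.1, 0.9), s = 0.1, design = d, seed = 1)
#' get_locus(sim, 3)
#' @export
simulate_dataset <- function(n_loci, p0, s, h = 0.5, design, noise = TRUE,
                             seed = NULL) {
  stopifnot(inherits(design, "sim_design"), n_loci >= 0)
  with_seed(seed, function() {
    draw <- function(x, what) {
      if (length(x) == 1L) rep(x, n_loci)
      else if (length(x) == 2L) stats::runif(n_loci, x[1L], x[2L])
      else if (length(x) == n_loci) as.numeric(x)
      else stop("'", what, "' must be a value, a range c(lo, hi), or length n_loci")
    }
    p0_i <- draw(p0, "p0")
    s_i <- draw(s, "s")
    R <- design$replicates
    pop <- if (n_loci > 0)
      wf_chains_batch(rep(p0_i, each = R), rep(s_i, each = R), h,
                      design$ploidy, design$Ne, design$sampling_times)
    else matrix(NA_real_, 0L, length(design$sampling_times))
    obs <- if (noise && n_loci > 0)
      pool_noise_batch(pop, lambda = design$coverage,
                       pool_size = design$pool_size)
    else list(freq = pop, alt = NULL, cov = NULL)
    structure(list(design = design,
                   truth = data.frame(locus = seq_len(n_loci), p0 = p0_i,
                                      s = s_i, h = rep(h, n_loci)),
                   freq = obs$freq, alt = obs$alt, cov = obs$cov,
                   pop_freq = pop),
              class = "sel_sim")
  })
}

#' @export
print.sel_sim <- function(x, ...) {
  cat("Simulated Pool-Seq dataset:", nrow(x$truth), "loci,",
      x$design$replicates, "replicate(s),",
      length(x$design$sampling_times), "time points\n")
  cat("  Ne =", x$design$Ne, " ploidy =", x$design$ploidy,
      " mean coverage =", x$design$coverage, "\n")
  invisible(x)
}

#' Extract one locus from a simulated dataset
#'
#' @param sim a \code{"sel_sim"} object from [simulate_dataset()].
#' @param i locus index.
#' @return A [sel_traj] object.
#' @export
get_locus <- function(sim, i) {
  stopifnot(inherits(sim, "sel_sim"), i >= 1, i <= nrow(sim$truth))
  R <- sim$design$replicates
  rows <- (i - 1L) * R + seq_len(R)
  sel_traj(sim$freq[rows, , drop = FALSE], sim$design$sampling_times,
           alt = sim$alt[rows, , drop = FALSE],
           cov = sim$cov[rows, , drop = FALSE])
}
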