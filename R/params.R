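#' Selection parameters of a single locus
#'
#' Bundles the selection coefficient \code{s}, the dominance parameter
#' \code{h} and the ploidy of the population into a validated object used by
#' the deterministic model and the Wright-Fisher simulator.
#'
#' Relative fitnesses are \eqn{w_A = 1 + s}, \eqn{w_a = 1} for haploids and
#' \eqn{w_{AA} = 1 + s}, \eqn{w_{Aa} = 1 + hs}, \eqn{w_{aa} = 1} for diploids.
#' \code{h = 0.5} is codominance, \code{h = 0} recessive, \code{h = 1}
#' dominant. Values of \code{h} outside \eqn{[0, 1]} (over-/underdominance)
#' are accepted with a warning; they are outside the range for which the
#' estimators have been validated.
#'
#' @param s selection coefficient per generation; must exceed -1 so that all
#'   fitnesses stay positive.
#' @param h dominance parameter; ignored for haploids.
#' @param ploidy \code{"diploid"} or \code{"haploid"}.
#' @return An object of class \code{"sel_params"}.
#' @examples
#' sel_params(s = 0.1, h = 0.5)
#' sel_params(s = 0.05, ploidy = "haploid")
#' @export
sel_params <- function(s, h = 0.5, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s))
  if (s <= -1)
    stop("'s' must be > -1 (relative fitness 1 + s must be positive)")
  stopifnot(is.numeric(h), length(h) == 1L, is.finite(h))
  if (ploidy == "diploid" && (h < 0 || h > 1))
    warning("'h' outside [0, 1]: over-/underdominance is accepted but untested")
  structure(list(s = s, h = h, ploidy = ploidy), class = "sel_params")
}

#' @export
print.sel_params <- function(x, ...) {
  cat("Selection parameters (", x$ploidy, ")\n", sep = "")
  cat("  s =", format(x$s), if (x$ploidy == "diploid") paste("  h =", format(x$h)), "\n")
  invisible(x)
}

#' Experimental design of a Pool-Seq time series
#'
#' Describes a (possibly replicated) Wright-Fisher + Pool-Seq experiment:
#' effective population size, duration, allele-frequency measurement times,
#' number of replicate populations and the sequencing-noise model.
#'
#' @param Ne effective population size (individuals).
#' @param generations total number of generations simulated.
#' @param interval measurement interval in generations; ignored when
#'   \code{sampling_times} is given. The default of 10 matches typical E&R
#'   designs where allele frequencies are sequenced every ten generations.
#' @param sampling_times generations at which allele frequencies are
#'   observed; must start at 0. Default \code{seq(0, generations, interval)}.
#' @param replicates number of independently evolving replicate populations.
#' @param coverage mean Pool-Seq sequencing coverage; per-sample coverage is
#'   drawn from a Poisson distribution with this mean.
#' @param pool_size optional number of individuals pooled for sequencing; when
#'   given, an intermediate pool allele frequency is drawn before read
#'   sampling. \code{NULL} (default) draws reads directly from the population
#'   frequency.
#' @param ploidy \code{"diploid"} or \code{"haploid"}; determines the number
#'   of allele copies (gametes) resampled each generation: \code{2 * Ne} for
#'   diploids, \code{Ne} for haploids.
#' @return An object of class \code{"sim_design"}.
#' @examples
#' # a standard E&R design: 6 replicates, Ne = 300, 60 generations at 80x
#' sim_design(Ne = 300, generations = 60, replicates = 6, coverage = 80)
#' @export
sim_design <- function(Ne = 300, generations = 60, interval = 10,
                       sampling_times = NULL, replicates = 1,
                       coverage = 80, pool_size = NULL,
                       ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(Ne >= 1, generations >= 1, replicates >= 1, coverage > 0)
  if (is.null(sampling_times))
    sampling_times <- seq(0L, as.integer(generations), by = as.integer(interval))
  sampling_times <- as.integer(sampling_times)
  if (sampling_times[1L] != 0L || any(diff(sampling_times) <= 0L) ||
      max(sampling_times) > generations)
    stop("'sampling_times' must start at 0, be strictly increasing and not exceed 'generations'")
  if (!is.null(pool_size)) stopifnot(pool_size >= 1)
  structure(list(Ne = as.integer(Ne), generations = as.integer(generations),
                 sampling_times = sampling_times,
                 replicates = as.integer(replicates),
                 coverage = coverage, pool_size = pool_size, ploidy = ploidy),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Pool-Seq time series design (", x$ploidy, ")\n", sep = "")
  cat("  Ne =", x$Ne, " generations =", x$generations,
      " replicates =", x$replicates, "\n")
  cat("  sampling times:", paste(x$sampling_times, collapse = ", "), "\n")
  cat("  mean coverage =", x$coverage,
      if (!is.null(x$pool_size)) paste(" pool size =", x$pool_size), "\n")
  invisible(x)
}

# number of allele copies resampled per generation
n_gametes <- function(Ne, ploidy) if (ploidy == "haploid") Ne else 2L * Ne
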