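#' Replicated allele-frequency trajectory
#'
#' Container for the time series of one locus: a replicates-by-times matrix
#' of observed allele frequencies, optionally backed by Pool-Seq read counts
#' (\code{alt}, \code{cov}). Missing observations (e.g. samples with zero
#' sequencing coverage) are \code{NA}.
#'
#' @param freq numeric matrix, replicates in rows, sampling times in columns.
#'   A plain vector is treated as a single replicate.
#' @param times generations of the columns; must start at 0 and increase.
#' @param alt,cov optional integer matrices of the same shape with the read
#'   count of the focal allele and the total coverage.
#' @return An object of class \code{"sel_traj"}.
#' @examples
#' tr <- sel_traj(rbind(c(0.1, 0.25, 0.4), c(0.1, 0.2, 0.5)), times = c(0, 10, 20))
#' combine_replicates(tr)
#' @export
sel_traj <- function(freq, times, alt = NULL, cov = NULL) {
  if (is.null(dim(freq))) freq <- matrix(freq, nrow = 1L)
  freq <- as.matrix(freq)
  times <- as.integer(times)
  stopifnot(ncol(freq) == length(times))
  if (times[1L] != 0L || any(diff(times) <= 0L))
    stop("'times' must start at 0 and be strictly increasing")
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  for (m in list(alt, cov))
    if (!is.null(m)) stopifnot(identical(dim(as.matrix(m)), dim(freq)))
  if (!is.null(alt) && !is.null(cov) && any(alt > cov, na.rm = TRUE))
    stop("'alt' counts cannot exceed 'cov'")
  structure(list(freq = freq, times = times, alt = alt, cov = cov),
            class = "sel_traj")
}

#' @export
print.sel_traj <- function(x, ...) {
  cat("Allele-frequency trajectory:", nrow(x$freq), "replicate(s),",
      length(x$times), "time points (generations ",
      x$times[1L], "-", max(x$times), ")\n", sep = " ")
  m <- round(x$freq, 3)
  dimnames(m) <- list(paste0("rep", seq_len(nrow(m))), paste0("F", x$times))
  print(m)
  invisible(x)
}

# usable-observation mask: a replicate is excluded from the first time its
# observed frequency hits 0 onwards (allele lost); NA observations are
# individually unusable. `f` is a chains x times matrix.
mask_lost <- function(f) {
  n <- nrow(f)
  lost <- rep(FALSE, n)
  use <- matrix(FALSE, n, ncol(f))
  for (j in seq_len(ncol(f))) {
    fj <- f[, j]
    lost <- lost | (!is.na(fj) & fj == 0)
    use[, j] <- !lost & !is.na(fj)
  }
  use
}

# consensus over replicates for a batch of units; f is (units*R) x T with the
# replicate index fastest; returns freq (units x T) and n_reps (units x T)
consensus_batch <- function(f, R) {
  use <- mask_lost(f)
  T_ <- ncol(f)
  U <- nrow(f) %/% R
  fu <- f * use
  fu[!use] <- 0
  dim(fu) <- c(R, U * T_)
  dim(use) <- c(R, U * T_)
  num <- .colSums(fu, R, U * T_)
  den <- .colSums(use, R, U * T_)
  cons <- num / den
  cons[den == 0] <- NA_real_
  list(freq = matrix(cons, U, T_), n_reps = matrix(den, U, T_))
}

#' Consensus trajectory across replicates
#'
#' Averages observed allele frequencies across replicate populations at each
#' sampling time, excluding each replicate from the first time point at which
#' its allele is observed lost (frequency 0) onwards, since trajectories
#' conditioned on surviving past a loss would otherwise bias the estimates.
#' Missing observations are skipped; time points at which no replicate is
#' usable are dropped.
#'
#' @param traj a [sel_traj] object.
#' @return A data frame with columns \code{time}, \code{freq} (consensus
#'   frequency) and \code{n_reps} (replicates contributing).
#' @export
combine_replicates <- function(traj) {
  stopifnot(inherits(traj, "sel_traj"))
  cb <- consensus_batch(traj$freq, nrow(traj$freq))
  keep <- cb$n_reps[1L, ] > 0
  data.frame(time = traj$times[keep], freq = cb$freq[1L, keep],
             n_reps = cb$n_reps[1L, keep])
}
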