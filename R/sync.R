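# ---- sync format (PoPoolation2 dialect) -------------------------------------
#
# Tab-separated: chrom, pos (1-based), reference base, then one column per
# sample holding "A:T:C:G:N:del" read counts. The sync format itself does not
# say which sample is which, so a layout table mapping sample columns to
# (replicate, time) must be supplied by the caller.

BASES <- c("A", "T", "C", "G")

#' Sample layout of a sync file
#'
#' Maps the sample columns of a sync file (in file order) to replicate and
#' time (generation).
#'
#' @param replicate replicate index of each sample column.
#' @param time generation of each sample column.
#' @return A data frame with class \code{"sync_layout"}.
#' @examples
#' # 2 replicates sequenced at generations 0 and 10, ordered rep-major
#' sync_layout(replicate = c(1, 1, 2, 2), time = c(0, 10, 0, 10))
#' @export
sync_layout <- function(replicate, time) {
  stopifnot(length(replicate) == length(time))
  lay <- data.frame(sample = seq_along(replicate),
                    replicate = as.integer(replicate),
                    time = as.integer(time))
  if (anyDuplicated(lay[c("replicate", "time")]))
    stop("duplicated (replicate, time) combination in layout")
  class(lay) <- c("sync_layout", "data.frame")
  lay
}

#' Read Pool-Seq allele counts from a sync file
#'
#' Parses the tab-separated sync format (chrom, pos, reference base, then one
#' "A:T:C:G:N:del" count column per sample) into per-locus time series. At
#' each locus the two bases with the highest total read count across all
#' samples form the biallelic pair (ties broken in base order A, T, C, G);
#' loci where more than two bases segregate above a noise floor are skipped
#' with a warning. The trajectory is polarised for the \emph{rising} allele:
#' the member of the pair whose pooled frequency increases from the first to
#' the last time point (ties resolved towards the non-reference allele).
#' N and deletion counts never enter the coverage.
#'
#' @param path sync file.
#' @param layout a [sync_layout] mapping sample columns to (replicate, time).
#' @param noise_floor a base is considered segregating when its pooled count
#'   exceeds this fraction of the total pooled count (and at least 2 reads).
#' @return A list of \code{"locus_series"} objects, each with \code{chrom},
#'   \code{pos}, \code{ref}, the allele pair (\code{rising}, \code{other}),
#'   replicate-by-time matrices \code{alt} and \code{cov}, the \code{times},
#'   and the raw 6-row count matrix \code{counts}. Convert to a trajectory
#'   with [as_sel_traj()].
#' @export
read_sync <- function(path, layout, noise_floor = 0.01) {
  stopifnot(inherits(layout, "sync_layout"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  out <- vector("list", length(lines))
  n_keep <- 0L
  times <- sort(unique(layout$time))
  reps <- sort(unique(layout$replicate))
  for (li in seq_along(lines)) {
    fld <- strsplit(lines[li], "\t", fixed = TRUE)[[1L]]
    if (length(fld) < 4L)
      stop("sync parse error at line ", li, ": fewer than 4 columns")
    if (length(fld) - 3L != nrow(layout))
      stop("sync line ", li, " has ", length(fld) - 3L,
           " sample columns but the layout describes ", nrow(layout))
    cnt <- suppressWarnings(
      vapply(fld[-(1:3)],
             function(x) as.integer(strsplit(x, ":", fixed = TRUE)[[1L]]),
             integer(6), USE.NAMES = FALSE))
    if (anyNA(cnt) || nrow(cnt) != 6L)
      stop("sync parse error at line ", li, ": malformed count field")
    rownames(cnt) <- c(BASES, "N", "del")
    pooled <- rowSums(cnt[BASES, , drop = FALSE])
    segregating <- pooled > max(2, noise_floor * sum(pooled))
    if (sum(segregating) > 2L) {
      warning("locus ", fld[1L], ":", fld[2L],
              " has >2 segregating bases; skipped")
      next
    }
    pair <- BASES[order(-pooled, seq_along(BASES))][1:2]
    # polarisation: pooled frequency change of pair[1] from first to last time
    f_at <- function(tm) {
      cols <- layout$sample[layout$time == tm]
      a <- sum(cnt[pair[1L], cols])
      tot <- a + sum(cnt[pair[2L], cols])
      if (tot == 0) NA_real_ else a / tot
    }
    d <- f_at(times[length(times)]) - f_at(times[1L])
    rising <- if (is.na(d) || d == 0) { # tie: ref-alt orientation
      if (pair[1L] == fld[3L]) pair[2L] else pair[1L]
    } else if (d > 0) pair[1L] else pair[2L]
    other <- setdiff(pair, rising)
    alt <- cov <- matrix(0L, length(reps), length(times),
                         dimnames = list(paste0("rep", reps),
                                         paste0("F", times)))
    for (k in seq_len(nrow(layout))) {
      i <- match(layout$replicate[k], reps)
      j <- match(layout$time[k], times)
      alt[i, j] <- cnt[rising, layout$sample[k]]
      cov[i, j] <- cnt[rising, layout$sample[k]] + cnt[other, layout$sample[k]]
    }
    n_keep <- n_keep + 1L
    out[[n_keep]] <- structure(
      list(chrom = fld[1L], pos = as.integer(fld[2L]), ref = fld[3L],
           rising = rising, other = other, alt = alt, cov = cov,
           times = times, counts = cnt, layout = layout),
      class = "locus_series")
  }
  out[seq_len(n_keep)]
}

#' @export
print.locus_series <- function(x, ...) {
  cat("Locus ", x$chrom, ":", x$pos, " (ref ", x$ref, "), rising allele ",
      x$rising, "/", x$other, "\n", sep = "")
  print(round(x$alt / ifelse(x$cov == 0, NA, x$cov), 3))
  invisible(x)
}

#' Convert a sync locus to an allele-frequency trajectory
#'
#' @param x a \code{"locus_series"} from [read_sync()].
#' @return A [sel_traj] with the rising-allele frequencies (\code{NA} where
#'   coverage is 0).
#' @export
as_sel_traj <- function(x) {
  stopifnot(inherits(x, "locus_series"))
  f <- x$alt / ifelse(x$cov == 0L, NA_integer_, x$cov)
  sel_traj(f, x$times, alt = x$alt, cov = x$cov)
}

#' Write loci to a sync file
#'
#' Emits the same tab-separated dialect read by [read_sync()], in the order
#' given; a read-write round trip preserves the file byte for byte.
#'
#' @param records list of \code{"locus_series"} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sync <- function(records, path) {
  lines <- vapply(records, function(x) {
    stopifnot(inherits(x, "locus_series"))
    paste(c(x$chrom, x$pos, x$ref,
            apply(x$counts, 2L, paste, collapse = ":")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a simulated dataset to sync records
#'
#' Represents each simulated locus as a biallelic A/T SNP (A = focal rising
#' allele) at consecutive positions, enabling a full write-read-estimate
#' round trip through the sync format.
#'
#' @param sim a \code{"sel_sim"} object with Pool-Seq counts.
#' @param chrom chromosome name used for all loci.
#' @return A list of \code{"locus_series"} objects.
#' @export
sync_records_from_sim <- function(sim, chrom = "sim") {
  stopifnot(inherits(sim, "sel_sim"), !is.null(sim$alt))
  R <- sim$design$replicates
  times <- sim$design$sampling_times
  layout <- sync_layout(replicate = rep(seq_len(R), each = length(times)),
                        time = rep(times, R))
  lapply(seq_len(nrow(sim$truth)), function(i) {
    rows <- (i - 1L) * R + seq_len(R)
    alt <- sim$alt[rows, , drop = FALSE]
    cov <- sim$cov[rows, , drop = FALSE]
    cnt <- matrix(0L, 6L, nrow(layout),
                  dimnames = list(c(BASES, "N", "del"), NULL))
    for (k in seq_len(nrow(layout))) {
      r <- layout$replicate[k]
      j <- match(layout$time[k], times)
      cnt["A", k] <- alt[r, j]
      cnt["T", k] <- cov[r, j] - alt[r, j]
    }
    dimnames(alt) <- dimnames(cov) <- list(paste0("rep", seq_len(R)),
                                           paste0("F", times))
    structure(list(chrom = chrom, pos = i, ref = "T", rising = "A",
                   other = "T", alt = alt, cov = cov, times = times,
                   counts = cnt, layout = layout),
              class = "locus_series")
  })
}
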