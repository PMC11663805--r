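# Aggregation of per-CpG records into sequential fixed-width bins over a
# target region, alpha-satellite bin annotation, and per-bin coverage tracks.
#
# The bin grid is anchored at the region start (bin i starts at
# region$start + i * bin_size); the final bin may be shorter than bin_size
# and is retained like any other bin.

#' Tile a region with sequential fixed-width bins
#'
#' @param region a 1-row interval data.frame.
#' @param bin_size bin width in bp (> 0); default 5000.
#' @return interval data.frame of `ceiling(length / bin_size)` bins tiling the
#'   region end-to-end; the last bin may be shorter.
#' @export
make_bins <- function(region, bin_size = 5000) {
  region <- .one_region(region)
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    cdr_stop("bin_size must be a positive number", "usage")
  }
  starts <- seq(region$start, region$end - 1, by = bin_size)
  ends <- pmin(starts + bin_size, region$end)
  genomic_interval(region$chrom, starts, ends)
}

#' Bin per-CpG methylation records over one region
#'
#' Each CpG is assigned to the bin containing its start coordinate. A bin's
#' `mean_freq` is the unweighted arithmetic mean of the per-CpG frequencies in
#' it (set `coverage_weighted = TRUE` for a valid-coverage-weighted mean).
#' Bins with no CpGs are flagged invalid (`is_valid = FALSE`, `mean_freq` NA)
#' and are excluded from all downstream signal statistics. `mean_valid_cov`
#' and `mean_mod_cov` are per-bin means of the per-CpG valid and
#' methylated-read counts.
#'
#' @param records methylation record data.frame (all on `region$chrom`).
#' @param region a 1-row interval data.frame.
#' @param bin_size bin width in bp; default 5000.
#' @param coverage_weighted weight per-CpG frequencies by valid coverage
#'   (off by default).
#' @return a `binned_profile` object: list with `region`, `bin_size` and
#'   `bins` (data.frame with columns `chrom`, `start`, `end`, `mean_freq`,
#'   `n_cpg`, `is_valid`, `is_alpha`, `mean_valid_cov`, `mean_mod_cov`).
#' @export
bin_methylation <- function(records, region, bin_size = 5000,
                            coverage_weighted = FALSE) {
  region <- .one_region(region)
  bins <- make_bins(region, bin_size)
  inside <- records$chrom == region$chrom &
    records$start >= region$start & records$start < region$end
  n_out <- sum(!inside)
  if (n_out > 0L) {
    message(sprintf("bin_methylation: ignored %d record(s) outside %s:%d-%d",
                    n_out, region$chrom, region$start, region$end))
  }
  rec <- records[inside, , drop = FALSE]
  if (nrow(rec) == 0L) {
    cdr_stop(sprintf("no methylation records in region %s:%d-%d",
                     region$chrom, region$start, region$end), "empty")
  }
  idx <- floor((rec$start - region$start) / bin_size) + 1L
  nb <- nrow(bins)
  n_cpg <- tabulate(idx, nbins = nb)
  sum_by_bin <- function(x) {
    out <- numeric(nb)
    s <- rowsum(x, idx, reorder = TRUE)
    out[as.integer(rownames(s))] <- s[, 1L]
    out
  }
  mean_freq <- if (coverage_weighted) {
    tot_w <- sum_by_bin(rec$valid_cov)
    ifelse(tot_w > 0, sum_by_bin(rec$freq * rec$valid_cov) / tot_w, NA_real_)
  } else {
    ifelse(n_cpg > 0, sum_by_bin(rec$freq) / n_cpg, NA_real_)
  }
  bins$mean_freq <- ifelse(n_cpg > 0, mean_freq, NA_real_)
  bins$n_cpg <- n_cpg
  bins$is_valid <- n_cpg > 0L
  bins$is_alpha <- FALSE
  bins$mean_valid_cov <- ifelse(n_cpg > 0, sum_by_bin(rec$valid_cov) / n_cpg, 0)
  bins$mean_mod_cov <- ifelse(n_cpg > 0, sum_by_bin(rec$n_mod) / n_cpg, 0)
  bins$name <- NULL
  structure(list(region = region, bin_size = bin_size, bins = bins),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("binned_profile: %s:%d-%d, %d bins of %d bp (%d valid, %d alpha)\n",
              x$region$chrom, x$region$start, x$region$end, nrow(x$bins),
              as.integer(x$bin_size), sum(x$bins$is_valid), sum(x$bins$is_alpha)))
  invisible(x)
}

#' Mark bins overlapping alpha-satellite annotation
#'
#' A bin is an alpha-satellite bin iff it overlaps at least `min_overlap_bp`
#' (default 1) base pairs of an annotation whose `repeat_name` is exactly
#' `"ALR/Alpha"` (case-sensitive). All other bins are set to `FALSE`.
#'
#' @param profile a `binned_profile`.
#' @param annotations repeat annotation data.frame from
#'   [read_repeat_annotation()].
#' @param min_overlap_bp minimum overlap in bp to count (default 1).
#' @param alpha_name annotation name treated as alpha-satellite.
#' @return the profile with `bins$is_alpha` filled in.
#' @export
annotate_alpha_bins <- function(profile, annotations, min_overlap_bp = 1,
                                alpha_name = "ALR/Alpha") {
  stopifnot(inherits(profile, "binned_profile"))
  alr <- annotations[annotations$repeat_name == alpha_name &
                       annotations$chrom == profile$region$chrom, , drop = FALSE]
  bins <- profile$bins
  is_alpha <- rep(FALSE, nrow(bins))
  for (k in seq_len(nrow(alr))) {
    ov <- .overlap_bp(bins$start, bins$end, alr$start[k], alr$end[k])
    is_alpha <- is_alpha | (ov >= min_overlap_bp)
  }
  profile$bins$is_alpha <- is_alpha
  profile
}
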