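# The CDR caller. Works on the alpha-satellite portion of a binned
# methylation profile:
#   1. signal statistics (median / mean / population SD over valid alpha-bins)
#   2. candidate selection: bins whose mean frequency falls below the median
#      by more than a required depth fraction (value < median * (1 - d))
#   3. topographic prominence filter at each candidate valley's deepest bin
#      (cutoff = prominence_fraction * median)
#   4. boundary extension outward while neighbouring alpha-bins stay below
#      mean - edge_sd_multiplier * SD
#   5. merging of calls separated by at most merge_gap_bins bins
#
# Both thresholds also have absolute modes (value < depth_fraction;
# prominence >= prominence_fraction) selectable via DetectionParams.

#' Detection parameters
#'
#' @param bin_size bin width in bp (default 5000).
#' @param depth_fraction required dip depth below the regional median, as a
#'   fraction of the median (default 0.34): a bin is a candidate iff its value
#'   is below `median * (1 - depth_fraction)`. With
#'   `absolute_thresholds = TRUE` it is instead an absolute frequency cutoff.
#' @param prominence_fraction minimum topographic prominence of a dip as a
#'   fraction of the regional median (default 0.30); absolute prominence when
#'   `absolute_thresholds = TRUE`.
#' @param edge_sd_multiplier boundary-extension threshold is
#'   `mean - edge_sd_multiplier * SD` (default 1.0).
#' @param merge_gap_bins merge calls separated by at most this many bins
#'   (default 1).
#' @param absolute_thresholds interpret `depth_fraction` and
#'   `prominence_fraction` as absolute frequencies instead of
#'   median-relative fractions (default FALSE).
#' @return a `detection_params` list.
#' @export
detection_params <- function(bin_size = 5000, depth_fraction = 0.34,
                             prominence_fraction = 0.30,
                             edge_sd_multiplier = 1.0, merge_gap_bins = 1L,
                             absolute_thresholds = FALSE) {
  if (bin_size <= 0) cdr_stop("bin_size must be > 0", "usage")
  if (depth_fraction <= 0 || depth_fraction >= 1) {
    cdr_stop("depth_fraction must be in (0, 1)", "usage")
  }
  if (prominence_fraction < 0 || prominence_fraction >= 1) {
    cdr_stop("prominence_fraction must be in [0, 1)", "usage")
  }
  if (edge_sd_multiplier < 0) cdr_stop("edge_sd_multiplier must be >= 0", "usage")
  if (merge_gap_bins < 0) cdr_stop("merge_gap_bins must be >= 0", "usage")
  structure(list(
    bin_size = bin_size, depth_fraction = depth_fraction,
    prominence_fraction = prominence_fraction,
    edge_sd_multiplier = edge_sd_multiplier,
    merge_gap_bins = as.integer(merge_gap_bins),
    absolute_thresholds = isTRUE(absolute_thresholds)
  ), class = "detection_params")
}

#' Extract the valid alpha-satellite signal from a profile
#'
#' @param profile an annotated `binned_profile`.
#' @return data.frame with `bin_index` (1-based index into the profile's bin
#'   list, genomic order) and `value` (mean methylation frequency) for valid
#'   alpha-bins only.
#' @export
alpha_signal <- function(profile) {
  stopifnot(inherits(profile, "binned_profile"))
  sel <- which(profile$bins$is_valid & profile$bins$is_alpha)
  if (length(sel) == 0L) {
    cdr_stop(sprintf("no alpha-satellite signal in region %s:%d-%d",
                     profile$region$chrom, profile$region$start,
                     profile$region$end), "empty")
  }
  data.frame(bin_index = sel, value = profile$bins$mean_freq[sel])
}

#' Summary statistics of an alpha-bin signal
#'
#' Median (midpoint of the two central order statistics for even n),
#' arithmetic mean, and population standard deviation (1/n denominator: the
#' signal is the full population of the region's alpha-bins, not a sample).
#'
#' @param signal data.frame from [alpha_signal()].
#' @return list with `median`, `mean`, `sd`, `n_alpha_bins`.
#' @export
signal_stats <- function(signal) {
  v <- signal$value
  if (length(v) == 0L) cdr_stop("empty signal", "usage")
  list(
    median = stats::median(v),
    mean = mean(v),
    sd = sqrt(mean((v - mean(v))^2)),
    n_alpha_bins = length(v)
  )
}

# Prominence of the valley at position idx of `values`, no precondition
# check. One-sided rule: walk away from idx until a value strictly lower than
# values[idx] is found or the sequence ends; that side's col height is the
# maximum value seen during the walk (the full side when the walk reaches the
# edge). Prominence = min(left col, right col) - values[idx]. An empty side
# (idx at the signal edge) imposes no col, so only the other side counts;
# if the immediate neighbour is already lower, no col is climbed and that
# side contributes 0.
.prominence <- function(values, idx) {
  v <- values[idx]
  side_max <- function(seq_vals) {
    if (length(seq_vals) == 0L) return(Inf)
    lower <- which(seq_vals < v)
    seen <- if (length(lower) > 0L) seq_vals[seq_len(lower[1L] - 1L)] else seq_vals
    if (length(seen) == 0L) v else max(seen)
  }
  L <- side_max(rev(values[seq_len(idx - 1L)]))
  R <- side_max(if (idx < length(values)) values[(idx + 1L):length(values)] else numeric(0))
  min(L, R) - v
}

#' Topographic prominence of a valley in a 1-D signal
#'
#' The prominence of a dip is its depth relative to the lowest "col" one must
#' climb over to reach a strictly deeper valley (or, failing that, the highest
#' value on that side of the signal), computed on the inverted signal.
#'
#' @param values numeric vector (e.g. alpha-bin methylation frequencies in
#'   genomic order).
#' @param idx index of a local minimum (neighbours, where present, must be
#'   >= `values[idx]`).
#' @return the prominence, a non-negative number.
#' @examples
#' valley_prominence(c(0.8, 0.2, 0.7, 0.1, 0.9), 4) # 0.70
#' valley_prominence(c(0.8, 0.2, 0.7, 0.1, 0.9), 2) # 0.50
#' @export
valley_prominence <- function(values, idx) {
  if (idx < 1L || idx > length(values)) cdr_stop("idx out of range", "usage")
  v <- values[idx]
  if ((idx > 1L && values[idx - 1L] < v) ||
      (idx < length(values) && values[idx + 1L] < v)) {
    cdr_stop("values[idx] is not a local minimum", "usage")
  }
  .prominence(values, idx)
}

#' Select candidate dip valleys below the depth threshold
#'
#' Candidate bins are valid alpha-bins whose value is below
#' `median * (1 - depth_fraction)` (or below `depth_fraction` itself in
#' absolute mode). Maximal runs of genomically consecutive candidate bins
#' (adjacent indices in the full bin list, so an excluded or non-alpha bin
#' splits a run) form one valley each. The valley's seed is its deepest bin
#' (leftmost on ties); prominence is evaluated at the seed's position within
#' the alpha-signal via the topographic rule.
#'
#' @param signal data.frame from [alpha_signal()].
#' @param stats list from [signal_stats()] on the same signal.
#' @param params a `detection_params` object.
#' @return data.frame of candidate valleys with columns `i`, `j` (inclusive
#'   bin-index range in the full profile), `min_index`, `min_value`,
#'   `prominence`.
#' @export
find_candidate_valleys <- function(signal, stats, params = detection_params()) {
  threshold <- if (params$absolute_thresholds) {
    params$depth_fraction
  } else {
    stats$median * (1 - params$depth_fraction)
  }
  cand <- signal$value < threshold
  empty <- data.frame(i = integer(0), j = integer(0), min_index = integer(0),
                      min_value = numeric(0), prominence = numeric(0))
  if (!any(cand)) return(empty)
  # split candidate alpha-positions into runs of genomically adjacent bins
  pos <- which(cand)
  bin_idx <- signal$bin_index[pos]
  run_id <- cumsum(c(1L, diff(bin_idx) != 1L))
  out <- lapply(split(seq_along(pos), run_id), function(grp) {
    p <- pos[grp]                       # positions within the alpha-signal
    vals <- signal$value[p]
    deepest <- p[which.min(vals)]       # which.min takes the leftmost tie
    data.frame(
      i = signal$bin_index[p[1L]], j = signal$bin_index[p[length(p)]],
      min_index = signal$bin_index[deepest],
      min_value = signal$value[deepest],
      prominence = .prominence(signal$value, deepest)
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Filter candidate valleys by topographic prominence
#'
#' Keeps candidates whose prominence is at least
#' `prominence_fraction * median` (>=, so a value exactly at the cutoff is
#' kept), or at least `prominence_fraction` in absolute mode. This removes
#' low-confidence calls where methylation is uniformly low across a
#' subregion: such bins sit below the depth threshold but climb no col.
#'
#' @inheritParams find_candidate_valleys
#' @param candidates data.frame from [find_candidate_valleys()].
#' @return the surviving candidates, order preserved.
#' @export
filter_by_prominence <- function(candidates, signal, stats,
                                 params = detection_params()) {
  cutoff <- if (params$absolute_thresholds) {
    params$prominence_fraction
  } else {
    params$prominence_fraction * stats$median
  }
  candidates[candidates$prominence >= cutoff, , drop = FALSE]
}

#' Extend a candidate valley's boundaries by the mean-minus-SD rule
#'
#' The extension threshold is `T = mean - edge_sd_multiplier * SD`, with mean
#' and SD computed over all valid alpha-bins of the region. The candidate's
#' bin range grows outward one bin at a time (left and right independently)
#' while the next bin is a valid alpha-bin AND its value is below `T`;
#' growth stops at the first bin failing either condition or at the profile
#' edge. Extension therefore never crosses an excluded or non-alpha bin.
#'
#' @param candidate a 1-row data.frame from [find_candidate_valleys()].
#' @param profile the annotated `binned_profile` the candidate came from.
#' @param stats list from [signal_stats()].
#' @param params a `detection_params` object.
#' @return the candidate with `i`/`j` possibly widened.
#' @export
extend_boundaries <- function(candidate, profile, stats,
                              params = detection_params()) {
  T_ext <- stats$mean - params$edge_sd_multiplier * stats$sd
  bins <- profile$bins
  ok <- function(k) {
    k >= 1L && k <= nrow(bins) && bins$is_valid[k] && bins$is_alpha[k] &&
      bins$mean_freq[k] < T_ext
  }
  i <- candidate$i
  j <- candidate$j
  while (ok(i - 1L)) i <- i - 1L
  while (ok(j + 1L)) j <- j + 1L
  candidate$i <- i
  candidate$j <- j
  candidate
}

#' Merge nearby calls
#'
#' Calls whose bin ranges overlap or are separated by at most
#' `merge_gap_bins` bins are merged into one; the merged call keeps the
#' deepest member's `min_index`/`min_value` and the maximum prominence.
#'
#' @param calls candidate data.frame sorted by `i`.
#' @param params a `detection_params` object.
#' @return merged data.frame.
#' @export
merge_calls <- function(calls, params = detection_params()) {
  if (nrow(calls) <= 1L) return(calls)
  calls <- calls[order(calls$i), , drop = FALSE]
  grp <- integer(nrow(calls))
  grp[1L] <- 1L
  cur_end <- calls$j[1L]
  for (k in 2L:nrow(calls)) {
    gap <- calls$i[k] - cur_end - 1L
    if (gap <= params$merge_gap_bins) {
      grp[k] <- grp[k - 1L]
      cur_end <- max(cur_end, calls$j[k])
    } else {
      grp[k] <- grp[k - 1L] + 1L
      cur_end <- calls$j[k]
    }
  }
  out <- lapply(split(seq_len(nrow(calls)), grp), function(rows) {
    m <- calls[rows, , drop = FALSE]
    deepest <- which.min(m$min_value)
    data.frame(
      i = min(m$i), j = max(m$j),
      min_index = m$min_index[deepest], min_value = m$min_value[deepest],
      prominence = max(m$prominence)
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call centromere dip regions on a binned profile
#'
#' Orchestrates the full caller: alpha-signal extraction, signal statistics,
#' depth-threshold candidate selection, prominence filtering, boundary
#' extension and merging, then converts surviving bin ranges to genomic
#' intervals. Deterministic for fixed input and parameters.
#'
#' @param profile an annotated `binned_profile` with at least one valid
#'   alpha-bin.
#' @param params a `detection_params` object.
#' @param region_label name written to the output BED name column (defaults
#'   to the region's `name`, or "CDR").
#' @return data.frame of calls with columns `chrom`, `start`, `end`, `name`,
#'   `min_freq`, `prominence`, `seed_bin_index`, `region_median`,
#'   `region_mean`, `region_sd`; zero rows when no dip qualifies.
#' @export
call_cdrs <- function(profile, params = detection_params(),
                      region_label = NULL) {
  stopifnot(inherits(profile, "binned_profile"))
  sig <- alpha_signal(profile)
  st <- signal_stats(sig)
  cand <- find_candidate_valleys(sig, st, params)
  cand <- filter_by_prominence(cand, sig, st, params)
  if (nrow(cand) > 0L) {
    cand <- do.call(rbind, lapply(seq_len(nrow(cand)), function(k) {
      extend_boundaries(cand[k, , drop = FALSE], profile, st, params)
    }))
    cand <- merge_calls(cand, params)
  }
  if (is.null(region_label)) {
    region_label <- profile$region$name
    if (is.na(region_label)) region_label <- "CDR"
  }
  bins <- profile$bins
  data.frame(
    chrom = rep(profile$region$chrom, nrow(cand)),
    start = bins$start[cand$i], end = bins$end[cand$j],
    name = rep(region_label, nrow(cand)),
    min_freq = cand$min_value, prominence = cand$prominence,
    seed_bin_index = cand$min_index,
    region_median = rep(st$median, nrow(cand)),
    region_mean = rep(st$mean, nrow(cand)),
    region_sd = rep(st$sd, nrow(cand)),
    stringsAsFactors = FALSE
  )
}
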