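# Classification of CDR calls against a truth interval set, mirroring a
# manual validation protocol with explicit overlap/tolerance rules:
# a truth dip is "correct" if a single overlapping call covers it to within
# boundary_tol at both ends, "partial" if some call overlaps it but leaves a
# boundary deficit larger than boundary_tol (the call could be extended on
# one or both sides), and "missed" if no call overlaps it. A call is
# "erroneous" if it overlaps no truth dip. One call overlapping two truth
# dips credits both (matching the caller's merge behaviour).

#' Classify calls against a truth set and compute precision/recall
#'
#' @param calls call data.frame (needs `chrom`, `start`, `end`), e.g. from
#'   [call_cdrs()] or [read_region_bed()].
#' @param truth truth interval data.frame.
#' @param boundary_tol boundary tolerance in bp (default 5000, one bin).
#' @return an `eval_result` list: counts `n_truth`, `n_calls`, `correct`,
#'   `partial`, `missed`, `erroneous`, plus `precision` =
#'   `(n_calls - erroneous) / n_calls` and `recall` =
#'   `(correct + partial) / n_truth`. With an empty denominator the metric is
#'   `NA` (not applicable), never a 0/0 division.
#' @export
classify_calls <- function(calls, truth, boundary_tol = 5000) {
  if (boundary_tol < 0) cdr_stop("boundary_tol must be >= 0", "usage")
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)
  truth_class <- character(n_truth)
  call_hit <- rep(FALSE, n_calls)
  for (t in seq_len(n_truth)) {
    ov <- calls$chrom == truth$chrom[t] &
      .overlaps(calls$start, calls$end, truth$start[t], truth$end[t])
    call_hit <- call_hit | ov
    if (!any(ov)) {
      truth_class[t] <- "missed"
    } else {
      covered <- ov & calls$start <= truth$start[t] + boundary_tol &
        calls$end >= truth$end[t] - boundary_tol
      truth_class[t] <- if (any(covered)) "correct" else "partial"
    }
  }
  erroneous <- sum(!call_hit)
  res <- list(
    n_truth = n_truth, n_calls = n_calls,
    correct = sum(truth_class == "correct"),
    partial = sum(truth_class == "partial"),
    missed = sum(truth_class == "missed"),
    erroneous = erroneous,
    precision = if (n_calls > 0) (n_calls - erroneous) / n_calls else NA_real_,
    recall = if (n_truth > 0) sum(truth_class != "missed") / n_truth else NA_real_,
    truth_class = truth_class
  )
  structure(res, class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    paste0("eval_result: %d truth / %d calls | correct %d, partial %d, ",
           "missed %d, erroneous %d | precision %s, recall %s\n"),
    x$n_truth, x$n_calls, x$correct, x$partial, x$missed, x$erroneous,
    ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
    ifelse(is.na(x$recall), "NA", sprintf("%.3f", x$recall))))
  invisible(x)
}

#' Write an evaluation summary as a small tab-separated table
#'
#' @param result an `eval_result` from [classify_calls()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_summary <- function(result, path) {
  keys <- c("n_truth", "n_calls", "correct", "partial", "missed",
            "erroneous", "precision", "recall")
  vals <- vapply(keys, function(k) {
    v <- result[[k]]
    if (is.na(v)) "NA" else format(v, digits = 6)
  }, character(1))
  writeLines(paste(keys, vals, sep = "\t"), path)
  invisible(path)
}
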