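# Structured conditions and small interval helpers shared across modules.

#' Signal a classed cdrscan error
#'
#' All user-facing errors in the package carry one of three subclasses so that
#' callers (and the command-line wrapper) can map them to distinct exit codes:
#' `cdr_usage_error` (bad arguments/parameters), `cdr_parse_error` (malformed
#' input file), `cdr_empty_error` (structurally valid input but no usable
#' signal, e.g. no records in a region or no alpha-satellite bins).
#'
#' @param msg character message.
#' @param class one of "usage", "parse", "empty".
#' @param ... additional condition fields (e.g. `line`, `region`).
#' @keywords internal
#' @noRd
cdr_stop <- function(msg, class = c("usage", "parse", "empty"), ...) {
  class <- match.arg(class)
  cls <- paste0("cdr_", class, "_error")
  stop(structure(
    class = c(cls, "cdr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Construct a genomic interval table
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open, so `length = end - start`.
#'
#' @param chrom character vector of sequence names.
#' @param start integer-like 0-based inclusive start positions.
#' @param end integer-like 0-based exclusive end positions.
#' @param name optional labels (recycled).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @examples
#' genomic_interval("chr8", 43746447, 47020471)
#' @export
genomic_interval <- function(chrom, start, end, name = NA_character_) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) {
    cdr_stop("interval coordinates must be numeric", "usage")
  }
  if (any(start < 0) || any(start >= end)) {
    cdr_stop("intervals require 0 <= start < end", "usage")
  }
  data.frame(
    chrom = as.character(chrom), start = start, end = end,
    name = as.character(name), stringsAsFactors = FALSE
  )
}

# TRUE where interval (start1,end1) overlaps (start2,end2) by >= 1 bp,
# half-open on both sides. Vectorised over the first pair.
.overlaps <- function(start1, end1, start2, end2) {
  start1 < end2 & end1 > start2
}

# Overlap length in bp between one interval and a vector of intervals.
.overlap_bp <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2))
}

# Single-interval accessor used when an operation expects exactly one region.
.one_region <- function(region) {
  if (!is.data.frame(region) || nrow(region) != 1L) {
    cdr_stop("expected exactly one region (a 1-row interval data.frame)", "usage")
  }
  region
}
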