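# Readers and writers for every on-disk format the tool touches:
# bedMethyl pileups, region BED, repeat annotations (BED or RepeatMasker .out),
# and the CDR-call BED output. All internal coordinates are 0-based half-open;
# RepeatMasker 1-based inclusive query coordinates are converted on read.
# Methylation is stored as a fraction in [0,1]; the bedMethyl percent column
# is divided by 100 on read.

# Read a whitespace/tab table as character, keeping original line numbers and
# skipping comment/track/browser lines.
.read_text_table <- function(path, sep = "\t", skip = 0L) {
  if (!file.exists(path)) cdr_stop(paste0("file not found: ", path), "usage")
  lines <- readLines(path, warn = FALSE)
  if (skip > 0L) lines <- lines[-seq_len(min(skip, length(lines)))]
  lineno <- seq_along(lines) + skip
  keep <- !grepl("^\\s*$", lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(list(fields = list(), lineno = integer(0)))
  }
  fields <- if (identical(sep, "ws")) {
    strsplit(trimws(lines), "\\s+")
  } else {
    strsplit(lines, sep, fixed = TRUE)
  }
  list(fields = fields, lineno = lineno)
}

.parse_num <- function(x, what, lineno, integer_only = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | (integer_only & v != floor(v))
  if (any(bad)) {
    i <- which(bad)[1L]
    cdr_stop(
      sprintf("line %d: malformed %s value '%s'", lineno[i], what, x[i]),
      "parse", line = lineno[i]
    )
  }
  v
}

#' Read a bedMethyl methylation pileup restricted to target regions
#'
#' Parses the tab-separated bedMethyl dialect written by modified-base pileup
#' tools. Two layouts are tolerated: the "simple" 9+2-column layout
#' (9 BED columns, then valid coverage and percent modified) and the extended
#' 12- or 18-column layout that additionally carries the modified-read count.
#' When the modified-read count column is absent it is reconstructed as
#' `round(valid_cov * percent / 100)`.
#'
#' Only 5mC records (modification code `"m"`) are kept; rows for other
#' modification codes (e.g. `"h"`) are dropped with a message. Records are
#' filtered to those overlapping a requested region and returned sorted by
#' `(chrom, start)`.
#'
#' @param path path to a bedMethyl file.
#' @param regions interval data.frame (see [genomic_interval()]) of target
#'   regions; must be non-empty.
#' @param dialect `"auto"` (detect by column count), `"simple"` (no
#'   modified-count column) or `"extended"`.
#' @return a `data.frame` of methylation records with columns `chrom`,
#'   `start`, `end`, `mod_code`, `strand`, `valid_cov`, `n_mod`, `freq`
#'   (fraction in \[0,1\]).
#' @export
read_bedmethyl <- function(path, regions, dialect = c("auto", "simple", "extended")) {
  dialect <- match.arg(dialect)
  if (!is.data.frame(regions) || nrow(regions) == 0L) {
    cdr_stop("regions must be a non-empty interval data.frame", "usage")
  }
  tab <- .read_text_table(path)
  if (length(tab$fields) == 0L) {
    cdr_stop(paste0("bedMethyl file is empty: ", path), "parse")
  }
  nf <- lengths(tab$fields)
  if (any(nf < 11L)) {
    i <- which(nf < 11L)[1L]
    cdr_stop(sprintf("line %d: expected >= 11 bedMethyl columns, found %d",
                     tab$lineno[i], nf[i]), "parse", line = tab$lineno[i])
  }
  if (dialect == "auto") {
    dialect <- if (stats::median(nf) >= 12) "extended" else "simple"
  }
  get_col <- function(j) vapply(tab$fields, function(f) f[[j]], character(1))
  chrom <- get_col(1L)
  start <- .parse_num(get_col(2L), "start coordinate", tab$lineno, integer_only = TRUE)
  end <- .parse_num(get_col(3L), "end coordinate", tab$lineno, integer_only = TRUE)
  mod_code <- get_col(4L)
  strand <- get_col(6L)
  valid_cov <- .parse_num(get_col(10L), "valid coverage", tab$lineno, integer_only = TRUE)
  pct <- .parse_num(get_col(11L), "percent modified", tab$lineno)
  if (any(pct < 0 | pct > 100)) {
    i <- which(pct < 0 | pct > 100)[1L]
    cdr_stop(sprintf("line %d: percent modified %.4g outside [0,100]",
                     tab$lineno[i], pct[i]), "parse", line = tab$lineno[i])
  }
  n_mod <- if (dialect == "extended") {
    if (any(nf < 12L)) {
      i <- which(nf < 12L)[1L]
      cdr_stop(sprintf("line %d: extended bedMethyl needs >= 12 columns",
                       tab$lineno[i]), "parse", line = tab$lineno[i])
    }
    .parse_num(get_col(12L), "modified-read count", tab$lineno, integer_only = TRUE)
  } else {
    round(valid_cov * pct / 100)
  }
  rec <- data.frame(
    chrom = chrom, start = start, end = end, mod_code = mod_code,
    strand = strand, valid_cov = valid_cov, n_mod = n_mod,
    freq = pct / 100, stringsAsFactors = FALSE
  )
  n_other <- sum(rec$mod_code != "m")
  if (n_other > 0L) {
    message(sprintf("read_bedmethyl: dropped %d non-5mC record(s)", n_other))
    rec <- rec[rec$mod_code == "m", , drop = FALSE]
  }
  # region filter, with an explicit error for any region left empty
  keep <- rep(FALSE, nrow(rec))
  for (r in seq_len(nrow(regions))) {
    hit <- rec$chrom == regions$chrom[r] &
      .overlaps(rec$start, rec$end, regions$start[r], regions$end[r])
    if (!any(hit)) {
      cdr_stop(sprintf("no bedMethyl records overlap region %s:%d-%d",
                       regions$chrom[r], regions$start[r], regions$end[r]),
               "empty", region = regions[r, , drop = FALSE])
    }
    keep <- keep | hit
  }
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[order(rec$chrom, rec$start), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Read a BED file of target regions
#'
#' @param path path to a BED3/BED4 file (0-based half-open).
#' @return interval data.frame with columns `chrom`, `start`, `end`, `name`;
#'   file order and duplicates are preserved.
#' @export
read_region_bed <- function(path) {
  tab <- .read_text_table(path)
  if (length(tab$fields) == 0L) cdr_stop(paste0("no regions in ", path), "empty")
  nf <- lengths(tab$fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1L]
    cdr_stop(sprintf("line %d: BED needs >= 3 columns", tab$lineno[i]),
             "parse", line = tab$lineno[i])
  }
  chrom <- vapply(tab$fields, `[[`, character(1), 1L)
  start <- .parse_num(vapply(tab$fields, `[[`, character(1), 2L),
                      "start coordinate", tab$lineno, integer_only = TRUE)
  end <- .parse_num(vapply(tab$fields, `[[`, character(1), 3L),
                    "end coordinate", tab$lineno, integer_only = TRUE)
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    cdr_stop(sprintf("line %d: degenerate interval (start >= end)", tab$lineno[i]),
             "parse", line = tab$lineno[i])
  }
  name <- vapply(tab$fields, function(f) {
    if (length(f) >= 4L) f[[4L]] else NA_character_
  }, character(1))
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

#' Read a repeat annotation in BED or RepeatMasker .out format
#'
#' All annotations are returned (not just "ALR/Alpha"); filtering to
#' alpha-satellite happens downstream in [annotate_alpha_bins()].
#'
#' @param path annotation file path.
#' @param dialect `"bed"` (>= 4 columns, column 4 = repeat name, optional
#'   column 5 = repeat class) or `"rmout"` (RepeatMasker .out: 3 header lines,
#'   whitespace-separated body; 1-based inclusive query coordinates are
#'   converted to 0-based half-open).
#' @return data.frame with columns `chrom`, `start`, `end`, `repeat_name`,
#'   `repeat_class`.
#' @export
read_repeat_annotation <- function(path, dialect = c("bed", "rmout")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) cdr_stop(
                        sprintf("unknown repeat-annotation dialect '%s'", dialect[1L]),
                        "usage"))
  if (dialect == "bed") {
    tab <- .read_text_table(path)
    nf <- lengths(tab$fields)
    if (length(tab$fields) == 0L || any(nf < 4L)) {
      i <- if (length(tab$fields) == 0L) NA_integer_ else which(nf < 4L)[1L]
      cdr_stop("repeat BED needs >= 4 columns (column 4 = repeat name)",
               "parse", line = tab$lineno[i])
    }
    chrom <- vapply(tab$fields, `[[`, character(1), 1L)
    start <- .parse_num(vapply(tab$fields, `[[`, character(1), 2L),
                        "start coordinate", tab$lineno, integer_only = TRUE)
    end <- .parse_num(vapply(tab$fields, `[[`, character(1), 3L),
                      "end coordinate", tab$lineno, integer_only = TRUE)
    repeat_name <- vapply(tab$fields, `[[`, character(1), 4L)
    repeat_class <- vapply(tab$fields, function(f) {
      if (length(f) >= 5L) f[[5L]] else NA_character_
    }, character(1))
  } else {
    tab <- .read_text_table(path, sep = "ws", skip = 3L)
    if (length(tab$fields) == 0L) cdr_stop("empty RepeatMasker .out body", "parse")
    nf <- lengths(tab$fields)
    if (any(nf < 15L)) {
      i <- which(nf < 15L)[1L]
      cdr_stop(sprintf("line %d: RepeatMasker .out body row has %d < 15 columns",
                       tab$lineno[i], nf[i]), "parse", line = tab$lineno[i])
    }
    chrom <- vapply(tab$fields, `[[`, character(1), 5L)
    qbegin <- .parse_num(vapply(tab$fields, `[[`, character(1), 6L),
                         "query begin", tab$lineno, integer_only = TRUE)
    qend <- .parse_num(vapply(tab$fields, `[[`, character(1), 7L),
                       "query end", tab$lineno, integer_only = TRUE)
    start <- qbegin - 1  # 1-based inclusive -> 0-based half-open
    end <- qend
    repeat_name <- vapply(tab$fields, `[[`, character(1), 10L)
    repeat_class <- vapply(tab$fields, `[[`, character(1), 11L)
  }
  data.frame(chrom = chrom, start = start, end = end,
             repeat_name = repeat_name, repeat_class = repeat_class,
             stringsAsFactors = FALSE)
}

#' Collapse per-strand CpG rows into strand-combined records
#'
#' bedMethyl pileups may report the two strands of one CpG dinucleotide as
#' separate rows: position `p` on `+` and `p+1` on `-`. Such pairs are
#' collapsed into a single record spanning the dinucleotide with `valid_cov`
#' and `n_mod` summed and `freq` recomputed as `n_mod / valid_cov`.
#' Unpaired and already strand-combined (`.`) rows pass through unchanged.
#'
#' @param records methylation record data.frame sorted by `(chrom, start)`.
#' @return data.frame of the same shape; total `valid_cov` and `n_mod` are
#'   conserved.
#' @export
merge_strand_records <- function(records) {
  if (nrow(records) == 0L) return(records)
  anchor <- records$start - (records$strand == "-")
  key <- paste(records$chrom, anchor)
  # only '+'/'-' rows participate in pairing; '.' rows are already combined.
  # A CpG is a pair iff its anchor key appears on both strands.
  pairable <- records$strand %in% c("+", "-")
  tab_plus <- unique(key[records$strand == "+"])
  tab_minus <- unique(key[records$strand == "-"])
  paired_keys <- intersect(tab_plus, tab_minus)
  is_paired <- pairable & key %in% paired_keys
  out_single <- records[!is_paired, , drop = FALSE]
  if (any(is_paired)) {
    p <- records[is_paired, , drop = FALSE]
    a <- anchor[is_paired]
    agg_cov <- rowsum(p$valid_cov, paste(p$chrom, a))
    agg_mod <- rowsum(p$n_mod, paste(p$chrom, a))
    first <- !duplicated(paste(p$chrom, a))
    merged <- data.frame(
      chrom = p$chrom[first], start = a[first], end = a[first] + 2,
      mod_code = p$mod_code[first], strand = ".",
      valid_cov = agg_cov[paste(p$chrom[first], a[first]), 1L],
      n_mod = agg_mod[paste(p$chrom[first], a[first]), 1L],
      stringsAsFactors = FALSE
    )
    merged$freq <- ifelse(merged$valid_cov > 0, merged$n_mod / merged$valid_cov, 0)
    out <- rbind(out_single, merged)
  } else {
    out <- out_single
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write CDR calls as a BED file
#'
#' One line per call: `chrom start end name score`, 0-based half-open, the
#' name column carrying the region label and the score column carrying the
#' call's minimum bin methylation frequency scaled to 0-1000 (rounded).
#' Calls are written as-is (no merging at write time). An empty call set
#' produces an empty, header-free file.
#'
#' @param calls CDR call data.frame from [call_cdrs()], sorted by
#'   `(chrom, start)`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cdr_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(calls)) calls$name else NA_character_
  name[is.na(name)] <- "CDR"
  score <- round(calls$min_freq * 1000)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d",
                   calls$chrom, as.integer(calls$start), as.integer(calls$end),
                   name, as.integer(score))
  writeLines(lines, path)
  invisible(path)
}
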