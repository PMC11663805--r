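# Shared fixture builders. All fixtures are constructed in code at test time.

# Build a binned_profile directly from a vector of bin values, bypassing the
# record-level pipeline, so detection-layer tests can state signals exactly.
make_profile <- function(values, alpha = rep(TRUE, length(values)),
                         valid = !is.na(values), bin_size = 5000,
                         chrom = "chrT", region_start = 0,
                         name = "test_region") {
  n <- length(values)
  region <- genomic_interval(chrom, region_start,
                             region_start + n * bin_size, name = name)
  vals <- ifelse(valid, values, NA_real_)
  bins <- data.frame(
    chrom = chrom,
    start = region_start + (seq_len(n) - 1) * bin_size,
    end = region_start + seq_len(n) * bin_size,
    mean_freq = vals,
    n_cpg = ifelse(valid, 10L, 0L),
    is_valid = valid,
    is_alpha = alpha,
    mean_valid_cov = ifelse(valid, 30, 0),
    mean_mod_cov = ifelse(valid, 30 * ifelse(is.na(vals), 0, vals), 0),
    stringsAsFactors = FALSE
  )
  structure(list(region = region, bin_size = bin_size, bins = bins),
            class = "binned_profile")
}

# Write methylation records as an on-disk bedMethyl file.
# dialect "extended": 12 columns incl. the modified-read count;
# dialect "simple": 11 columns (count reconstructed from percent on read).
write_bedmethyl_file <- function(records, path, dialect = "extended",
                                 digits = 2) {
  pct <- formatC(100 * records$freq, digits = digits, format = "f")
  base <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0,0,0\t%d\t%s",
                  records$chrom, as.integer(records$start),
                  as.integer(records$end), records$mod_code,
                  as.integer(records$valid_cov), records$strand,
                  as.integer(records$start), as.integer(records$end),
                  as.integer(records$valid_cov), pct)
  lines <- if (dialect == "extended") {
    paste0(base, "\t", as.integer(records$n_mod))
  } else {
    base
  }
  writeLines(lines, path)
  path
}

# Quick record data.frame constructor.
methyl_records <- function(chrom, start, valid_cov, n_mod, strand = ".",
                           mod_code = "m", end = start + 1) {
  data.frame(chrom = chrom, start = start, end = end, mod_code = mod_code,
             strand = strand, valid_cov = valid_cov, n_mod = n_mod,
             freq = ifelse(valid_cov > 0, n_mod / valid_cov, 0),
             stringsAsFactors = FALSE)
}

# A small RepeatMasker .out file with the standard 3 header lines.
write_rmout_file <- function(path, chrom, qbegin, qend, repeat_name,
                             repeat_class = "Satellite") {
  header <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  body <- sprintf(
    " 1000  10.0  0.1  0.2  %s  %d  %d  (0)  +  rep_unit  %s/%s  1  171  (0)  %d",
    chrom, qbegin, qend, repeat_name, repeat_class, seq_along(qbegin))
  # RepeatMasker puts name in col 10 and class in col 11; build explicitly
  body <- vapply(seq_along(qbegin), function(i) {
    paste(c("1000", "10.0", "0.1", "0.2", chrom[i], qbegin[i], qend[i],
            "(0)", "+", repeat_name[i], repeat_class[i], "1", "171", "(0)",
            i), collapse = "  ")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
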