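# Seeded generator of centromeric methylation fixtures: a hypermethylated
# alpha-satellite higher-order-repeat array flanked by other satellite
# sequence, with one or more planted hypomethylation dips (CDRs). Emits
# per-CpG pileup records, repeat annotations, and the truth intervals, plus
# writers producing the exact on-disk dialects the io readers consume.

#' Simulation parameters
#'
#' Defaults describe a typical human centromere target: a 3-Mbp region of
#' interest whose central 2 Mbp is the alpha-satellite HOR array, CpG sites
#' every ~60 bp on average, a hypermethylated baseline (0.85) with one
#' planted dip to 0.10 of length 60-150 kbp, linear methylation ramps of
#' 10 kbp at the dip edges, and 30x mean read coverage.
#'
#' @param region_length region of interest length in bp.
#' @param alpha_start,alpha_end alpha-satellite array within the region
#'   (region-relative bp); default the central 2 Mbp.
#' @param cpg_mean_spacing mean CpG inter-site spacing in bp.
#' @param baseline_meth methylation fraction outside dips.
#' @param dip_meth methylation fraction at a dip's floor.
#' @param n_dips number of planted dips.
#' @param dip_length_range length range (bp) a dip is drawn from.
#' @param edge_ramp width (bp) of the linear ramp at each dip edge.
#' @param mean_coverage mean per-CpG valid read coverage (Poisson).
#' @param seed integer seed; all randomness is reproducible from it.
#' @param chrom sequence name used for all emitted records.
#' @param region_start region start coordinate (bp).
#' @return a `sim_params` list.
#' @export
sim_params <- function(region_length = 3e6,
                       alpha_start = NULL, alpha_end = NULL,
                       cpg_mean_spacing = 60, baseline_meth = 0.85,
                       dip_meth = 0.10, n_dips = 1L,
                       dip_length_range = c(60000, 150000),
                       edge_ramp = 10000, mean_coverage = 30,
                       seed = 1L, chrom = "cen_sim", region_start = 0) {
  if (is.null(alpha_start) || is.null(alpha_end)) {
    # default alpha array: the central 2 Mbp, or two-thirds of a short region
    alpha_len <- min(2e6, round(region_length * 2 / 3))
    alpha_start <- region_start + round((region_length - alpha_len) / 2)
    alpha_end <- alpha_start + alpha_len
  }
  alpha_end <- min(alpha_end, region_start + region_length)
  if (alpha_start < region_start || alpha_start >= alpha_end) {
    cdr_stop("alpha array must lie inside the region", "usage")
  }
  if (!(dip_meth >= 0 && dip_meth <= baseline_meth && baseline_meth <= 1)) {
    cdr_stop("need 0 <= dip_meth <= baseline_meth <= 1", "usage")
  }
  if (dip_length_range[1] > dip_length_range[2] || dip_length_range[1] <= 0) {
    cdr_stop("invalid dip_length_range", "usage")
  }
  structure(list(
    region_length = region_length, alpha_start = alpha_start,
    alpha_end = alpha_end, cpg_mean_spacing = cpg_mean_spacing,
    baseline_meth = baseline_meth, dip_meth = dip_meth,
    n_dips = as.integer(n_dips), dip_length_range = dip_length_range,
    edge_ramp = edge_ramp, mean_coverage = mean_coverage,
    seed = as.integer(seed), chrom = chrom, region_start = region_start
  ), class = "sim_params")
}

# Place n non-overlapping dips of the requested lengths wholly inside the
# alpha array, rejection-sampling start positions.
.place_dips <- function(params) {
  n <- params$n_dips
  if (n == 0L) return(genomic_interval("x", 0, 1)[0, ])
  lens <- round(stats::runif(n, params$dip_length_range[1],
                             params$dip_length_range[2]))
  placed <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in 1:200) {
      s <- round(stats::runif(1, params$alpha_start,
                              params$alpha_end - lens[k]))
      e <- s + lens[k]
      # keep dips apart by at least one ramp width so they stay distinct
      if (nrow(placed) == 0 ||
          all(e + params$edge_ramp <= placed[, 1] |
                s - params$edge_ramp >= placed[, 2])) {
        placed <- rbind(placed, c(s, e))
        ok <- TRUE
        break
      }
    }
    if (!ok) cdr_stop("could not place non-overlapping dips in alpha array", "usage")
  }
  placed <- placed[order(placed[, 1]), , drop = FALSE]
  genomic_interval(params$chrom, placed[, 1], placed[, 2],
                   name = sprintf("dip_%d", seq_len(n)))
}

# True per-position methylation: baseline outside dips, dip floor inside,
# linear ramps of width edge_ramp just inside each dip's edges.
.true_meth <- function(pos, truth, params) {
  p <- rep(params$baseline_meth, length(pos))
  ramp <- params$edge_ramp
  for (k in seq_len(nrow(truth))) {
    s <- truth$start[k]
    e <- truth$end[k]
    inside <- pos >= s & pos < e
    if (!any(inside)) next
    x <- pos[inside]
    r <- pmin(ramp, (e - s) / 2)  # ramps never cross in a short dip
    depth <- params$baseline_meth - params$dip_meth
    frac <- pmin(1, pmin(x - s, e - x) / r)  # 0 at edge -> 1 at core
    p[inside] <- params$baseline_meth - depth * frac
  }
  p
}

#' Simulate a centromeric methylation region with planted CDRs
#'
#' CpG positions are drawn with geometric inter-site spacing. Per-CpG valid
#' coverage is Poisson(`mean_coverage`); the methylated-read count is
#' Binomial(coverage, p(x)) where p(x) is the true methylation level at the
#' site (baseline outside dips, dip floor inside, linear edge ramps).
#' Zero-coverage sites are not emitted (a pileup would not report them).
#' Annotations cover the alpha array with "ALR/Alpha" and the flanks with
#' HSat labels, so the flanking sequence carries CpGs but no alpha-satellite.
#'
#' @param params a [sim_params()] object.
#' @return list with `records` (methylation records), `annotations` (repeat
#'   annotation data.frame), `truth` (planted dip intervals), and `region`
#'   (the 1-row region of interest interval). Fully reproducible from
#'   `params$seed`.
#' @export
simulate_region <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  region <- genomic_interval(params$chrom, params$region_start,
                             params$region_start + params$region_length,
                             name = "sim_region")
  truth <- .place_dips(params)
  # geometric gaps with mean cpg_mean_spacing (gap >= 1 bp)
  n_exp <- ceiling(params$region_length / params$cpg_mean_spacing * 1.25) + 100
  gaps <- stats::rgeom(n_exp, prob = 1 / params$cpg_mean_spacing) + 1
  pos <- params$region_start + cumsum(gaps)
  pos <- pos[pos < region$end - 1]
  p_true <- .true_meth(pos, truth, params)
  cov <- stats::rpois(length(pos), params$mean_coverage)
  nmod <- stats::rbinom(length(pos), cov, p_true)
  keep <- cov > 0
  records <- data.frame(
    chrom = params$chrom, start = pos[keep], end = pos[keep] + 1,
    mod_code = "m", strand = ".", valid_cov = cov[keep],
    n_mod = nmod[keep], freq = nmod[keep] / cov[keep],
    stringsAsFactors = FALSE
  )
  annotations <- data.frame(
    chrom = params$chrom,
    start = c(region$start, params$alpha_start, params$alpha_end),
    end = c(params$alpha_start, params$alpha_end, region$end),
    repeat_name = c("HSAT", "ALR/Alpha", "HSAT"),
    repeat_class = "Satellite", stringsAsFactors = FALSE
  )
  annotations <- annotations[annotations$end > annotations$start, , drop = FALSE]
  list(records = records, annotations = annotations, truth = truth,
       region = region)
}

#' Write a simulated region to disk as a fixture directory
#'
#' Emits the exact dialects the io readers consume: `methyl.bedmethyl`
#' (extended 12-column bedMethyl, percent to 2 decimals), `repeats.bed`
#' (BED5 with repeat name and class), `truth.bed`, and `region.bed`.
#'
#' @param sim list from [simulate_region()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bedmethyl = file.path(out_dir, "methyl.bedmethyl"),
    repeats = file.path(out_dir, "repeats.bed"),
    truth = file.path(out_dir, "truth.bed"),
    region = file.path(out_dir, "region.bed")
  )
  r <- sim$records
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0,0,0\t%d\t%.2f\t%d",
    r$chrom, as.integer(r$start), as.integer(r$end), r$mod_code,
    as.integer(r$valid_cov), r$strand, as.integer(r$start),
    as.integer(r$end), as.integer(r$valid_cov), 100 * r$freq,
    as.integer(r$n_mod)), paths["bedmethyl"])
  a <- sim$annotations
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", a$chrom, as.integer(a$start),
                     as.integer(a$end), a$repeat_name, a$repeat_class),
             paths["repeats"])
  t <- sim$truth
  if (nrow(t) == 0L) {
    cat("", file = paths["truth"])
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s", t$chrom, as.integer(t$start),
                       as.integer(t$end), t$name), paths["truth"])
  }
  g <- sim$region
  writeLines(sprintf("%s\t%d\t%d\t%s", g$chrom, as.integer(g$start),
                     as.integer(g$end), g$name), paths["region"])
  invisible(paths)
}
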