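# Per-region diagnostic figure: three vertically stacked panels sharing the
# genomic x-axis - (top) repeat-annotation blocks with a bar over each CDR
# call, (middle) per-bin mean methylation frequency with the regional median
# as a reference line, (bottom) per-bin total and methylated read coverage.
# CDR x-spans are shaded in all panels. Base graphics keep the figure light
# and fully deterministic.

# fixed default palette keyed by repeat name; ALR/Alpha visually distinct
.repeat_palette <- function(names) {
  pal <- c("ALR/Alpha" = "#D55E00", "HSAT" = "#56B4E9", "HSAT2" = "#56B4E9",
           "HSAT3" = "#0072B2", "BSAT" = "#009E73", "GSAT" = "#CC79A7")
  cols <- pal[names]
  cols[is.na(cols)] <- "#999999"
  unname(cols)
}

#' Render the multi-track region plot
#'
#' @param profile an annotated `binned_profile`.
#' @param annotations repeat annotation data.frame for the region.
#' @param calls call data.frame from [call_cdrs()] (may have zero rows).
#' @param output_path image file path.
#' @param image_format `"png"`, `"svg"`, or `"pdf"`.
#' @param sample_name label used in the figure title.
#' @return invisibly, the figure's data model: a list with the `shaded`
#'   spans (exactly the call intervals), the median reference value, and the
#'   panel contents; useful for programmatic checks. Inputs are never
#'   mutated.
#' @export
render_region_plot <- function(profile, annotations, calls,
                               output_path,
                               image_format = c("png", "svg", "pdf"),
                               sample_name = "sample") {
  stopifnot(inherits(profile, "binned_profile"))
  image_format <- tryCatch(match.arg(image_format),
                           error = function(e) cdr_stop(
                             sprintf("unknown image format '%s'", image_format[1L]),
                             "usage"))
  region <- profile$region
  bins <- profile$bins
  if (nrow(bins) == 0L) cdr_stop("empty profile", "usage")
  if (!dir.exists(dirname(output_path))) {
    cdr_stop(paste0("output directory does not exist: ", dirname(output_path)),
             "usage")
  }
  ann <- annotations[annotations$chrom == region$chrom &
                       .overlaps(annotations$start, annotations$end,
                                 region$start, region$end), , drop = FALSE]
  med <- tryCatch(signal_stats(alpha_signal(profile))$median,
                  cdr_empty_error = function(e) NA_real_)
  fig_data <- list(
    region = region,
    shaded = calls[, c("chrom", "start", "end"), drop = FALSE],
    median = med,
    methylation = bins[, c("start", "end", "mean_freq", "is_valid")],
    coverage = bins[, c("start", "end", "mean_valid_cov", "mean_mod_cov")],
    annotations = ann
  )
  dev <- switch(image_format,
    png = function(p) grDevices::png(p, width = 1600, height = 900, res = 130),
    svg = function(p) grDevices::svg(p, width = 12, height = 7),
    pdf = function(p) grDevices::pdf(p, width = 12, height = 7)
  )
  ok <- tryCatch({ dev(output_path); TRUE },
                 error = function(e) FALSE)
  if (!ok) cdr_stop(paste0("cannot open output device at ", output_path), "usage")
  on.exit(grDevices::dev.off(), add = TRUE)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old), add = TRUE)
  graphics::layout(matrix(1:3, ncol = 1), heights = c(1.1, 2.2, 2.2))
  xlim <- c(region$start, region$end)
  mids <- (bins$start + bins$end) / 2
  shade <- function() {
    for (k in seq_len(nrow(calls))) {
      graphics::rect(calls$start[k], graphics::par("usr")[3],
                     calls$end[k], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("#E69F00", 0.25), border = NA)
    }
  }

  # panel 1: repeat annotation + CDR bars
  graphics::par(mar = c(0.5, 4.5, 2.5, 1))
  graphics::plot(NA, xlim = xlim, ylim = c(0, 2), xaxt = "n", yaxt = "n",
                 xlab = "", ylab = "repeats", bty = "n",
                 main = sprintf("%s  %s:%s-%s", sample_name, region$chrom,
                                format(region$start, big.mark = ","),
                                format(region$end, big.mark = ",")))
  shade()
  if (nrow(ann) > 0L) {
    graphics::rect(pmax(ann$start, region$start), 0.2,
                   pmin(ann$end, region$end), 0.9,
                   col = .repeat_palette(ann$repeat_name), border = NA)
  }
  for (k in seq_len(nrow(calls))) {
    graphics::segments(calls$start[k], 1.5, calls$end[k], 1.5,
                       lwd = 6, col = "black", lend = 1)
    graphics::text((calls$start[k] + calls$end[k]) / 2, 1.9, "CDR", cex = 0.8)
  }

  # panel 2: binned methylation frequency; invalid bins left blank
  graphics::par(mar = c(0.5, 4.5, 0.5, 1))
  mf <- ifelse(bins$is_valid, bins$mean_freq, NA_real_)
  graphics::plot(mids, mf, type = "n", xlim = xlim, ylim = c(0, 1),
                 xaxt = "n", xlab = "", ylab = "mean CpG methylation")
  shade()
  graphics::lines(mids, mf, col = "#0072B2")
  graphics::points(mids[bins$is_alpha], mf[bins$is_alpha],
                   pch = 16, cex = 0.4, col = "#D55E00")
  if (!is.na(med)) graphics::abline(h = med, lty = 2, col = "grey40")

  # panel 3: per-bin total and methylated coverage
  graphics::par(mar = c(4, 4.5, 0.5, 1))
  ymax <- max(bins$mean_valid_cov, 1)
  graphics::plot(mids, bins$mean_valid_cov, type = "n", xlim = xlim,
                 ylim = c(0, ymax * 1.05),
                 xlab = sprintf("position on %s (bp)", region$chrom),
                 ylab = "mean read coverage")
  shade()
  graphics::lines(mids, bins$mean_valid_cov, col = "grey30")
  graphics::lines(mids, bins$mean_mod_cov, col = "#D55E00")
  graphics::legend("topright", legend = c("total", "methylated"),
                   col = c("grey30", "#D55E00"), lty = 1, bty = "n", cex = 0.8)

  invisible(fig_data)
}
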