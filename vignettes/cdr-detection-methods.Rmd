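---
title: "Calling centromere dip regions from binned CpG methylation"
author: "cdrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling centromere dip regions from binned CpG methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrscan)
```

## The signal and its assumptions

A sequence-resolved centromere behaves, epigenetically, like a
hypermethylated plateau: CpG methylation across the α-satellite
higher-order-repeat (HOR) array sits high and relatively flat, and the
centromere dip region (CDR) — the CENP-A/kinetochore site — appears as a
localized valley tens of kilobases wide. `cdrscan` assumes exactly this
regime:

* the assembly is contiguous through the target region, so per-CpG pileup
  coordinates are meaningful;
* methylation is summarized per CpG as a *frequency* (fraction of valid
  reads calling 5mC), already aggregated by an upstream modified-base
  pileup tool — the package consumes bedMethyl, it does not pile up BAMs;
* the repeat annotation marks α-satellite as `ALR/Alpha`; detection uses
  α-bins only, so flanking pericentromeric sequence (HSat and other
  satellites) can and should be included in the target region without
  affecting calls — it only improves the diagnostic plot.

The caller is deliberately rule-based, not model-based. There is no
significance or FDR machinery because the underlying signal admits no
obvious null: methylation along a HOR array is strongly autocorrelated and
array-specific. The rules below are transparent and each is exposed as a
parameter.

## The detection rules

Let `f_i` be the mean CpG methylation frequency of bin `i` (sequential
5-kbp bins anchored at the region start; a bin's value is the *unweighted*
mean over the CpGs whose start coordinate falls in it; bins with no CpGs
are excluded everywhere). Restrict to bins overlapping `ALR/Alpha` by at
least 1 bp, and let `m`, `μ`, `σ` be the median, mean, and population
standard deviation of that α-signal.

1. **Depth.** Bin `i` is a candidate iff `f_i < m·(1 − d)`, `d = 0.34` by
   default. Maximal runs of *genomically* adjacent candidate bins form one
   candidate dip; a bin excluded for having no CpGs (or no α-satellite)
   splits a run, so a call never silently spans an annotation gap.
2. **Prominence.** At the dip's deepest bin (leftmost on ties, for
   determinism) the topographic prominence is computed on the α-signal:
   walk left and right until a strictly lower value or the signal end,
   record the maximum climbed on each side, and take
   `min(left, right) − f_min`. A side with no bins at all imposes no col.
   Dips with prominence `< 0.30·m` are dropped. This is what protects
   against subregions of uniformly low methylation: their candidate bins
   sit in a basin with no walls, so their prominence is near zero even
   though they pass the depth rule.
3. **Extension.** Each surviving call grows outward one bin at a time while
   the next bin is a valid α-bin with value below `μ − k·σ` (`k = 1`).
   Smaller `k` never shrinks a call.
4. **Merging.** Calls separated by at most `merge_gap_bins = 1` bin merge;
   a single noisy bin inside one biological CDR should not split the call.

### Why the thresholds are median-relative

The two headline parameters (0.34 and 0.30) are interpreted as fractions
*of the regional median*, not absolute frequencies: the candidate cutoff is
`m·(1 − 0.34)` and the prominence cutoff `0.30·m`. A dip must therefore be
deep *relative to its own array*, which keeps behavior sensible across
arrays whose baseline methylation differs. This reading also reproduces the
documented failure directions — a larger depth fraction misses shallowly
hypomethylated CDRs, a smaller one admits coverage noise. Because the
absolute reading is also defensible (and makes the prominence filter a
fixed ruler across regions), both thresholds switch to absolute mode with
`detection_params(absolute_thresholds = TRUE)`.

Two further choices were genuinely open and are resolved as follows:
prominence is computed on the α-subsequence (gap-removed signal), since
detection is defined on α-bins only; and extension statistics (`μ`, `σ`)
come from the whole region's α-bins, not a per-candidate neighborhood, so
all calls in a region share one reference level.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `bin_size` | 5000 | bp | methylation averaging window; also the output coordinate resolution |
| `depth_fraction` | 0.34 | fraction of median | required dip depth below `m` |
| `prominence_fraction` | 0.30 | fraction of median | minimum topographic prominence |
| `edge_sd_multiplier` | 1.0 | SDs | boundary-extension level `μ − k·σ` |
| `merge_gap_bins` | 1 | bins | maximum gap between merged calls |
| `boundary_tol` (evaluation) | 5000 | bp | slack before a boundary deficit makes a call "partial" |

Coverage quality matters more than any threshold: at low or uneven
coverage, per-bin means are noisy and spurious candidates appear. The
diagnostic plot shows the per-bin total and methylated coverage precisely
so such calls can be excluded by inspection.

## What the synthetic generator emulates — and what it does not

`simulate_region()` draws the stated world used throughout the tests: a
3-Mbp region whose central 2 Mbp is `ALR/Alpha` (for regions shorter than
2 Mbp the default array is the central two-thirds), CpG sites at geometric
spacing with mean 60 bp, Poisson(30) valid coverage per CpG, and
methylated-read counts that are Binomial in the true local methylation —
0.85 baseline, 0.10 at the dip floor, with 10-kbp *linear* ramps at dip
edges. Linear (rather than sigmoid) ramps are the simplest shape that
exercises the boundary-extension rule; the width is configurable. Flanks
carry CpGs too, so the recommendation to include flanking sequence is
exercisable, and a null world (`dip_meth = baseline_meth`) is allowed for
testing that nothing is called when nothing is planted.

The generator does **not** emulate several features of real centromeres:
mapping-induced coverage waves and collapses, array-scale methylation
trends, strand-split bedMethyl rows (available separately via
`merge_strand_records()` fixtures), CpG-density variation between monomers,
or secondary shallow dips. A green planted-dip test therefore establishes
that the rules recover clean dips of the stated geometry at 30× coverage —
it does not certify performance on degraded real data, which is what the
coverage track and manual review are for.

## Numerical and degenerate-case choices

* Methylation is a fraction in [0,1] internally; bedMethyl percent is
  divided by 100 on read, and a reconstructed modified-read count
  (`round(cov·pct/100)`) is used when the 11-column dialect omits it.
* Population (1/n) SD, since the α-bins are the full population of the
  region; at typical n ≈ 400–600 the sample/population difference is
  negligible, but the choice is fixed for determinism.
* Even-length medians are midpoints of the two central order statistics.
* Ties at a dip's deepest bin resolve leftmost; candidate runs are ordered
  by genomic position; the output BED is sorted by `(chrom, start)` — the
  whole pipeline is byte-deterministic for fixed inputs.
* The prominence cutoff is inclusive (`≥`), the depth cutoff strict (`<`);
  a value exactly at the candidate threshold is *not* a candidate.
* A region with no α-annotated valid bin raises a structured empty-signal
  error (CLI exit code 4) rather than returning an empty call set, because
  silence would be indistinguishable from a confidently dip-free array.
* The last bin of a region may be shorter than `bin_size` and is treated
  like any other bin; discarding it could truncate a boundary CDR.

## Known limitations

* No sub-bin boundary refinement: call edges land on the 5-kbp grid.
* No joint calling across samples or haplotypes.
* The evaluation categories (correct / partial / missed / erroneous)
  operationalize with a fixed overlap-and-tolerance rule what is, in
  practice, a manual review protocol; the two agree only to the extent the
  tolerance (default one bin) matches a reviewer's judgment.
* RepeatMasker and the modified-base pileup are upstream interfaces:
  `cdrscan` parses their outputs (`.out` and bedMethyl) but never runs
  them.
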