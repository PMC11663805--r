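# cdrscan

Detection of **centromere dip regions (CDRs)** from long-read CpG
methylation pileups.

## The problem

Human centromeres are built from near-identical ~171-bp α-satellite repeats
organized into higher-order-repeat (HOR) arrays. Across a fully assembled
HOR array the CpG methylation level is high almost everywhere — except for
one or more localized hypomethylated windows, the centromere dip regions.
CDRs coincide with CENP-A chromatin and mark the kinetochore attachment
site, so locating them is the first step in most centromere epigenetics
analyses. With methylation-aware long reads (ONT or PacBio HiFi) aligned to
a contiguous assembly, a per-CpG pileup in bedMethyl format carries enough
signal to call CDRs directly; `cdrscan` is for anyone with such a pileup, a
BED of centromeric target regions, and a repeat annotation.

## The method

For each target region (an α-satellite HOR array ± flanks), with per-bin
mean CpG methylation frequency `f` computed in sequential 5-kbp bins
(empty bins excluded) and restricted to bins overlapping `ALR/Alpha`
annotation:

1. **Candidate selection** — let `m` = median of the α-bin signal. A bin is
   a candidate iff `f < m·(1 − d)` with depth fraction `d = 0.34`; maximal
   runs of genomically adjacent candidate bins form one candidate dip each.
2. **Prominence filter** — each dip's topographic prominence (depth of the
   valley relative to the lowest col separating it from a deeper valley or
   the signal edge, computed on the inverted signal) must satisfy
   `prominence ≥ 0.30·m`. This removes low-confidence calls where
   methylation is uniformly low across a subregion.
3. **Boundary extension** — each surviving call grows outward bin by bin
   while the next α-bin stays below `mean − 1·SD` of the α-signal.
4. **Merge** — calls separated by ≤ 1 bin are merged.

Outputs are a BED file of calls (name = region label, score = minimum bin
frequency × 1000) and a three-panel diagnostic figure per region: repeat
annotation with CDR bars, binned methylation with the median reference
line, and total/methylated read coverage, with every call span shaded.

All thresholds are exposed (`detection_params()`), including absolute
(non-median-relative) variants of `d` and the prominence cutoff.

## Worked example

```r
library(cdrscan)

# a 3-Mbp synthetic region: central 2-Mbp alpha-satellite array,
# baseline methylation 0.85, one planted 110-kbp dip to 0.10, 30x coverage
sim <- simulate_region(sim_params(seed = 7, dip_length_range = c(110000, 110000)))

profile <- bin_methylation(sim$records, sim$region)
profile <- annotate_alpha_bins(profile, sim$annotations)
profile
#> binned_profile: cen_sim:0-3000000, 600 bins of 5000 bp (600 valid, 400 alpha)

calls <- call_cdrs(profile)
calls
#>     chrom   start     end       name   min_freq prominence seed_bin_index
#> 1 cen_sim 2370000 2475000 sim_region 0.08556372  0.7668988            491
#>   region_median region_mean region_sd
#> 1      0.849158   0.8118752 0.1605734

classify_calls(calls, sim$truth, boundary_tol = 5000)
#> eval_result: 1 truth / 1 calls | correct 1, partial 0, missed 0, erroneous 0 | precision 1.000, recall 1.000
```

The planted dip (truth: `cen_sim:2369039-2479039`) is recovered as a single
call on the 5-kbp bin grid: its deepest bin (index 491) sits at methylation
0.086 against a regional α-bin median of 0.849, with topographic prominence
0.77 — far above the 0.30 × median ≈ 0.25 cutoff. The call covers the truth
interval to within one bin at each boundary, so the evaluator classifies it
as *correct*.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cdrscan", package = "cdrscan"))')
Rscript "$CLI" simulate --seed 7 --out fixtures/
Rscript "$CLI" call --bedmethyl fixtures/methyl.bedmethyl \
    --regions fixtures/region.bed --repeats fixtures/repeats.bed \
    --out results/ --sample demo --plot png
Rscript "$CLI" evaluate --calls results/demo_cdrs.bed --truth fixtures/truth.bed
```

`call` accepts `--bin-size`, `--depth-fraction`, `--prominence-fraction`,
`--edge-sd`, `--merge-gap`, `--absolute-thresholds`, `--combine-strands`,
`--repeat-dialect bed|rmout`, `--skip-errors` and a YAML/JSON `--config`
file mirroring the flags (explicit flags win). Exit codes: 0 success,
2 usage, 3 parse, 4 empty signal.

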