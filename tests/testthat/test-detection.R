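# detection: alpha signal, stats, prominence, candidate selection, filters,
# boundary extension, merging, and the orchestrated caller.

test_that("alpha_signal filters to valid alpha-bins in genomic order", {
  prof <- make_profile(c(0.8, 0.7, 0.6, 0.5, 0.4),
                       alpha = c(FALSE, TRUE, TRUE, FALSE, TRUE))
  sig <- alpha_signal(prof)
  expect_equal(sig$bin_index, c(2L, 3L, 5L))
  expect_equal(sig$value, c(0.7, 0.6, 0.4))
  # all-alpha profile is the identity sequence
  all_a <- alpha_signal(make_profile(c(0.8, 0.7)))
  expect_equal(all_a$bin_index, 1:2)
  # invalid bins are dropped even when alpha
  prof2 <- make_profile(c(0.8, NA, 0.6), alpha = rep(TRUE, 3))
  expect_equal(alpha_signal(prof2)$bin_index, c(1L, 3L))
  # no alpha signal at all is a structured error
  expect_error(alpha_signal(make_profile(c(0.8, 0.7), alpha = c(FALSE, FALSE))),
               class = "cdr_empty_error")
})

test_that("signal_stats: median/mean/population-SD match direct formulas", {
  st <- signal_stats(data.frame(bin_index = 1:4, value = c(0.2, 0.8, 0.8, 0.8)))
  expect_equal(st$median, 0.8)
  expect_equal(st$mean, 0.65)
  expect_equal(st$n_alpha_bins, 4L)
  expect_equal(signal_stats(data.frame(bin_index = 1:3, value = rep(0.5, 3)))$sd, 0)
  # even-n median is the midpoint of the two central order statistics
  expect_equal(signal_stats(data.frame(bin_index = 1:4,
                                       value = c(0.1, 0.3, 0.5, 0.9)))$median, 0.4)
  set.seed(3)
  v <- runif(1000)
  st2 <- signal_stats(data.frame(bin_index = seq_along(v), value = v))
  sv <- sort(v)
  expect_equal(st2$median, (sv[500] + sv[501]) / 2, tolerance = 1e-12)
  expect_equal(st2$mean, sum(v) / 1000, tolerance = 1e-12)
  expect_equal(st2$sd, sqrt(sum((v - sum(v) / 1000)^2) / 1000), tolerance = 1e-12)
})

test_that("valley_prominence follows the left/right-walk rule", {
  v <- c(0.8, 0.2, 0.7, 0.1, 0.9)
  # no value lower than 0.1 exists: both sides use their full-side maximum
  expect_equal(valley_prominence(v, 4), 0.70)
  # right walk from 0.2 stops at 0.1; left side reaches the edge
  expect_equal(valley_prominence(v, 2), 0.50)
  # strictly decreasing: prominence at the last point spans the whole signal
  mono <- c(0.9, 0.7, 0.5, 0.3)
  expect_equal(valley_prominence(mono, 4), 0.6)
  expect_error(valley_prominence(v, 3), class = "cdr_usage_error")  # not a minimum
  expect_error(valley_prominence(v, 9), class = "cdr_usage_error")
})

test_that("valley_prominence matches the brute-force oracle on random signals", {
  set.seed(19)
  grid <- seq(0.1, 0.9, by = 0.1)
  for (case in 1:400) {
    n <- sample(2:12, 1)
    v <- sample(grid, n, replace = TRUE)
    for (idx in seq_len(n)) {
      is_min <- (idx == 1 || v[idx - 1] >= v[idx]) &&
        (idx == n || v[idx + 1] >= v[idx])
      if (is_min) {
        expect_equal(valley_prominence(v, idx), prominence_oracle(v, idx))
      }
    }
  }
})

test_that("find_candidate_valleys selects runs below the median-relative depth", {
  # stated rule: with median 0.75 and depth 0.34 the threshold is 0.495
  sig <- data.frame(bin_index = 1:4, value = c(0.70, 0.45, 0.40, 0.70))
  st <- list(median = 0.75, mean = 0.6, sd = 0.1, n_alpha_bins = 4L)
  cand <- find_candidate_valleys(sig, st, detection_params())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$i, 2L)
  expect_equal(cand$j, 3L)
  expect_equal(cand$min_value, 0.40)
  expect_equal(cand$min_index, 3L)
  # flat signal at the median: nothing below the threshold
  flat <- data.frame(bin_index = 1:5, value = rep(0.75, 5))
  expect_equal(nrow(find_candidate_valleys(flat, st, detection_params())), 0L)
  # two runs separated by an above-threshold bin stay distinct
  sig2 <- data.frame(bin_index = 1:7,
                     value = c(0.8, 0.3, 0.35, 0.8, 0.31, 0.3, 0.8))
  cand2 <- find_candidate_valleys(sig2, st, detection_params())
  expect_equal(nrow(cand2), 2L)
  expect_equal(cand2$min_index, c(2L, 6L))
  # ties at the deepest bin resolve to the leftmost
  expect_equal(find_candidate_valleys(
    data.frame(bin_index = 1:4, value = c(0.8, 0.3, 0.3, 0.8)), st,
    detection_params())$min_index, 2L)
  # a gap in genomic bin indices splits a run even below threshold
  sig3 <- data.frame(bin_index = c(1L, 2L, 4L, 5L),
                     value = c(0.3, 0.32, 0.33, 0.3))
  expect_equal(nrow(find_candidate_valleys(sig3, st, detection_params())), 2L)
  # absolute-threshold mode compares values to depth_fraction directly
  abs_p <- detection_params(depth_fraction = 0.42, absolute_thresholds = TRUE)
  expect_equal(find_candidate_valleys(sig, st, abs_p)$min_value, 0.40)
  expect_equal(nrow(find_candidate_valleys(sig, st, abs_p)), 1L)
})

test_that("candidate selection + prominence match exhaustive oracle on small signals", {
  set.seed(23)
  grid <- seq(0.1, 0.9, by = 0.1)
  params <- detection_params()
  for (case in 1:300) {
    n <- sample(3:12, 1)
    v <- sample(grid, n, replace = TRUE)
    # random subset of bins present (gaps exercise genomic adjacency)
    present <- sort(sample(seq_len(n + 3), n))
    sig <- data.frame(bin_index = present, value = v)
    st <- signal_stats(sig)
    got <- find_candidate_valleys(sig, st, params)
    want <- candidates_oracle(sig, st$median, params$depth_fraction)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("filter_by_prominence applies the median-scaled cutoff inclusively", {
  st <- list(median = 0.75, mean = 0.6, sd = 0.1, n_alpha_bins = 10L)
  cand <- data.frame(i = c(1L, 5L, 8L), j = c(2L, 6L, 9L),
                     min_index = c(1L, 5L, 8L), min_value = c(0.3, 0.4, 0.35),
                     prominence = c(0.50, 0.10, 0.225))
  kept <- filter_by_prominence(cand, NULL, st, detection_params())
  # cutoff 0.30 * 0.75 = 0.225; 0.50 kept, 0.10 dropped, boundary value kept
  expect_equal(kept$prominence, c(0.50, 0.225))
  # absolute mode uses the raw prominence cutoff
  kept_abs <- filter_by_prominence(cand, NULL, st,
                                   detection_params(prominence_fraction = 0.3,
                                                    absolute_thresholds = TRUE))
  expect_equal(kept_abs$prominence, 0.50)
})

test_that("extend_boundaries grows calls to the mean-minus-SD level", {
  # mean 0.70, sd 0.10, multiplier 1 -> extension threshold 0.60
  vals <- c(0.8, 0.8, 0.3, 0.55, 0.58, 0.65, 0.8)
  prof <- make_profile(vals)
  st <- list(median = 0.75, mean = 0.70, sd = 0.10, n_alpha_bins = 7L)
  cand <- data.frame(i = 3L, j = 3L, min_index = 3L, min_value = 0.3,
                     prominence = 0.5)
  ext <- extend_boundaries(cand, prof, st, detection_params())
  expect_equal(ext$i, 3L)
  expect_equal(ext$j, 5L)  # 0.55 and 0.58 < 0.60; 0.65 stops the walk
  # multiplier 0 raises the threshold to the mean: extensions never shrink
  ext0 <- extend_boundaries(cand, prof, st,
                            detection_params(edge_sd_multiplier = 0))
  expect_true(ext0$i <= ext$i && ext0$j >= ext$j)
  expect_equal(ext0$j, 6L)
  # extension never crosses a non-alpha or invalid bin
  prof2 <- make_profile(vals, alpha = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(extend_boundaries(cand, prof2, st, detection_params())$j, 3L)
  prof3 <- make_profile(replace(vals, 4, NA))
  expect_equal(extend_boundaries(cand, prof3, st, detection_params())$j, 3L)
  # extension stops at the profile edge
  cand_edge <- data.frame(i = 1L, j = 1L, min_index = 1L, min_value = 0.3,
                          prominence = 0.5)
  prof4 <- make_profile(c(0.3, 0.5, 0.8))
  ext4 <- extend_boundaries(cand_edge, prof4, st, detection_params())
  expect_equal(c(ext4$i, ext4$j), c(1L, 2L))
})

test_that("extend_boundaries covers every below-threshold bin of a planted ramp", {
  # sigmoid-edged dip across bins; scan oracle: the extended call must cover
  # at least the contiguous alpha-bins below T around the seed
  x <- seq(-6, 6, length.out = 41)
  vals <- 0.85 - 0.75 / (1 + exp(3 * (abs(x) - 3)))
  prof <- make_profile(vals)
  sig <- alpha_signal(prof)
  st <- signal_stats(sig)
  params <- detection_params()
  cand <- find_candidate_valleys(sig, st, params)
  expect_equal(nrow(cand), 1L)
  ext <- extend_boundaries(cand, prof, st, params)
  T_ext <- st$mean - st$sd
  seed <- cand$min_index
  # direct scan: contiguous below-T run containing the seed
  lo <- seed; while (lo > 1 && vals[lo - 1] < T_ext) lo <- lo - 1
  hi <- seed; while (hi < length(vals) && vals[hi + 1] < T_ext) hi <- hi + 1
  expect_true(ext$i <= lo && ext$j >= hi)
})

test_that("merge_calls joins overlapping/nearby calls and matches the union oracle", {
  params <- detection_params()
  a <- data.frame(i = 1L, j = 5L, min_index = 3L, min_value = 0.2, prominence = 0.5)
  b <- data.frame(i = 5L, j = 8L, min_index = 7L, min_value = 0.3, prominence = 0.6)
  m <- merge_calls(rbind(a, b), params)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$i, m$j), c(1L, 8L))
  expect_equal(m$min_value, 0.2)   # deepest member wins
  expect_equal(m$min_index, 3L)
  expect_equal(m$prominence, 0.6)  # max over members
  # calls 10 bins apart with merge_gap_bins = 1 stay separate
  c2 <- data.frame(i = 19L, j = 20L, min_index = 19L, min_value = 0.3,
                   prominence = 0.4)
  expect_equal(nrow(merge_calls(rbind(a, c2), params)), 2L)
  # gap exactly merge_gap_bins merges (one lone bin between calls)
  d <- data.frame(i = 7L, j = 9L, min_index = 8L, min_value = 0.25,
                  prominence = 0.3)
  expect_equal(nrow(merge_calls(rbind(a, d), params)), 1L)
  # random sets vs the fixed-point union oracle
  set.seed(31)
  for (case in 1:60) {
    k <- sample(1:6, 1)
    i <- sort(sample(1:40, k))
    ranges <- data.frame(i = i, j = i + sample(0:6, k, replace = TRUE),
                         min_index = i, min_value = runif(k, 0.1, 0.4),
                         prominence = runif(k))
    gap <- sample(0:2, 1)
    got <- merge_calls(ranges, detection_params(merge_gap_bins = gap))
    want <- merge_oracle(ranges[, c("i", "j")], gap)
    expect_equal(got[, c("i", "j")], want, ignore_attr = TRUE)
  }
})

test_that("call_cdrs finds planted dips and nothing in flat regions", {
  set.seed(5)
  sim <- simulate_region(sim_params(seed = 5,
                                    dip_length_range = c(110000, 110000)))
  prof <- annotate_alpha_bins(bin_methylation(sim$records, sim$region),
                              sim$annotations)
  calls <- call_cdrs(prof)
  expect_equal(nrow(calls), 1L)
  ov <- min(calls$end, sim$truth$end) - max(calls$start, sim$truth$start)
  expect_gt(ov / (sim$truth$end - sim$truth$start), 0.9)
  expect_lt(calls$min_freq, calls$region_median)
  expect_true(calls$start >= sim$region$start && calls$end <= sim$region$end)
  # fully hypermethylated region: zero calls
  flat <- simulate_region(sim_params(seed = 6, n_dips = 0L))
  pflat <- annotate_alpha_bins(bin_methylation(flat$records, flat$region),
                               flat$annotations)
  expect_equal(nrow(call_cdrs(pflat)), 0L)
  # two well-separated dips produce two separate calls
  p2 <- sim_params(seed = 9, region_length = 4e6, alpha_start = 5e5,
                   alpha_end = 3.5e6, n_dips = 2L,
                   dip_length_range = c(100000, 100000))
  sim2 <- simulate_region(p2)
  gap_bp <- sim2$truth$start[2] - sim2$truth$end[1]
  expect_gt(gap_bp, 10000)  # generator keeps dips apart
  prof2 <- annotate_alpha_bins(bin_methylation(sim2$records, sim2$region),
                               sim2$annotations)
  calls2 <- call_cdrs(prof2)
  expect_equal(nrow(calls2), 2L)
})

test_that("call_cdrs attaches regional statistics and respects labels", {
  vals <- c(rep(0.85, 8), 0.2, 0.15, 0.2, rep(0.85, 8))
  prof <- make_profile(vals)
  calls <- call_cdrs(prof, region_label = "roi_1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$name, "roi_1")
  st <- signal_stats(alpha_signal(prof))
  expect_equal(calls$region_median, st$median)
  expect_equal(calls$region_mean, st$mean)
  expect_equal(calls$region_sd, st$sd)
  expect_equal(calls$min_freq, 0.15)
  # interval lies on the bin grid
  expect_equal((calls$end - calls$start) %% prof$bin_size, 0)
})
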