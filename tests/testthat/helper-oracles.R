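# Independent brute-force oracles the implementation is checked against.
# These deliberately use plain loops and direct formulas, not the package's
# vectorised code paths.

# Topographic valley prominence by literal application of the walk rule:
# step away from idx one position at a time, tracking the maximum seen,
# until a strictly lower value appears or the sequence ends; the edge side
# uses the maximum of the whole side.
prominence_oracle <- function(values, idx) {
  x <- values[idx]
  walk <- function(positions) {
    if (length(positions) == 0) return(Inf)  # empty side imposes no col
    seen <- numeric(0)
    for (k in positions) {
      if (values[k] < x) {
        return(if (length(seen) > 0) max(seen) else x)
      }
      seen <- c(seen, values[k])
    }
    max(seen)
  }
  left <- walk(rev(seq_len(idx - 1)))
  right <- walk(if (idx < length(values)) (idx + 1):length(values) else integer(0))
  min(left, right) - x
}

# Candidate valleys by exhaustive scan: mark below-threshold positions,
# group maximal runs of genomically adjacent bin indices, take the leftmost
# deepest bin of each run, attach its oracle prominence.
candidates_oracle <- function(signal, med, depth_fraction) {
  thr <- med * (1 - depth_fraction)
  below <- which(signal$value < thr)
  if (length(below) == 0) {
    return(data.frame(i = integer(0), j = integer(0), min_index = integer(0),
                      min_value = numeric(0), prominence = numeric(0)))
  }
  runs <- list()
  cur <- below[1]
  for (p in below[-1]) {
    last <- cur[length(cur)]
    if (signal$bin_index[p] == signal$bin_index[last] + 1) {
      cur <- c(cur, p)
    } else {
      runs[[length(runs) + 1]] <- cur
      cur <- p
    }
  }
  runs[[length(runs) + 1]] <- cur
  do.call(rbind, lapply(runs, function(ps) {
    deepest <- ps[which.min(signal$value[ps])]
    data.frame(i = signal$bin_index[ps[1]], j = signal$bin_index[ps[length(ps)]],
               min_index = signal$bin_index[deepest],
               min_value = signal$value[deepest],
               prominence = prominence_oracle(signal$value, deepest))
  }))
}

# Quadratic interval-overlap test: >= min_bp of overlap, half-open.
overlaps_oracle <- function(s1, e1, s2, e2, min_bp = 1) {
  (min(e1, e2) - max(s1, s2)) >= min_bp
}

# Union of bin-index ranges allowing gaps of <= gap bins, by repeated
# pairwise merging until a fixed point (independent of the sweep in
# merge_calls).
merge_oracle <- function(ranges, gap) {
  repeat {
    n <- nrow(ranges)
    if (n < 2) break
    merged <- FALSE
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        sep <- max(ranges$i[a], ranges$i[b]) - min(ranges$j[a], ranges$j[b]) - 1
        if (sep <= gap) {
          ranges$i[a] <- min(ranges$i[a], ranges$i[b])
          ranges$j[a] <- max(ranges$j[a], ranges$j[b])
          ranges <- ranges[-b, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  ranges[order(ranges$i), , drop = FALSE]
}
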