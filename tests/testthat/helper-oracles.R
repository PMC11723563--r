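# Independent brute-force oracles used across the suite. These re-derive the
# same quantities as the package operations with the simplest possible loops,
# so agreement is informative.

# O(n * w) sliding RMS
oracle_rms <- function(x, fs, window) {
  n <- length(x)
  w <- round(window * fs)
  half_l <- (w - 1) %/% 2
  half_r <- w - 1 - half_l
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_l)
    hi <- min(n, i + half_r)
    out[i] <- sqrt(mean(x[lo:hi]^2))
  }
  out
}

# run-length scanner: supra-threshold runs, gap merging, minimum duration
oracle_stage1 <- function(env, fs, threshold, min_duration, merge_gap) {
  n <- length(env)
  above <- env > threshold
  runs <- list()
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j + 1)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  gap <- round(merge_gap * fs)
  merged <- list()
  for (r in runs) {
    m <- length(merged)
    if (m > 0 && r[1] - merged[[m]][2] < gap) {
      merged[[m]][2] <- r[2]
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  min_len <- round(min_duration * fs)
  keep <- Filter(function(r) r[2] - r[1] >= min_len, merged)
  if (length(keep) == 0) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  do.call(rbind, lapply(keep, function(r) cbind(start = r[1], end = r[2])))
}

# per-sample peak counter (strict local maxima above threshold)
oracle_peak_count <- function(x, threshold) {
  n <- length(x)
  cnt <- 0
  for (i in seq_len(n)) {
    if (i > 1 && i < n && x[i] > x[i - 1] && x[i] > x[i + 1] &&
          x[i] > threshold) {
      cnt <- cnt + 1
    }
  }
  cnt
}

# connected components of the interval-overlap graph by explicit union-find
oracle_overlap_components <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && start[i] < end[j] && start[j] < end[i]) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# exact two-sided rank-sum p by full subset enumeration
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)])
  sets <- utils::combn(n, nx)
  ws <- apply(sets, 2, function(idx) sum(ranks[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# compact config for fast simulation tests
quick_config <- function(duration = 60, seed = 1, ...) {
  simulation_config(duration = duration, seed = seed, ...)
}

# match detected events to injected pulses by event midpoint
match_events <- function(events, train, fs) {
  mid <- (events$start_s + events$end_s) / 2
  vapply(seq_len(nrow(train)), function(i) {
    j <- which(mid >= train$onset[i] & mid <= train$onset[i] + train$d[i])
    if (length(j) == 0) NA_integer_ else j[1]
  }, integer(1))
}
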