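test_that("preprocessing passes the band, notches harmonics, kills stop-band", {
  fs <- 1000
  t <- seq(1 / fs, 10, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  gain_db <- function(f, band) {
    x <- sin(2 * pi * f * t)
    rec <- recording(matrix(x, 1), fs)
    y <- preprocess(rec, band)$data[1, ]
    sel <- 2000:8000 # avoid filter edges
    20 * log10(rms(y[sel]) / rms(x[sel]))
  }
  expect_lt(gain_db(180, "ripple"), -40)       # 3rd harmonic of 60 Hz notched
  expect_gt(gain_db(140, "ripple"), -1)        # pass band
  expect_lt(gain_db(300, "ripple"), -40)       # stop band
  expect_lt(gain_db(300, "fast_ripple"), -40)  # 5th harmonic notched
  expect_gt(gain_db(350, "fast_ripple"), -1)
  expect_lt(gain_db(150, "fast_ripple"), -40)
  expect_error(preprocess(recording(matrix(t, 1), 400), "fast_ripple"), "rate")
})

test_that("rms envelope matches the brute-force sliding window", {
  fs <- 1000
  expect_equal(rms_envelope(rep(2, 100), fs, 0.003)[5:96], rep(2, 92))
  expect_equal(rms_envelope(numeric(50), fs, 0.003), numeric(50))
  set.seed(1)
  x <- sin(2 * pi * 100 * (1:1000) / fs) + rnorm(1000, sd = 0.1)
  expect_equal(rms_envelope(x, fs, 0.003), oracle_rms(x, fs, 0.003))
  expect_equal(rms_envelope(x, fs, 0.021), oracle_rms(x, fs, 0.021))
  expect_error(rms_envelope(x, fs, 0.001), "2 samples")
})

test_that("stage 1 equals the brute-force run scanner on random envelopes", {
  fs <- 1000
  p <- detector_params()
  set.seed(7)
  for (trial in 1:50) {
    env <- abs(rnorm(1000, mean = 1, sd = 0.6))
    thr <- mean(env) + p$n_sd * sd(env)
    got <- stage1_candidates(env, fs, p)
    want <- oracle_stage1(env, fs, thr, p$min_duration, p$merge_gap)
    expect_equal(unname(got), unname(want))
  }
  # sub-minimum runs are rejected: a single 4 ms excursion
  env <- rep(0.1, 1000)
  env[500:503] <- 10
  expect_equal(nrow(stage1_candidates(env, fs, p, threshold = 1)), 0)
  # 6 ms is accepted
  env[500:505] <- 10
  expect_equal(nrow(stage1_candidates(env, fs, p, threshold = 1)), 1)
  # zero-variance segments are skipped, not errored
  out <- stage1_candidates(rep(1, 1000), fs, p)
  expect_equal(nrow(out), 0)
  expect_true(isTRUE(attr(out, "skipped")))
})

test_that("stage 2 counts supra-threshold peaks like the per-sample oracle", {
  fs <- 1000
  p <- detector_params()
  set.seed(8)
  for (trial in 1:50) {
    xf <- rnorm(1000)
    cand <- cbind(start = c(101, 501), end = c(300, 900))
    got <- stage2_qualify(xf, cand, fs, detector_params(min_peaks = 1),
                          threshold = 1)
    want <- vapply(seq_len(nrow(cand)), function(k) {
      oracle_peak_count(abs(xf[cand[k, 1]:(cand[k, 2] - 1)]), 1)
    }, numeric(1))
    expect_equal(got$n_peaks, want[want >= 1])
  }
  # six-peak rule: a burst with exactly 5 clean cycles fails, 6 passes
  mk <- function(ncyc) {
    x <- numeric(600)
    tt <- seq(0, ncyc / 100, by = 1 / fs)
    # half-sine lobes at 100 Hz -> one rectified peak per 5 ms lobe
    x[101:(101 + length(tt) - 1)] <- 5 * abs(sin(2 * pi * 50 * tt))
    x
  }
  cand <- cbind(start = 90L, end = 300L)
  p1 <- detector_params(min_peaks = 6)
  expect_equal(nrow(stage2_qualify(mk(5), cand, fs, p1, threshold = 1)), 0)
  expect_equal(nrow(stage2_qualify(mk(6), cand, fs, p1, threshold = 1)), 1)
  # no supra-threshold sample -> rejected
  expect_equal(nrow(stage2_qualify(rnorm(600, sd = 0.01), cand, fs, p1,
                                   threshold = 1)), 0)
})

test_that("a 60 ms 140 Hz burst yields ~2 rectified peaks per cycle", {
  fs <- 1000
  x <- numeric(1000)
  tt <- seq(0, 0.06, by = 1 / fs)
  x[201:(200 + length(tt))] <- 10 * sin(2 * pi * 140 * tt)
  cand <- cbind(start = 195L, end = 270L)
  got <- stage2_qualify(x, cand, fs, detector_params(), threshold = 2,
                        band = band_spec("ripple"))
  expect_equal(nrow(got), 1)
  # ~8.4 cycles -> ~17 rectified lobes
  expect_gt(got$n_peaks, 12)
  expect_lt(got$n_peaks, 20)
})

test_that("detection is deterministic and gain invariant", {
  cfg <- quick_config(duration = 120, seed = 4)
  rec <- simulate_recording(cfg)
  e1 <- detect_hfos(rec, "fast_ripple")
  e2 <- detect_hfos(rec, "fast_ripple")
  expect_identical(e1, e2)
  expect_gt(nrow(e1), 5)
  rec10 <- rec
  rec10$data <- rec10$data * 10
  e10 <- detect_hfos(rec10, "fast_ripple")
  expect_equal(e1[c("channel", "start", "end", "n_peaks")],
               e10[c("channel", "start", "end", "n_peaks")])
})

test_that("raising the threshold multiplier never adds detections", {
  cfg <- quick_config(duration = 120, seed = 12)
  rec <- simulate_recording(cfg)
  counts <- vapply(c(2, 3, 4, 5), function(ns) {
    nrow(detect_hfos(rec, "fast_ripple", detector_params(n_sd = ns)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("short records are processed as one shorter segment", {
  cfg <- quick_config(duration = 30, dist_K = dist_const(40),
                      dist_rho = dist_const(3), seed = 13)
  rec <- simulate_recording(cfg)
  ev <- detect_hfos(rec, "fast_ripple")
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$end <= ncol(rec$data) + 1))
})

test_that("events coincident with CAR detections are removed", {
  cfg <- quick_config(duration = 60, dist_K = dist_const(40),
                      dist_rho = dist_const(3), seed = 21)
  rec <- simulate_recording(cfg)
  ev <- detect_hfos(rec, "fast_ripple")
  expect_gt(nrow(ev), 0)
  # CAR identical to the channel: every event also fires on the CAR
  ev_car <- detect_hfos(rec, "fast_ripple", car = rec$data[1, ])
  expect_equal(nrow(ev_car), 0)
})

test_that("DC steps that ring the band-pass filter are rejected", {
  fs <- 1000
  set.seed(30)
  x <- rnorm(60000, sd = 2)
  x[30001:60000] <- x[30001:60000] + 200 # large DC shift mid-record
  rec <- recording(matrix(x, 1), fs)
  ev_raw <- detect_hfos(rec, "fast_ripple", artifact_reject = FALSE)
  near_step <- ev_raw$start > 29500 & ev_raw$start < 30500
  expect_gt(sum(near_step), 0) # the filter rings at the step
  ev <- detect_hfos(rec, "fast_ripple", artifact_reject = TRUE)
  expect_equal(sum(ev$start > 29500 & ev$start < 30500), 0)
})

test_that("genuine bursts survive artifact rejection", {
  cfg <- quick_config(duration = 120, dist_s = dist_exponential(6),
                      dist_K = dist_const(30), dist_rho = dist_const(3),
                      dist_f0 = dist_uniform(310, 400), seed = 31)
  rec <- simulate_recording(cfg)
  ev_raw <- detect_hfos(rec, "fast_ripple", artifact_reject = FALSE)
  ev <- detect_hfos(rec, "fast_ripple", artifact_reject = TRUE)
  expect_gte(nrow(ev), 0.95 * nrow(ev_raw))
})
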