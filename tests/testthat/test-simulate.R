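test_that("point-mass distributions give deterministic pulse trains", {
  cfg <- quick_config(
    duration = 10,
    dist_s = dist_const(1), dist_d = dist_const(0.05),
    dist_K = dist_const(30)
  )
  set.seed(1)
  tr <- sample_hfo_train(cfg)
  expect_equal(nrow(tr), 9)
  expect_equal(tr$onset, 1 + (0:8) * 1.05, tolerance = 1e-12)
  expect_true(all(tr$onset + tr$d <= cfg$duration))

  cfg2 <- quick_config(duration = 0.5, dist_s = dist_const(1))
  set.seed(1)
  expect_equal(nrow(sample_hfo_train(cfg2)), 0)
})

test_that("pulse count follows the renewal-process expectation", {
  cfg <- quick_config(duration = 1200, dist_s = dist_exponential(2))
  counts <- vapply(1:500, function(s) {
    set.seed(s)
    nrow(sample_hfo_train(cfg))
  }, numeric(1))
  expected <- 1200 / (2 + dist_mean(cfg$dist_d))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1) # +1: boundary-drop bias
})

test_that("rendered pulses have unit-peak envelopes and correct spectra", {
  expect_equal(render_hfo_signal(data.frame(), 1000, 1), numeric(1000))

  tr <- data.frame(onset = 0.2, d = 0.1, K = 10, f0 = 140, phase = 0)
  x <- render_hfo_signal(tr, 1000, 1)
  expect_gt(max(abs(x)), 0.9 * 10)
  expect_lte(max(abs(x)), 10)
  expect_equal(sum(x[1:199]^2), 0) # zero outside the pulse

  # spectral argmax within f0 +/- 1/d
  seg <- x[201:300]
  spec <- Mod(stats::fft(c(seg, numeric(4096 - length(seg)))))
  fpk <- (which.max(spec[1:2048]) - 1) * 1000 / 4096
  expect_lt(abs(fpk - 140), 1 / 0.1 + 1)
})

test_that("background noise hits its target RMS and spectral slope", {
  cfg0 <- quick_config(bg_sigma = 0)
  set.seed(1)
  expect_equal(generate_background(cfg0), numeric(60000))

  for (alpha in c(0, 1)) {
    cfg <- quick_config(bg_sigma = 15, bg_exponent = alpha)
    set.seed(42)
    x <- generate_background(cfg)
    expect_equal(sqrt(mean(x^2)), 15, tolerance = 0.05)
    psd <- welch_psd(x, cfg$fs, nperseg = 4096)
    sel <- psd$freq >= 1 & psd$freq <= 400
    fit <- stats::lm(log(psd$psd[sel]) ~ log(psd$freq[sel]))
    expect_equal(unname(stats::coef(fit)[2]), -alpha,
                 tolerance = if (alpha == 0) 0.1 else 0.15)
  }
})

test_that("source mixing follows the saturating coverage rule", {
  set.seed(1)
  hfo <- rnorm(100)
  b1 <- rnorm(100)
  b2 <- rnorm(100)
  expect_equal(mix_sources(hfo, b1, b2, 1), hfo + b1)
  expect_equal(mix_sources(hfo, b1, b2, 3), mix_sources(hfo, b1, b2, 1))
  expect_equal(mix_sources(hfo, 0 * b1, 0 * b2, 0.5), 0.5 * hfo)
  expect_error(mix_sources(hfo, b1, b2, 0), "rho")
  expect_error(mix_sources(hfo, b1, b2, 3.5), "rho")
})

test_that("simulated recordings are reproducible and sized correctly", {
  cfg <- quick_config(duration = 60, seed = 9)
  rec1 <- simulate_recording(cfg)
  rec2 <- simulate_recording(cfg)
  expect_identical(rec1$data, rec2$data)
  expect_equal(ncol(rec1$data), 60000)
  expect_equal(rec1$fs, 1000)
  expect_false(is.null(rec1$ground_truth[[1]]$train))

  cfg20 <- simulation_config() # defaults: 20 min at 1000 Hz
  expect_equal(round(cfg20$duration * cfg20$fs), 1200000)
})

test_that("scaling the amplitude point-mass scales the noiseless output", {
  base <- list(
    duration = 30, dist_s = dist_exponential(2),
    dist_rho = dist_const(1), bg_sigma = 0,
    measurement_noise = FALSE, seed = 11
  )
  r1 <- simulate_recording(do.call(quick_config, c(base, list(dist_K = dist_const(10)))))
  r3 <- simulate_recording(do.call(quick_config, c(base, list(dist_K = dist_const(30)))))
  expect_equal(3 * r1$data, r3$data, tolerance = 1e-10)
})

test_that("cohort records share ground truth across areas", {
  cfg <- quick_config(duration = 30, seed = 2)
  coh <- simulate_cohort(cfg, areas = c(1.08, 2.16, 4.32), n_per_area = 2,
                         base_seed = 7)
  expect_length(coh, 2)
  expect_length(coh[[1]], 3)
  gt_small <- coh[[1]][[1]]$ground_truth[[1]]
  gt_quad <- coh[[1]][[3]]$ground_truth[[1]]
  expect_identical(gt_small$train, gt_quad$train)
  expect_identical(gt_small$rho, gt_quad$rho)
  # coverage shrinks with area until it saturates
  expect_gte(gt_small$coverage, gt_quad$coverage)
  expect_length(simulate_cohort(cfg, n_per_area = 0), 0)
})

test_that("measured burst amplitude is non-increasing in electrode area", {
  cfg <- quick_config(
    duration = 20,
    dist_s = dist_const(2), dist_d = dist_const(0.05),
    dist_K = dist_const(30), dist_f0 = dist_const(350),
    dist_rho = dist_const(0.9), # patch smaller than the smallest contact
    bg_sigma = 0, measurement_noise = FALSE, seed = 3
  )
  coh <- simulate_cohort(cfg, areas = c(1.08, 2.16, 4.32), n_per_area = 1,
                         base_seed = 5)
  peaks <- vapply(coh[[1]], function(r) max(abs(r$data)), numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
  expect_gt(peaks[1] / peaks[3], 2) # quarter coverage, near-unity |H|
})

test_that("degenerate or invalid configurations are rejected", {
  expect_error(quick_config(dist_s = dist_const(0)), "positive")
  expect_error(quick_config(dist_rho = dist_uniform(0.5, 4)), "rho")
  expect_error(quick_config(dist_f0 = dist_uniform(100, 200)), "band")
  expect_error(quick_config(fs = 900), "fs")
})
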