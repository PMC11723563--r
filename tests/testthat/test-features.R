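test_that("event amplitude recovers the envelope of known signals", {
  fs <- 1000
  t <- (1:2000) / fs
  # constant-amplitude sinusoid: envelope = K
  xf <- 20 * sin(2 * pi * 140 * t)
  expect_equal(event_amplitude(501, 801, xf, fs), 20, tolerance = 0.02 * 20)
  # zero signal
  expect_equal(event_amplitude(501, 801, numeric(2000), fs), 0)
  # Hann burst: mean envelope = K * mean(w) = K / 2
  d <- 0.1
  tr <- data.frame(onset = 1, d = d, K = 10, f0 = 140, phase = 0)
  x <- render_hfo_signal(tr, fs, 2)
  got <- event_amplitude(1001, 1001 + round(d * fs), x, fs)
  expect_equal(got, 10 * 0.5, tolerance = 0.05 * 5)
  # linearity
  expect_equal(event_amplitude(1001, 1101, 3 * x, fs), 3 * got,
               tolerance = 1e-9)
  # record-edge events are padded by reflection, not errored
  expect_gt(event_amplitude(1, 60, xf, fs), 0)
})

test_that("peak frequency finds the dominant line after whitening", {
  fs <- 1000
  t <- (1:1000) / fs
  x <- sin(2 * pi * 140 * t)
  expect_equal(event_peak_frequency(301, 501, x, fs, "ripple"), 140,
               tolerance = 2)
  # equal-amplitude 100 + 200 Hz: whitening boosts the higher line
  x2 <- sin(2 * pi * 100 * t) + sin(2 * pi * 200 * t)
  expect_equal(event_peak_frequency(301, 501, x2, fs, "ripple"), 200,
               tolerance = 2)
  # band restriction at the fast-ripple edge
  x3 <- sin(2 * pi * 250 * t)
  pf <- event_peak_frequency(301, 501, x3, fs, "fast_ripple")
  expect_true(pf >= 250 && pf <= 500)
  # too-short events are flagged missing (< 2 cycles of band.low)
  expect_true(is.na(event_peak_frequency(301, 320, x, fs, "ripple")))
})

test_that("event grouping matches the union-find overlap oracle", {
  # 3 events on 3 channels, mutually overlapping -> one group, S = 3
  ev <- data.frame(channel = c("a", "b", "c"),
                   start = c(10L, 15L, 18L), end = c(30L, 40L, 25L))
  g <- group_events(ev, 1000)
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$spread, 3)
  # 2 disjoint events on one channel -> two groups, S = 1 each
  ev2 <- data.frame(channel = "a", start = c(10L, 100L), end = c(30L, 130L))
  g2 <- group_events(ev2, 1000)
  expect_equal(g2$groups$spread, c(1, 1))
  # chain A~B, B~C without A~C -> transitive closure into one group
  ev3 <- data.frame(channel = c("a", "b", "c"),
                    start = c(10L, 25L, 45L), end = c(30L, 50L, 70L))
  g3 <- group_events(ev3, 1000)
  expect_equal(nrow(g3$groups), 1)
  # touching endpoints (half-open) do not overlap
  ev4 <- data.frame(channel = c("a", "b"), start = c(10L, 30L), end = c(30L, 50L))
  expect_equal(nrow(group_events(ev4, 1000)$groups), 2)

  set.seed(99)
  for (trial in 1:25) {
    n <- sample(2:40, 1)
    start <- sample.int(500, n, replace = TRUE)
    len <- sample.int(60, n, replace = TRUE)
    ev <- data.frame(channel = sample(letters[1:8], n, replace = TRUE),
                     start = start, end = start + len)
    g <- group_events(ev, 1000)
    comp <- oracle_overlap_components(ev$start, ev$end)
    # same partition up to label permutation
    ord <- order(ev$start, ev$end)
    canon <- function(l) match(l, unique(l))
    expect_equal(canon(g$events$group_id), canon(comp[ord]))
    expect_equal(sum(g$groups$n_members), n)
    expect_lte(nrow(g$groups), n)
  }
})

test_that("channel rates count events per minute, zeros included", {
  ev <- data.frame(channel = rep("ch01", 40))
  r <- channel_rates(ev, 20, c("ch01", "ch02"))
  expect_equal(r$rate, c(2, 0))
  expect_equal(channel_rates(ev[0, , drop = FALSE], 20, c("a", "b"))$rate,
               c(0, 0))
  set.seed(1)
  ev2 <- data.frame(channel = sample(c("a", "b", "c"), 100, replace = TRUE))
  r2 <- channel_rates(ev2, 10, c("a", "b", "c"))
  expect_equal(r2$rate * 10, as.numeric(table(ev2$channel)[r2$channel]))
})

test_that("global rate per area counts overlapping events once", {
  lay <- grid_layout()
  small <- make_shorting_scheme(lay, "small")
  # 144 unique events in 20 minutes over the full grid
  fake_groups <- data.frame(group_id = 1:144)
  expect_equal(global_rate_per_area(fake_groups, 20, scheme_total_area(small)),
               144 / 20 / 69.12)
  expect_equal(global_rate_per_area(fake_groups[0, , drop = FALSE], 20, 69.12), 0)
  # duplicating every event onto an overlapping second channel changes nothing
  set.seed(3)
  start <- seq(10, 4000, by = 150) + sample.int(20, 27, replace = TRUE)
  ev <- data.frame(channel = "ch01", start = start, end = start + 40L)
  dup <- ev
  dup$channel <- "ch02"
  g1 <- group_events(ev, 1000)$groups
  g2 <- group_events(rbind(ev, dup), 1000)$groups
  expect_equal(global_rate_per_area(g1, 20, 69.12),
               global_rate_per_area(g2, 20, 69.12))
  expect_true(all(g2$spread == 2))
})
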