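test_that("shorting schemes tile the grid with conserved total area", {
  lay <- grid_layout()
  small <- make_shorting_scheme(lay, "small")
  pair <- make_shorting_scheme(lay, "pair")
  quad <- make_shorting_scheme(lay, "quad")

  expect_length(small$groups, 64)
  expect_length(pair$groups, 32)
  expect_length(quad$groups, 16)
  expect_equal(small$effective_area, 1.08)
  expect_equal(pair$effective_area, 2.16)
  expect_equal(quad$effective_area, 4.32)
  for (s in list(small, pair, quad)) {
    expect_equal(scheme_total_area(s), 69.12)
    # disjoint and covering
    all_ch <- unname(unlist(s$groups))
    expect_equal(sort(all_ch), sort(lay$positions$channel))
  }
  # groups are mutually adjacent cells
  pos <- lay$positions
  for (g in quad$groups) {
    p <- pos[pos$channel %in% g, ]
    expect_equal(diff(range(p$row)), 1)
    expect_equal(diff(range(p$col)), 1)
  }
  expect_error(make_shorting_scheme(grid_layout(n_rows = 3, n_cols = 3), "quad"))
})

test_that("virtual shorting averages member channels exactly", {
  lay <- grid_layout(n_rows = 2, n_cols = 2)
  set.seed(1)
  x <- rnorm(500)
  # identical members -> identity
  rec <- recording(rbind(x, x, x, x), 1000, channel_ids = lay$positions$channel)
  quad <- make_shorting_scheme(lay, "quad")
  expect_equal(apply_shorting(rec, quad)$data[1, ], x)
  # cancellation
  rec2 <- recording(rbind(x, -x), 1000, channel_ids = c("ch01", "ch02"))
  pairsc <- make_shorting_scheme(grid_layout(n_rows = 1, n_cols = 2), "pair")
  expect_equal(max(abs(apply_shorting(rec2, pairsc)$data)), 0)
  # random group equals the brute-force per-sample mean
  m <- matrix(rnorm(4 * 500), nrow = 4)
  rec4 <- recording(m, 1000, channel_ids = lay$positions$channel)
  out <- apply_shorting(rec4, quad)
  expect_equal(out$data[1, ], colMeans(m))
  expect_equal(out$electrode_area, 4 * lay$electrode_area)
  # small scheme is the identity
  small <- make_shorting_scheme(lay, "small")
  expect_equal(unname(apply_shorting(rec4, small)$data), unname(m))
  # missing channels are rejected
  expect_error(apply_shorting(rec2, quad), "channels")
})

test_that("common average referencing zeroes the cross-channel mean", {
  m <- matrix(rnorm(3 * 400), nrow = 3)
  rec <- recording(m, 1000)
  out <- common_average_reference(rec)
  expect_equal(out$car, colMeans(m))
  expect_equal(out$recording$data, sweep(m, 2, colMeans(m)),
               ignore_attr = TRUE)
  expect_equal(max(abs(colMeans(out$recording$data))), 0, tolerance = 1e-12)
  # identical channels -> all-zero output
  recI <- recording(rbind(m[1, ], m[1, ]), 1000)
  expect_equal(max(abs(common_average_reference(recI)$recording$data)), 0)
  expect_error(common_average_reference(recording(m[1, , drop = FALSE], 1000)))
})

test_that("shorting commutes with re-referencing for equal group sizes", {
  lay <- grid_layout(n_rows = 2, n_cols = 2)
  m <- matrix(rnorm(4 * 300), nrow = 4)
  rec <- recording(m, 1000, channel_ids = lay$positions$channel)
  pairsc <- make_shorting_scheme(lay, "pair")
  a <- common_average_reference(apply_shorting(rec, pairsc))$recording$data
  b <- apply_shorting(common_average_reference(rec)$recording, pairsc)$data
  expect_equal(a, b, tolerance = 1e-12)
})
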