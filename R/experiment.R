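#' Electrode-size experiment on synthetic iEEG
#'
#' Reproduces the simulated size-dependence analysis: records are generated
#' with [simulate_cohort()] so that each source realization is re-measured at
#' every electrode area, HFOs are detected per record, features are computed,
#' and the per-area distributions of global rate per area, amplitude, duration
#' and peak frequency are compared between adjacent sizes with
#' [rank_sum_test()].
#'
#' Rate per area is compared across records (one value per record); event
#' features (amplitude, duration, peak frequency) are compared across the
#' pooled detected events of each area, mirroring the per-subject
#' comparisons on recorded data. Per-record medians are also returned.
#'
#' @param cfg A [simulation_config()].
#' @param areas Electrode areas, mm^2.
#' @param n_per_area Records per area.
#' @param params A [detector_params()].
#' @param seed Integer seed for the cohort.
#' @return Object of class `size_experiment`: `records` (one row per record x
#'   area), `events` (event level), `tests` (adjacent-pair rank-sum p-values
#'   per feature), plus the configuration snapshot.
#' @export
run_size_experiment <- function(cfg,
                                areas = c(1.08, 2.16, 4.32),
                                n_per_area = 50L,
                                params = detector_params(),
                                seed = 1L) {
  stopifnot(inherits(cfg, "simulation_config"), n_per_area >= 1)
  duration_min <- cfg$duration / 60
  rec_rows <- list()
  ev_rows <- list()
  for (i in seq_len(n_per_area)) {
    set.seed(seed + i)
    recs <- simulate_recording_impl(cfg, areas)
    for (ai in seq_along(areas)) {
      rec <- recs[[ai]]
      ev <- detect_hfos(rec, cfg$band, params)
      ev <- annotate_features(ev, rec, cfg$band, params)
      grp <- group_events(ev, rec$fs)
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        record = i, area = areas[ai],
        n_events = nrow(ev),
        rate_per_area = global_rate_per_area(grp$groups, duration_min, areas[ai]),
        med_amplitude = if (nrow(ev)) stats::median(ev$amplitude) else NA_real_,
        med_duration_ms = if (nrow(ev)) stats::median(ev$duration_s) * 1000 else NA_real_,
        med_peak_freq = if (nrow(ev)) stats::median(ev$peak_freq, na.rm = TRUE) else NA_real_
      )
      if (nrow(ev) > 0) {
        ev$record <- i
        ev$area <- areas[ai]
        ev_rows[[length(ev_rows) + 1L]] <- ev
      }
    }
  }
  records <- do.call(rbind, rec_rows)
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else empty_events()
  tests <- size_experiment_tests(records, events, areas)
  structure(
    list(
      records = records, events = events, tests = tests,
      areas = areas, n_per_area = n_per_area, band = cfg$band,
      config = cfg, seed = seed
    ),
    class = "size_experiment"
  )
}

# rate per area is compared across records (one value per record); event
# features are compared across pooled detected events, as in the per-subject
# amplitude/duration/peak-frequency comparisons
size_experiment_tests <- function(records, events, areas) {
  feat_src <- list(
    rate_per_area = function(a) records$rate_per_area[records$area == a],
    amplitude = function(a) events$amplitude[events$area == a],
    duration_ms = function(a) events$duration_s[events$area == a] * 1000,
    peak_freq = function(a) events$peak_freq[events$area == a]
  )
  out <- list()
  for (f in names(feat_src)) {
    for (j in seq_len(length(areas) - 1)) {
      a1 <- areas[j]
      a2 <- areas[j + 1]
      x <- feat_src[[f]](a1)
      y <- feat_src[[f]](a2)
      x <- x[is.finite(x)]
      y <- y[is.finite(y)]
      p <- if (length(x) && length(y)) rank_sum_test(x, y)$p.value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        feature = f, area_small = a1, area_large = a2,
        median_small = if (length(x)) stats::median(x) else NA_real_,
        median_large = if (length(y)) stats::median(y) else NA_real_,
        p = p, stars = p_stars(p)
      )
    }
  }
  do.call(rbind, out)
}

#' @export
print.size_experiment <- function(x, ...) {
  cat(sprintf("<size_experiment> %s band, %d records x %d areas\n",
              x$band, x$n_per_area, length(x$areas)))
  med <- stats::aggregate(
    cbind(rate_per_area, med_amplitude, med_duration_ms, med_peak_freq) ~ area,
    data = x$records, FUN = function(v) stats::median(v, na.rm = TRUE),
    na.action = stats::na.pass
  )
  print(med, row.names = FALSE)
  cat("adjacent-size rank-sum tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Per-area medians of a size experiment
#'
#' @param exp A `size_experiment`.
#' @param feature Column of `exp$records`.
#' @return Named numeric vector of per-area medians (names = areas).
#' @export
size_experiment_medians <- function(exp, feature = "rate_per_area") {
  vapply(exp$areas, function(a) {
    stats::median(exp$records[[feature]][exp$records$area == a], na.rm = TRUE)
  }, numeric(1)) |> stats::setNames(sprintf("%.2f", exp$areas))
}

#' Ripple versus fast-ripple rate comparison
#'
#' Per-channel rates in the two bands with the Wilcoxon rank-sum comparison
#' across channels.
#'
#' @param events_ripple,events_fast Event tables for the two bands (same
#'   recording).
#' @param duration_min Recording duration, minutes.
#' @param channels Channel labels.
#' @return `list(rates =, p =, statistic =)`; `rates` has columns `channel`,
#'   `ripple`, `fast_ripple`.
#' @export
band_rate_comparison <- function(events_ripple, events_fast, duration_min,
                                 channels) {
  r <- channel_rates(events_ripple, duration_min, channels)
  f <- channel_rates(events_fast, duration_min, channels)
  ht <- rank_sum_test(f$rate, r$rate)
  list(
    rates = data.frame(channel = channels, ripple = r$rate,
                       fast_ripple = f$rate),
    p = ht$p.value,
    statistic = unname(ht$statistic)
  )
}

#' Spatial-spread summary per electrode scheme
#'
#' Counts events with spread S = 1 versus S > 1 for each shorting scheme.
#'
#' @param groups_by_scheme Named list: scheme label -> group table from
#'   [group_events()].
#' @return `data.frame(scheme, n_groups, n_s1, n_sgt1, frac_s1)`.
#' @export
summarize_spread <- function(groups_by_scheme) {
  out <- lapply(names(groups_by_scheme), function(lbl) {
    g <- groups_by_scheme[[lbl]]
    data.frame(
      scheme = lbl,
      n_groups = nrow(g),
      n_s1 = sum(g$spread == 1),
      n_sgt1 = sum(g$spread > 1),
      frac_s1 = if (nrow(g)) mean(g$spread == 1) else NA_real_
    )
  })
  do.call(rbind, out)
}
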