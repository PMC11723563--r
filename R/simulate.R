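#' Band definitions
#'
#' Ripple band 80-250 Hz, fast-ripple band 250-500 Hz.
#'
#' @param name `"ripple"` or `"fast_ripple"`.
#' @return List with `name`, `low`, `high` (Hz), class `band_spec`.
#' @export
band_spec <- function(name = c("ripple", "fast_ripple")) {
  name <- match.arg(name)
  lims <- switch(name, ripple = c(80, 250), fast_ripple = c(250, 500))
  structure(list(name = name, low = lims[1], high = lims[2]), class = "band_spec")
}

default_f0_dist <- function(band) {
  # kept strictly inside the band and below typical Nyquist margins
  if (band == "ripple") dist_uniform(90, 240) else dist_uniform(260, 450)
}

#' Configuration of the synthetic iEEG generator
#'
#' Describes one simulated channel: an HFO pulse train (gap `s`, duration `d`,
#' amplitude `K`, intra-event frequency `f0`) occurring in tissue that covers a
#' proportion `rho` of the reference electrode contact, embedded in 1/f
#' background activity, and measured through the lumped electrode model.
#'
#' Defaults follow the study conditions of the measurement model: 1000 Hz
#' sampling, 20-minute records, fast-ripple band, exponential inter-pulse gaps,
#' gamma-distributed durations spanning roughly 30-100 ms, a symmetric
#' (truncated-Gaussian) amplitude distribution, and an HFO-tissue proportion
#' uniform on (0, 3] (the generating patch ranges from almost zero to three
#' times the size of the measuring electrode; coverage saturates at 1).
#'
#' @param fs Sampling rate, Hz.
#' @param duration Record length, s.
#' @param band `"ripple"` or `"fast_ripple"`.
#' @param dist_s Inter-pulse gap distribution, s.
#' @param dist_d Pulse duration distribution, s.
#' @param dist_K Pulse amplitude distribution, uV.
#' @param dist_rho HFO-proportion distribution, support within (0, 3].
#' @param dist_f0 Intra-event frequency distribution, Hz (inside the band,
#'   strictly below `fs/2`).
#' @param bg_sigma Background RMS, uV.
#' @param bg_exponent Background spectral slope alpha in 1/f^alpha.
#' @param electrode An [electrode_model()]; its `area` is the reference area
#'   that `rho` is measured against.
#' @param measurement_noise Add interface thermal noise during measurement?
#' @param seed Integer RNG seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(fs = 1000,
                              duration = 1200,
                              band = c("fast_ripple", "ripple"),
                              dist_s = dist_exponential(mean = 4),
                              dist_d = dist_gamma(mean = 0.055, shape = 10),
                              dist_K = dist_truncnorm(mean = 30, sd = 10, lower = 0),
                              dist_rho = dist_uniform(0.05, 3),
                              dist_f0 = NULL,
                              bg_sigma = 15,
                              bg_exponent = 1,
                              electrode = electrode_model(),
                              measurement_noise = TRUE,
                              seed = 1L) {
  band <- match.arg(band)
  if (is.null(dist_f0)) dist_f0 <- default_f0_dist(band)
  bs <- band_spec(band)
  stopifnot(
    fs > 0, duration > 0,
    fs >= 2 * bs$high,
    bg_sigma >= 0,
    inherits(electrode, "electrode_model")
  )
  for (nm in c("dist_s", "dist_d", "dist_K", "dist_rho", "dist_f0")) {
    sp <- get(nm)
    if (!inherits(sp, "dist_spec")) stop(nm, " must be a dist_spec")
  }
  # gaps and durations must not be degenerate at zero
  for (nm in c("dist_s", "dist_d")) {
    sup <- dist_support(get(nm))
    if (sup[2] <= 0) stop(nm, ": support must be positive")
  }
  sup_rho <- dist_support(dist_rho)
  if (sup_rho[1] <= 0 || sup_rho[2] > 3) {
    stop("dist_rho support must lie within (0, 3]")
  }
  sup_f0 <- dist_support(dist_f0)
  if (sup_f0[1] < bs$low || sup_f0[2] > bs$high || sup_f0[2] >= fs / 2) {
    stop("dist_f0 support must lie inside the band and below fs/2")
  }
  structure(
    list(
      fs = fs, duration = duration, band = band,
      dist_s = dist_s, dist_d = dist_d, dist_K = dist_K,
      dist_rho = dist_rho, dist_f0 = dist_f0,
      bg_sigma = bg_sigma, bg_exponent = bg_exponent,
      electrode = electrode, measurement_noise = measurement_noise,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %s band, fs = %g Hz, %g s, bg = %g uV (1/f^%g), A = %g mm^2, seed = %d\n",
    x$band, x$fs, x$duration, x$bg_sigma, x$bg_exponent, x$electrode$area, x$seed
  ))
  invisible(x)
}

#' Sample an HFO pulse train
#'
#' Alternates draws of a gap `s` and a pulse `(d, K, f0, phase)` until the
#' record duration is exhausted; a pulse that would overrun the end of the
#' record is dropped. Consecutive gaps (pulse end to next onset) equal the
#' sampled `s` values.
#'
#' @param cfg A [simulation_config()]. Uses the current RNG state; seed
#'   externally (or via [simulate_recording()]) for reproducibility.
#' @return `data.frame(onset, d, K, f0, phase)` of class `hfo_train` with the
#'   band stored as attribute `band`.
#' @export
sample_hfo_train <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  onset <- d <- K <- f0 <- phase <- numeric(0)
  t_end <- 0
  repeat {
    s <- draw_dist(cfg$dist_s, 1)
    start <- t_end + s
    if (start >= cfg$duration) break
    di <- draw_dist(cfg$dist_d, 1)
    ki <- draw_dist(cfg$dist_K, 1)
    fi <- draw_dist(cfg$dist_f0, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    if (start + di > cfg$duration) break
    onset <- c(onset, start)
    d <- c(d, di)
    K <- c(K, ki)
    f0 <- c(f0, fi)
    phase <- c(phase, ph)
    t_end <- start + di
  }
  train <- data.frame(onset = onset, d = d, K = K, f0 = f0, phase = phase)
  attr(train, "band") <- cfg$band
  class(train) <- c("hfo_train", "data.frame")
  train
}

#' Render an HFO pulse train into a waveform
#'
#' Each pulse is an amplitude-modulated sinusoid
#' `K * w(t) * sin(2 pi f0 t + phase)` with a raised-cosine (Hann) envelope
#' `w` of length `d` (peak 1); the waveform is zero between pulses.
#'
#' @param train An `hfo_train` (see [sample_hfo_train()]); a `phase` column is
#'   used if present, otherwise phase 0.
#' @param fs Sampling rate, Hz.
#' @param duration Record length, s.
#' @return Numeric waveform, uV, of length `round(duration * fs)`.
#' @export
render_hfo_signal <- function(train, fs, duration) {
  n <- round(duration * fs)
  x <- numeric(n)
  if (NROW(train) == 0L) return(x)
  stopifnot(all(train$onset >= 0), all(train$onset + train$d <= duration + 1e-9))
  phase <- if ("phase" %in% names(train)) train$phase else rep(0, nrow(train))
  for (i in seq_len(nrow(train))) {
    i0 <- floor(train$onset[i] * fs) + 1L
    i1 <- min(n, ceiling((train$onset[i] + train$d[i]) * fs))
    if (i1 < i0) next
    t_rel <- ((i0:i1) - 1) / fs - train$onset[i]
    w <- sin(pi * pmin(pmax(t_rel / train$d[i], 0), 1))^2
    x[i0:i1] <- x[i0:i1] +
      train$K[i] * w * sin(2 * pi * train$f0[i] * t_rel + phase[i])
  }
  x
}

#' Generate the 1/f background activity of one tissue source
#'
#' @param cfg A [simulation_config()]. Independent draw per call (current RNG).
#' @return Numeric waveform, uV.
#' @export
generate_background <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  powerlaw_noise(round(cfg$duration * cfg$fs), cfg$fs,
                 sigma = cfg$bg_sigma, alpha = cfg$bg_exponent)
}

#' Mix HFO-generating and surrounding tissue sources
#'
#' The electrode sees a coverage-weighted average of the HFO-generating patch
#' (HFO train plus its local background) and the surrounding non-HFO tissue:
#' `p * (hfo + bg_hfo_region) + (1 - p) * bg_rest` with
#' `p = min(rho_hfog, 1)` — coverage saturates once the patch is at least as
#' large as the contact.
#'
#' @param hfo Rendered HFO waveform, uV.
#' @param bg_hfo_region Background of the HFO-generating tissue, uV.
#' @param bg_rest Background of the surrounding tissue, uV.
#' @param rho_hfog HFO proportion, in (0, 3].
#' @return Tissue potential waveform, uV.
#' @export
mix_sources <- function(hfo, bg_hfo_region, bg_rest, rho_hfog) {
  stopifnot(
    length(hfo) == length(bg_hfo_region),
    length(hfo) == length(bg_rest)
  )
  if (!is.finite(rho_hfog) || rho_hfog <= 0 || rho_hfog > 3) {
    stop("rho_hfog must lie in (0, 3]")
  }
  p <- min(rho_hfog, 1)
  p * (hfo + bg_hfo_region) + (1 - p) * bg_rest
}

#' Recording container
#'
#' @param data Channels x samples matrix, uV (a vector is treated as one
#'   channel).
#' @param fs Sampling rate, Hz.
#' @param channel_ids Character channel labels (default from rownames or
#'   `ch01`...).
#' @param layout Optional [grid_layout()].
#' @param electrode_area Effective contact area per channel, mm^2 (scalar or
#'   per-channel vector).
#' @param ground_truth Optional per-channel list of injected trains
#'   (`list(train =, rho =, coverage =)`).
#' @return Object of class `hfo_recording`.
#' @export
recording <- function(data, fs, channel_ids = NULL, layout = NULL,
                      electrode_area = NA_real_, ground_truth = NULL) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), fs > 0)
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data)
    if (is.null(channel_ids)) {
      channel_ids <- sprintf("ch%02d", seq_len(nrow(data)))
    }
  }
  stopifnot(length(channel_ids) == nrow(data))
  rownames(data) <- channel_ids
  structure(
    list(
      data = data, fs = fs, channel_ids = channel_ids, layout = layout,
      electrode_area = electrode_area, ground_truth = ground_truth
    ),
    class = "hfo_recording"
  )
}

#' @export
print.hfo_recording <- function(x, ...) {
  cat(sprintf(
    "<hfo_recording> %d channel(s) x %d samples @ %g Hz (%.1f min)%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs / 60,
    if (!is.null(x$ground_truth)) ", with ground truth" else ""
  ))
  invisible(x)
}

#' Duration of a recording in minutes
#' @param rec An `hfo_recording`.
#' @return Numeric scalar, minutes.
#' @export
recording_duration_min <- function(rec) ncol(rec$data) / rec$fs / 60

#' Simulate one measured iEEG channel
#'
#' Composes the full generative chain: pulse train -> rendering -> two
#' independent background draws -> coverage mixing (one `rho` draw per record)
#' -> lumped electrode measurement. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return Single-channel [recording()] with ground truth attached.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  simulate_recording_impl(cfg, areas = cfg$electrode$area)[[1]]
}

# Draws one source realization (train, rho, backgrounds, measurement-noise
# seed draws) and measures it at each requested contact area. The coverage at
# area A is min(rho * A_ref / A, 1), A_ref being the config electrode area, so
# the same absolute HFO-generating patch is seen by every electrode size.
simulate_recording_impl <- function(cfg, areas) {
  train <- sample_hfo_train(cfg)
  rho <- draw_dist(cfg$dist_rho, 1)
  bg_hfo <- generate_background(cfg)
  bg_rest <- generate_background(cfg)
  hfo <- render_hfo_signal(train, cfg$fs, cfg$duration)
  a_ref <- cfg$electrode$area
  noise_seed <- sample.int(.Machine$integer.max, 1L)
  lapply(areas, function(a) {
    em <- cfg$electrode
    em$area <- a
    rho_eff <- rho * a_ref / a
    pot <- mix_sources(hfo, bg_hfo, bg_rest, rho_eff)
    set.seed(noise_seed) # same underlying noise draws at every area
    meas <- electrode_transfer(pot, em, cfg$fs, add_noise = cfg$measurement_noise)
    recording(
      matrix(meas, nrow = 1), cfg$fs,
      channel_ids = "ch01",
      electrode_area = a,
      ground_truth = list(list(
        train = train, rho = rho, coverage = min(rho_eff, 1)
      ))
    )
  })
}

#' Simulate a cohort of records re-measured at several electrode areas
#'
#' For each record index the injected pulse train, `rho`, backgrounds and
#' measurement-noise draws are shared across areas, so the contact area is the
#' only varying factor (default areas 1.08, 2.16, 4.32 mm^2: the small, pair
#' and quad configurations).
#'
#' @param cfg A [simulation_config()].
#' @param areas Electrode areas, mm^2.
#' @param n_per_area Records per area.
#' @param base_seed Integer; record `i` uses seed `base_seed + i`.
#' @return List of length `n_per_area`; element `i` is a named list of
#'   recordings, one per area.
#' @export
simulate_cohort <- function(cfg, areas = c(1.08, 2.16, 4.32),
                            n_per_area = 1L, base_seed = cfg$seed) {
  stopifnot(length(areas) >= 1, n_per_area >= 0)
  lapply(seq_len(n_per_area), function(i) {
    set.seed(base_seed + i)
    out <- simulate_recording_impl(cfg, areas)
    names(out) <- sprintf("area_%.2f", areas)
    out
  })
}

#' Simulate an independent-channel grid recording
#'
#' Every grid channel carries its own independent source realization
#' (train, rho, backgrounds) under the same configuration.
#'
#' @param cfg A [simulation_config()].
#' @param layout A [grid_layout()].
#' @param seed Integer seed.
#' @return Multi-channel [recording()] with per-channel ground truth.
#' @export
simulate_grid_recording <- function(cfg, layout = grid_layout(), seed = cfg$seed) {
  n_ch <- nrow(layout$positions)
  n <- round(cfg$duration * cfg$fs)
  data <- matrix(0, nrow = n_ch, ncol = n)
  gt <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    ch_cfg <- cfg
    ch_cfg$seed <- as.integer(seed + i)
    rec <- simulate_recording(ch_cfg)
    data[i, ] <- rec$data[1, ]
    gt[[i]] <- rec$ground_truth[[1]]
  }
  recording(data, cfg$fs,
            channel_ids = layout$positions$channel, layout = layout,
            electrode_area = layout$electrode_area, ground_truth = gt)
}

#' Simulate a grid recording with ripple and fast-ripple trains per channel
#'
#' Each channel receives two independent pulse trains (one per band) inside
#' the same HFO-generating patch, sharing one `rho` draw, background and
#' measurement chain. Used for between-band rate comparisons.
#'
#' @param cfg_ripple,cfg_fast [simulation_config()]s for the two bands; they
#'   must agree on `fs`, `duration`, background and electrode.
#' @param n_channels Number of channels.
#' @param seed Integer seed.
#' @return Multi-channel [recording()]; ground truth stores both trains.
#' @export
simulate_dual_band_recording <- function(cfg_ripple, cfg_fast,
                                         n_channels = 64L, seed = 1L) {
  stopifnot(
    cfg_ripple$fs == cfg_fast$fs,
    cfg_ripple$duration == cfg_fast$duration
  )
  n <- round(cfg_ripple$duration * cfg_ripple$fs)
  data <- matrix(0, nrow = n_channels, ncol = n)
  gt <- vector("list", n_channels)
  for (i in seq_len(n_channels)) {
    set.seed(as.integer(seed + i))
    tr_r <- sample_hfo_train(cfg_ripple)
    tr_f <- sample_hfo_train(cfg_fast)
    rho <- draw_dist(cfg_ripple$dist_rho, 1)
    bg_hfo <- generate_background(cfg_ripple)
    bg_rest <- generate_background(cfg_ripple)
    hfo <- render_hfo_signal(tr_r, cfg_ripple$fs, cfg_ripple$duration) +
      render_hfo_signal(tr_f, cfg_ripple$fs, cfg_ripple$duration)
    pot <- mix_sources(hfo, bg_hfo, bg_rest, rho)
    data[i, ] <- electrode_transfer(pot, cfg_ripple$electrode, cfg_ripple$fs,
                                    add_noise = cfg_ripple$measurement_noise)
    gt[[i]] <- list(ripple = tr_r, fast_ripple = tr_f, rho = rho,
                    coverage = min(rho, 1))
  }
  recording(data, cfg_ripple$fs,
            electrode_area = cfg_ripple$electrode$area, ground_truth = gt)
}
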