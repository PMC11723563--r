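#' Parameters of the two-threshold RMS HFO detector
#'
#' The detector computes the sliding-window RMS envelope of the band-filtered
#' signal; runs where the envelope exceeds a first threshold (mean + `n_sd`
#' SD) for at least `min_duration` are candidates, and a candidate qualifies
#' as an HFO if the rectified signal within it shows at least `min_peaks`
#' local maxima above a second mean + `n_sd` SD threshold. Thresholds are
#' recomputed per channel and per `segment_length` segment.
#'
#' @param rms_window RMS window length, s (3 ms).
#' @param min_duration Minimum supra-threshold duration, s (6 ms).
#' @param n_sd SD multiplier for both thresholds (3).
#' @param min_peaks Minimum rectified peaks above the second threshold (6).
#' @param merge_gap Candidates separated by less than this merge before the
#'   duration test, s.
#' @param segment_length Detection segment length, s (60).
#' @param threshold_reference `"rms"`: the first threshold is mean + n_sd SD
#'   of the RMS envelope itself; `"rectified"`: both thresholds come from the
#'   rectified filtered signal.
#' @param boundary_extension Extend accepted event boundaries outward to where
#'   the envelope falls back to its segment mean. Keeps measured duration a
#'   property of the event rather than of its signal-to-noise ratio.
#' @param filter_order Butterworth band-pass order (applied forward-backward).
#' @param notch_q Quality factor of the line-noise notches.
#' @param step_window Half-width of the wide-band window inspected around an
#'   event for transient/DC-shift artifacts, s.
#' @param step_block Block length for step-level estimation, s.
#' @param step_sd_mult Step rejection: a level change between adjacent blocks
#'   above this multiple of the segment's wide-band SD flags the event.
#' @param jump_power_frac Jump rejection: flag when a lone sample-to-sample
#'   jump would account for more than this fraction of the event band power.
#' @param jump_ratio A jump counts as "lone" when it exceeds this multiple of
#'   the event's median absolute sample-to-sample difference.
#' @return Object of class `detector_params`.
#' @export
detector_params <- function(rms_window = 0.003,
                            min_duration = 0.006,
                            n_sd = 3,
                            min_peaks = 6L,
                            merge_gap = 0.010,
                            segment_length = 60,
                            threshold_reference = c("rms", "rectified"),
                            boundary_extension = TRUE,
                            filter_order = 6L,
                            notch_q = 30,
                            step_window = 0.1,
                            step_block = 0.010,
                            step_sd_mult = 5,
                            jump_power_frac = 0.2,
                            jump_ratio = 8) {
  threshold_reference <- match.arg(threshold_reference)
  stopifnot(
    rms_window > 0, min_duration > 0, n_sd > 0, min_peaks >= 1,
    merge_gap >= 0, segment_length > 0, filter_order >= 1, notch_q > 0,
    step_window > 0, step_block > 0, step_sd_mult > 0,
    jump_power_frac > 0, jump_ratio > 0
  )
  structure(
    list(
      rms_window = rms_window, min_duration = min_duration, n_sd = n_sd,
      min_peaks = as.integer(min_peaks), merge_gap = merge_gap,
      segment_length = segment_length,
      threshold_reference = threshold_reference,
      boundary_extension = boundary_extension,
      filter_order = as.integer(filter_order), notch_q = notch_q,
      step_window = step_window, step_block = step_block,
      step_sd_mult = step_sd_mult, jump_power_frac = jump_power_frac,
      jump_ratio = jump_ratio
    ),
    class = "detector_params"
  )
}

# zero-phase band filter: Butterworth band-pass (high-pass when the band's
# upper edge sits at Nyquist) plus IIR notches at the odd 60 Hz harmonics
# falling inside the band
band_filter <- function(x, band, fs, params = detector_params()) {
  ny <- fs / 2
  if (band$high >= ny * 0.999) {
    bf <- signal::butter(params$filter_order, band$low / ny, type = "high")
  } else {
    bf <- signal::butter(params$filter_order, c(band$low, band$high) / ny,
                         type = "pass")
  }
  y <- signal::filtfilt(bf, x)
  for (f0 in notch_freqs(band, fs)) {
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * params$notch_q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    y <- signal::filtfilt(signal::Arma(b = b, a = a), y)
  }
  y
}

notch_freqs <- function(band, fs) {
  h <- 60 * seq(1, by = 2, length.out = 16)
  h[h > band$low & h < band$high & h < fs / 2]
}

#' Band-specific preprocessing
#'
#' Zero-phase Butterworth band-pass in the ripple or fast-ripple band, plus
#' zero-phase notches at the odd harmonics of 60 Hz that fall inside the band.
#'
#' @param rec A [recording()].
#' @param band A [band_spec()] (or its name).
#' @param params A [detector_params()] (filter order / notch Q).
#' @return Filtered [recording()].
#' @export
preprocess <- function(rec, band, params = detector_params()) {
  stopifnot(inherits(rec, "hfo_recording"))
  if (is.character(band)) band <- band_spec(band)
  if (rec$fs < 2 * band$high) stop("sampling rate too low for this band")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    out$data[i, ] <- band_filter(rec$data[i, ], band, rec$fs, params)
  }
  out$ground_truth <- rec$ground_truth
  out
}

#' Sliding-window RMS envelope
#'
#' Centered root-mean-square in windows of `window` seconds; the output has
#' the same length as the input (edge windows are truncated).
#'
#' @param x Waveform.
#' @param fs Sampling rate, Hz.
#' @param window Window length, s (>= 2 samples).
#' @return Envelope, same length as `x`.
#' @export
rms_envelope <- function(x, fs, window = 0.003) {
  n <- length(x)
  w <- round(window * fs)
  if (w < 2) stop("rms window must span at least 2 samples")
  half_l <- (w - 1) %/% 2
  half_r <- w - 1 - half_l
  cs <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_l)
  hi <- pmin(n, i + half_r)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

# maximal runs of TRUE in a logical vector -> matrix(start, end) half-open
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' Stage 1: supra-threshold candidate segments
#'
#' Marks maximal runs where the RMS envelope exceeds
#' `T1 = mean + n_sd * SD` (of the envelope by default; a precomputed
#' threshold may be supplied). Runs separated by less than `merge_gap` are
#' merged before the minimum-duration test.
#'
#' @param env RMS envelope of one detection segment.
#' @param fs Sampling rate, Hz.
#' @param params A [detector_params()].
#' @param threshold Optional externally computed T1.
#' @return Integer matrix with columns `start`, `end` (1-based, half-open).
#'   Zero rows when the segment has no variance (skipped).
#' @export
stage1_candidates <- function(env, fs, params = detector_params(),
                              threshold = NULL) {
  empty <- cbind(start = integer(0), end = integer(0))
  if (is.null(threshold)) {
    s <- stats::sd(env)
    if (!is.finite(s) || s == 0) {
      attr(empty, "skipped") <- TRUE
      return(empty)
    }
    threshold <- mean(env) + params$n_sd * s
  }
  runs <- logical_runs(env > threshold)
  if (nrow(runs) == 0) return(empty)
  gap <- round(params$merge_gap * fs)
  if (nrow(runs) > 1 && gap > 0) {
    merged <- runs[1, , drop = FALSE]
    for (k in 2:nrow(runs)) {
      if (runs[k, "start"] - merged[nrow(merged), "end"] < gap) {
        merged[nrow(merged), "end"] <- runs[k, "end"]
      } else {
        merged <- rbind(merged, runs[k, , drop = FALSE])
      }
    }
    runs <- merged
  }
  min_len <- round(params$min_duration * fs)
  runs[runs[, "end"] - runs[, "start"] >= min_len, , drop = FALSE]
}

# strict local maxima of a vector; plateaus credited to their leftmost sample
local_maxima <- function(x) {
  r <- rle(x)
  v <- r$values
  k <- length(v)
  if (k < 3) return(integer(0))
  is_peak <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k], FALSE)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  starts[is_peak]
}

#' Stage 2: peak-count qualification
#'
#' A candidate becomes an HFO when the rectified filtered signal within it
#' has at least `min_peaks` strict local maxima above
#' `T2 = mean(|xf|) + n_sd * SD(|xf|)` (computed over the whole segment).
#' Rectification doubles the lobe rate to `2 f0`, which exceeds Nyquist for
#' fast ripples at common clinical sampling rates; peaks are therefore
#' counted on a band-limited (FFT zero-padding) upsampled copy of the
#' segment, so the count matches the signal's true oscillation cycles
#' (two rectified peaks per cycle) at any sampling rate.
#'
#' @param xf Band-filtered waveform of the detection segment.
#' @param candidates Matrix from [stage1_candidates()].
#' @param fs Sampling rate, Hz.
#' @param params A [detector_params()].
#' @param threshold Optional externally computed T2.
#' @param band Band of the segment (sets the anti-alias upsampling factor;
#'   `NULL` = no upsampling).
#' @return `data.frame(start, end, n_peaks)` of qualified events.
#' @export
stage2_qualify <- function(xf, candidates, fs, params = detector_params(),
                           threshold = NULL, band = NULL) {
  r <- abs(xf)
  if (is.null(threshold)) threshold <- mean(r) + params$n_sd * stats::sd(r)
  up <- if (is.null(band)) 1L else peak_upsample_factor(band, fs)
  xs <- if (up > 1L) fft_upsample(xf, up) else xf
  out <- data.frame(start = integer(0), end = integer(0), n_peaks = integer(0))
  for (k in seq_len(nrow(candidates))) {
    i0 <- candidates[k, "start"]
    i1 <- candidates[k, "end"] - 1L
    seg <- abs(xs[((i0 - 1L) * up + 1L):(i1 * up)])
    pk <- local_maxima(seg)
    np <- sum(seg[pk] > threshold)
    if (np >= params$min_peaks) {
      out <- rbind(out, data.frame(start = i0, end = i1 + 1L, n_peaks = np))
    }
  }
  out
}

# rectified lobes sit at 2*f0; sample them with at least ~4 points per lobe
peak_upsample_factor <- function(band, fs) {
  max(1L, as.integer(ceiling(8 * band$high / fs)))
}

# band-limited interpolation by FFT zero padding (amplitude preserving)
fft_upsample <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n < 4L) return(x)
  m <- n * k
  X <- stats::fft(x)
  Y <- complex(m)
  h <- floor(n / 2)
  if (n %% 2 == 0) {
    Y[1:h] <- X[1:h]
    Y[h + 1L] <- X[h + 1L] / 2
    Y[m - h + 1L] <- X[h + 1L] / 2
    if (h >= 2) Y[(m - h + 2L):m] <- X[(h + 2L):n]
  } else {
    Y[1:(h + 1L)] <- X[1:(h + 1L)]
    Y[(m - h + 1L):m] <- X[(h + 2L):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# extend event boundaries outward to the nearest sustained (>= min_run
# samples) excursion of the envelope at or below `floor_level`; short dips
# between oscillation lobes do not stop the extension. Merges events that
# come to overlap.
extend_boundaries <- function(events, env, floor_level, min_run = 3L) {
  if (nrow(events) == 0) return(events)
  runs <- logical_runs(env <= floor_level)
  runs <- runs[runs[, "end"] - runs[, "start"] >= min_run, , drop = FALSE]
  for (k in seq_len(nrow(events))) {
    lo <- runs[runs[, "end"] <= events$start[k], "end"]
    events$start[k] <- if (length(lo)) max(lo) else 1L
    hi <- runs[runs[, "start"] >= events$end[k], "start"]
    events$end[k] <- if (length(hi)) min(hi) else length(env) + 1L
  }
  events <- events[order(events$start), , drop = FALSE]
  keep <- events[1, , drop = FALSE]
  for (k in seq_len(nrow(events))[-1]) {
    if (events$start[k] < keep$end[nrow(keep)]) {
      keep$end[nrow(keep)] <- max(keep$end[nrow(keep)], events$end[k])
      keep$n_peaks[nrow(keep)] <- max(keep$n_peaks[nrow(keep)], events$n_peaks[k])
    } else {
      keep <- rbind(keep, events[k, , drop = FALSE])
    }
  }
  keep
}

# run the two detector stages on one filtered segment; returns events in
# segment-local coordinates
detect_segment <- function(xf, fs, params, band = NULL) {
  env <- rms_envelope(xf, fs, params$rms_window)
  if (params$threshold_reference == "rectified") {
    r <- abs(xf)
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) return(NULL)
    t1 <- mean(r) + params$n_sd * s
  } else {
    s <- stats::sd(env)
    if (!is.finite(s) || s == 0) return(NULL)
    t1 <- mean(env) + params$n_sd * s
  }
  cand <- stage1_candidates(env, fs, params, threshold = t1)
  ev <- stage2_qualify(xf, cand, fs, params, band = band)
  if (params$boundary_extension && nrow(ev) > 0) {
    ev <- extend_boundaries(ev, env, mean(env),
                            min_run = max(2L, round(params$rms_window * fs)))
  }
  ev
}

segment_bounds <- function(n, fs, segment_length) {
  seg_n <- round(segment_length * fs)
  starts <- seq(1L, n, by = seg_n)
  ends <- pmin(starts + seg_n - 1L, n)
  # fold a trailing sliver (< 1 s) into the previous segment
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1) < fs) {
    ends[length(ends) - 1] <- ends[length(ends)]
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  cbind(start = starts, end = ends)
}

empty_events <- function() {
  data.frame(
    channel = character(0), band = character(0),
    start = integer(0), end = integer(0),
    start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
    n_peaks = integer(0), stringsAsFactors = FALSE
  )
}

#' Detect HFOs in a recording
#'
#' Per channel, the record is band-filtered once and divided into one-minute
#' segments; both detection thresholds are recomputed within each segment.
#' Records shorter than one segment are processed as a single segment. When a
#' common-average signal is supplied, events are screened against detections
#' on the CAR and against wide-band transient/DC-shift artifacts
#' (see [reject_artifacts()]).
#'
#' @param rec A [recording()] (raw; filtering is internal).
#' @param band A [band_spec()] or its name.
#' @param params A [detector_params()].
#' @param car Optional common-average waveform for artifact rejection.
#' @param artifact_reject Apply the transient/DC-shift rule (and the CAR rule
#'   when `car` is given)?
#' @return Event table: `channel`, `band`, `start`/`end` (1-based half-open
#'   sample indices), `start_s`/`end_s`/`duration_s`, `n_peaks`.
#' @export
detect_hfos <- function(rec, band, params = detector_params(), car = NULL,
                        artifact_reject = TRUE) {
  stopifnot(inherits(rec, "hfo_recording"))
  if (is.character(band)) band <- band_spec(band)
  n <- ncol(rec$data)
  segs <- segment_bounds(n, rec$fs, params$segment_length)
  all_events <- list()
  for (ci in seq_len(nrow(rec$data))) {
    xf <- band_filter(rec$data[ci, ], band, rec$fs, params)
    for (si in seq_len(nrow(segs))) {
      i0 <- segs[si, "start"]
      i1 <- segs[si, "end"]
      ev <- detect_segment(xf[i0:i1], rec$fs, params, band = band)
      if (is.null(ev) || nrow(ev) == 0) next
      ev$start <- ev$start + i0 - 1L
      ev$end <- ev$end + i0 - 1L
      ev$channel <- rec$channel_ids[ci]
      all_events[[length(all_events) + 1L]] <- ev
    }
  }
  if (length(all_events) == 0) return(empty_events())
  events <- do.call(rbind, all_events)
  events$band <- band$name
  events$start_s <- (events$start - 1L) / rec$fs
  events$end_s <- (events$end - 1L) / rec$fs
  events$duration_s <- (events$end - events$start) / rec$fs
  events <- events[order(events$channel, events$start),
                   c("channel", "band", "start", "end",
                     "start_s", "end_s", "duration_s", "n_peaks")]
  rownames(events) <- NULL
  if (artifact_reject) {
    events <- reject_artifacts(events, rec, car, band, params)
  }
  events
}

#' Artifact rejection
#'
#' Two rules: (a) the full detector is run on the common-average signal and
#' any event overlapping a CAR detection is removed (skipped when `car` is
#' `NULL`); (b) an event is removed as a fast transient / DC shift when the
#' wide-band signal around it contains a step between adjacent 10 ms mean
#' levels exceeding `step_sd_mult` times the segment's wide-band SD, or when a
#' lone sample-to-sample jump would account for more than `jump_power_frac` of
#' the event's band power.
#'
#' @param events Event table from [detect_hfos()].
#' @param rec The raw (wide-band) [recording()].
#' @param car Common-average waveform or `NULL`.
#' @param band A [band_spec()] or its name.
#' @param params A [detector_params()].
#' @return Filtered event table.
#' @export
reject_artifacts <- function(events, rec, car, band, params = detector_params()) {
  if (nrow(events) == 0) return(events)
  if (is.character(band)) band <- band_spec(band)
  keep <- rep(TRUE, nrow(events))

  if (!is.null(car)) {
    car_rec <- recording(matrix(car, nrow = 1), rec$fs, channel_ids = "CAR")
    car_events <- detect_hfos(car_rec, band, params, car = NULL,
                              artifact_reject = FALSE)
    if (nrow(car_events) > 0) {
      for (k in seq_len(nrow(events))) {
        ov <- car_events$start < events$end[k] & car_events$end > events$start[k]
        if (any(ov)) keep[k] <- FALSE
      }
    }
  }

  n <- ncol(rec$data)
  segs <- segment_bounds(n, rec$fs, params$segment_length)
  blk <- max(1L, round(params$step_block * rec$fs))
  pad <- round(params$step_window * rec$fs)
  e_step <- band_step_energy(band, rec$fs, params)
  xf_cache <- new.env()
  for (k in which(keep)) {
    ci <- match(events$channel[k], rec$channel_ids)
    if (is.na(ci)) next
    x <- rec$data[ci, ]
    seg_i <- which(segs[, "start"] <= events$start[k] &
                     segs[, "end"] >= events$start[k])[1]
    xseg <- x[segs[seg_i, "start"]:segs[seg_i, "end"]]
    # robust wide-band noise scale: unaffected by the very steps being tested
    seg_sd <- stats::mad(diff(xseg)) / sqrt(2)
    lo <- max(1L, events$start[k] - pad)
    hi <- min(n, events$end[k] - 1L + pad)
    win <- x[lo:hi]
    nb <- length(win) %/% blk
    if (nb >= 2) {
      means <- colMeans(matrix(win[seq_len(nb * blk)], nrow = blk))
      if (max(abs(diff(means))) > params$step_sd_mult * seg_sd) {
        keep[k] <- FALSE
        next
      }
    }
    ev_x <- x[events$start[k]:(events$end[k] - 1L)]
    dd <- abs(diff(ev_x))
    if (length(dd) >= 3) {
      dmax <- max(dd)
      typical <- stats::median(dd)
      if (dmax > params$jump_ratio * max(typical, .Machine$double.eps)) {
        key <- events$channel[k]
        if (is.null(xf_cache[[key]])) {
          xf_cache[[key]] <- band_filter(x, band, rec$fs, params)
        }
        e_event <- sum(xf_cache[[key]][events$start[k]:(events$end[k] - 1L)]^2)
        if (dmax^2 * e_step > params$jump_power_frac * e_event) {
          keep[k] <- FALSE
        }
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# band energy injected by a unit-height step, computed numerically from the
# filtered step response
band_step_energy <- function(band, fs, params) {
  n <- round(2 * fs)
  step <- c(numeric(n / 2), rep(1, n - n / 2))
  sum(band_filter(step, band, fs, params)^2)
}
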