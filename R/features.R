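#' Analytic-signal (Hilbert) envelope
#'
#' Magnitude of the analytic signal, computed through the FFT.
#'
#' @param x Real waveform.
#' @return Envelope, same length as `x`.
#' @export
analytic_envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' HFO amplitude: mean upper Hilbert envelope over the event
#'
#' The envelope is computed on the event padded by `pad` seconds on each side
#' (reflection padding at record edges) to limit edge effects, then cropped to
#' the event samples and averaged.
#'
#' @param start,end Event sample indices (1-based, half-open).
#' @param xf Band-filtered waveform of the whole channel.
#' @param fs Sampling rate, Hz.
#' @param pad Padding, s (default 50 ms).
#' @return Amplitude in uV.
#' @export
event_amplitude <- function(start, end, xf, fs, pad = 0.05) {
  n <- length(xf)
  stopifnot(end > start, start >= 1, end <= n + 1)
  np <- round(pad * fs)
  idx <- (start - np):(end - 1L + np)
  # reflect indices that fall outside the record
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  env <- analytic_envelope(xf[idx])
  mean(env[(np + 1L):(np + end - start)])
}

#' HFO peak frequency after spectral whitening
#'
#' The event segment is whitened by first-order differencing (attenuating
#' low-frequency power), Hann-windowed, zero-padded to at least 1 Hz
#' resolution, and the frequency of maximal spectral magnitude within the
#' band is returned. Events shorter than two cycles of the band's lower edge
#' have no defined peak frequency (`NA`).
#'
#' @inheritParams event_amplitude
#' @param band A [band_spec()] or its name.
#' @return Peak frequency, Hz, or `NA`.
#' @export
event_peak_frequency <- function(start, end, xf, fs, band) {
  if (is.character(band)) band <- band_spec(band)
  len <- end - start
  if (len / fs < 2 / band$low) return(NA_real_)
  seg <- diff(xf[start:(end - 1L)])
  m <- length(seg)
  if (m < 4) return(NA_real_)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
  nfft <- max(ceiling(fs), 2^ceiling(log2(m)))
  spec <- Mod(stats::fft(c(seg * win, numeric(nfft - m))))
  freqs <- (0:(nfft - 1)) * fs / nfft
  sel <- freqs >= band$low & freqs <= min(band$high, fs / 2)
  freqs[sel][which.max(spec[sel])]
}

#' Attach amplitude and peak frequency to detected events
#'
#' @param events Event table from [detect_hfos()].
#' @param rec The raw [recording()] the events came from.
#' @param band A [band_spec()] or its name.
#' @param params A [detector_params()] (for the band filter).
#' @return Event table with `amplitude` (uV) and `peak_freq` (Hz) columns.
#' @export
annotate_features <- function(events, rec, band, params = detector_params()) {
  if (is.character(band)) band <- band_spec(band)
  events$amplitude <- numeric(nrow(events))
  events$peak_freq <- numeric(nrow(events))
  if (nrow(events) == 0) return(events)
  for (ch in unique(events$channel)) {
    ci <- match(ch, rec$channel_ids)
    xf <- band_filter(rec$data[ci, ], band, rec$fs, params)
    rows <- which(events$channel == ch)
    for (k in rows) {
      events$amplitude[k] <- event_amplitude(events$start[k], events$end[k],
                                             xf, rec$fs)
      events$peak_freq[k] <- event_peak_frequency(events$start[k],
                                                  events$end[k], xf, rec$fs,
                                                  band)
    }
  }
  events
}

#' Group temporally overlapping events across channels
#'
#' Events whose intervals overlap (strictly positive intersection, chained
#' transitively) form one group; the group's spread `S` is the number of
#' distinct channels involved. An HFO observed on only one electrode with no
#' temporal overlap elsewhere has `S = 1`.
#'
#' @param events Event table (any channels).
#' @param fs Sampling rate, Hz (for the group span in seconds).
#' @return `list(events =, groups =)`: the events gain a `group_id` column;
#'   `groups` is a table with `group_id`, `start`, `end`, `span_s`,
#'   `n_members`, `spread`.
#' @export
group_events <- function(events, fs) {
  if (nrow(events) == 0) {
    return(list(
      events = cbind(events, group_id = integer(0)),
      groups = data.frame(group_id = integer(0), start = integer(0),
                          end = integer(0), span_s = numeric(0),
                          n_members = integer(0), spread = integer(0))
    ))
  }
  ord <- order(events$start, events$end)
  ev <- events[ord, , drop = FALSE]
  gid <- integer(nrow(ev))
  cur <- 0L
  cur_end <- -Inf
  for (k in seq_len(nrow(ev))) {
    if (ev$start[k] < cur_end) {
      gid[k] <- cur
      cur_end <- max(cur_end, ev$end[k])
    } else {
      cur <- cur + 1L
      gid[k] <- cur
      cur_end <- ev$end[k]
    }
  }
  ev$group_id <- gid
  groups <- do.call(rbind, lapply(split(ev, ev$group_id), function(g) {
    data.frame(
      group_id = g$group_id[1],
      start = min(g$start), end = max(g$end),
      span_s = (max(g$end) - min(g$start)) / fs,
      n_members = nrow(g),
      spread = length(unique(g$channel))
    )
  }))
  rownames(groups) <- NULL
  rownames(ev) <- NULL
  list(events = ev, groups = groups)
}

#' Per-channel HFO rates
#'
#' @param events Event table.
#' @param duration_min Recording duration, minutes.
#' @param channels Channel labels (channels with no events report 0).
#' @return `data.frame(channel, rate)` in events/min.
#' @export
channel_rates <- function(events, duration_min, channels) {
  stopifnot(duration_min > 0)
  counts <- table(factor(events$channel, levels = channels))
  data.frame(
    channel = channels,
    rate = as.numeric(counts) / duration_min,
    stringsAsFactors = FALSE
  )
}

#' Global HFO rate per unit electrode area
#'
#' Unique events (temporally overlapping detections counted once, via
#' [group_events()]) per minute, divided by the summed physical contact area.
#' The summed area is the same for the small, pair and quad schemes
#' (64 x 1.08 = 69.12 mm^2 on the default grid); for a single simulated
#' electrode it is that electrode's area.
#'
#' @param groups Group table from [group_events()].
#' @param duration_min Recording duration, minutes.
#' @param total_area_mm2 Summed physical contact area, mm^2 (see
#'   [scheme_total_area()]).
#' @return Rate in events/min/mm^2.
#' @export
global_rate_per_area <- function(groups, duration_min, total_area_mm2) {
  stopifnot(duration_min > 0, total_area_mm2 > 0)
  nrow(groups) / duration_min / total_area_mm2
}
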