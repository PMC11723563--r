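#' Write / read event tables
#'
#' CSV with a stable column order; an empty event list produces a header-only
#' file.
#'
#' @param events Event table ([detect_hfos()] output, possibly annotated).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  lead <- intersect(
    c("channel", "band", "start", "end", "start_s", "end_s", "duration_s",
      "n_peaks", "amplitude", "peak_freq", "group_id", "record", "area"),
    names(events)
  )
  events <- events[, c(lead, setdiff(names(events), lead)), drop = FALSE]
  data.table::fwrite(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Ground-truth table of a simulated recording
#'
#' Flattens the per-channel injected trains into one table.
#'
#' @param rec A simulated [recording()].
#' @return `data.frame(channel, onset_s, duration_s, amplitude_uV, f0_hz,
#'   phase, rho_hfog)`.
#' @export
ground_truth_table <- function(rec) {
  stopifnot(inherits(rec, "hfo_recording"))
  if (is.null(rec$ground_truth)) {
    stop("recording carries no ground truth")
  }
  rows <- lapply(seq_along(rec$ground_truth), function(i) {
    gt <- rec$ground_truth[[i]]
    tr <- gt$train
    if (is.null(tr) || NROW(tr) == 0) return(NULL)
    data.frame(
      channel = rec$channel_ids[i],
      onset_s = tr$onset, duration_s = tr$d, amplitude_uV = tr$K,
      f0_hz = tr$f0, phase = tr$phase, rho_hfog = gt$rho
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      channel = character(0), onset_s = numeric(0), duration_s = numeric(0),
      amplitude_uV = numeric(0), f0_hz = numeric(0), phase = numeric(0),
      rho_hfog = numeric(0)
    )
  }
  out
}

#' Write / read a recording container
#'
#' A portable directory container: `meta.json` (rate, channels, areas),
#' `signals.csv` (samples x channels, uV) and, when present,
#' `ground_truth.csv`. Round-trips signals at full double precision.
#'
#' @param rec A [recording()].
#' @param dir Container directory (created if needed).
#' @return `dir` (write) or the restored [recording()] (read).
#' @export
write_recording_container <- function(rec, dir) {
  stopifnot(inherits(rec, "hfo_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    fs = rec$fs,
    channel_ids = rec$channel_ids,
    electrode_area = rec$electrode_area,
    n_samples = ncol(rec$data),
    has_ground_truth = !is.null(rec$ground_truth)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  sig <- as.data.frame(t(rec$data))
  names(sig) <- rec$channel_ids
  data.table::fwrite(sig, file.path(dir, "signals.csv"))
  if (!is.null(rec$ground_truth)) {
    data.table::fwrite(ground_truth_table(rec), file.path(dir, "ground_truth.csv"))
  }
  invisible(dir)
}

#' @rdname write_recording_container
#' @export
read_recording_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  sig <- data.table::fread(file.path(dir, "signals.csv"))
  data <- t(as.matrix(sig))
  rec <- recording(data, meta$fs, channel_ids = meta$channel_ids,
                   electrode_area = meta$electrode_area)
  gt_path <- file.path(dir, "ground_truth.csv")
  if (isTRUE(meta$has_ground_truth) && file.exists(gt_path)) {
    gt <- as.data.frame(data.table::fread(gt_path))
    rec$ground_truth <- lapply(meta$channel_ids, function(ch) {
      g <- gt[gt$channel == ch, , drop = FALSE]
      if (nrow(g) == 0) return(list(train = NULL, rho = NA_real_))
      train <- data.frame(onset = g$onset_s, d = g$duration_s,
                          K = g$amplitude_uV, f0 = g$f0_hz, phase = g$phase)
      class(train) <- c("hfo_train", "data.frame")
      list(train = train, rho = g$rho_hfog[1])
    })
  }
  rec
}

#' Read a recording from disk
#'
#' @param path Container directory or EDF file.
#' @param format `"container"` or `"edf"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("container", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format,
    container = read_recording_container(path),
    edf = read_edf(path)
  )
}

#' Serialize / restore a simulation configuration as YAML
#'
#' @param cfg A [simulation_config()].
#' @param path YAML file.
#' @return `path` (write) / the restored config (read).
#' @export
write_simulation_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  lst <- list(
    fs = cfg$fs, duration = cfg$duration, band = cfg$band,
    dist_s = dist_to_list(cfg$dist_s),
    dist_d = dist_to_list(cfg$dist_d),
    dist_K = dist_to_list(cfg$dist_K),
    dist_rho = dist_to_list(cfg$dist_rho),
    dist_f0 = dist_to_list(cfg$dist_f0),
    bg_sigma = cfg$bg_sigma, bg_exponent = cfg$bg_exponent,
    electrode = unclass(cfg$electrode),
    measurement_noise = cfg$measurement_noise,
    seed = cfg$seed
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  lst <- yaml::read_yaml(path)
  em <- lst$electrode
  simulation_config(
    fs = lst$fs, duration = lst$duration, band = lst$band,
    dist_s = dist_from_list(lst$dist_s),
    dist_d = dist_from_list(lst$dist_d),
    dist_K = dist_from_list(lst$dist_K),
    dist_rho = dist_from_list(lst$dist_rho),
    dist_f0 = dist_from_list(lst$dist_f0),
    bg_sigma = lst$bg_sigma, bg_exponent = lst$bg_exponent,
    electrode = electrode_model(
      area = em$area, c_dl = em$c_dl, r_ct = em$r_ct,
      tissue_resistivity = em$tissue_resistivity,
      z_in = em$z_in, temperature = em$temperature, material = em$material
    ),
    measurement_noise = lst$measurement_noise,
    seed = lst$seed
  )
}

#' Write a run manifest
#'
#' JSON record of the package version, seed and per-stage parameters,
#' sufficient to re-run a deterministic stage identically.
#'
#' @param path Output JSON file.
#' @param stage Stage label.
#' @param params Named list of stage parameters (serializable).
#' @param seed Seed(s) used.
#' @param inputs Character vector of input files/directories.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, stage, params = list(), seed = NA,
                               inputs = character(0)) {
  manifest <- list(
    stage = stage,
    package = "hfoarea",
    version = as.character(utils::packageVersion("hfoarea")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
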