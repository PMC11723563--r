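#' Write a recording to EDF
#'
#' European Data Format (16-bit), the clinical interchange format for EEG.
#' One data record per second; a final partial second is zero-padded. Physical
#' units are uV; each channel is scaled to the full 16-bit digital range of
#' its own amplitude extent.
#'
#' @param rec A [recording()].
#' @param path Output `.edf` file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "hfo_recording"))
  ns <- nrow(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  data <- if (pad > 0) cbind(rec$data, matrix(0, ns, pad)) else rec$data

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  pad80 <- function(x) formatC(substr(x, 1, 80), width = 80, flag = "-")
  pad8 <- function(x) formatC(substr(as.character(x), 1, 8), width = 8, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad8("0"),
    pad80("X X X X"),
    pad80("Startdate X X X X"),
    "01.01.00", "00.00.00",
    pad8(256L * (1L + ns)),
    formatC("", width = 44, flag = "-"),
    pad8(n_rec),
    pad8(1L),
    formatC(as.character(ns), width = 4, flag = "-")
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste0(formatC(substr(as.character(vals), 1, width),
                             width = width, flag = "-"), collapse = ""),
              con, eos = NULL)
  }
  fld(rec$channel_ids, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin_, format = "g", digits = 7), 8)
  fld(formatC(pmax_, format = "g", digits = 7), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)

  # re-read the printed physical bounds so the scaling matches what a reader
  # will parse from the 8-char header fields
  pmin_h <- as.numeric(formatC(pmin_, format = "g", digits = 7))
  pmax_h <- as.numeric(formatC(pmax_, format = "g", digits = 7))
  scale <- (pmax_h - pmin_h) / (dmax - dmin)
  dig <- matrix(0L, ns, ncol(data))
  for (i in seq_len(ns)) {
    d <- round((data[i, ] - pmin_h[i]) / scale[i]) + dmin
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      writeBin(dig[i, idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path `.edf` file.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80) # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80) # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("channels disagree on samples per record; not supported")
  }
  if (length(unique(tolower(units))) != 1) {
    stop("channels disagree on physical units; not supported")
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      data[i, idx] <- pmin_[i] + (d - dmin[i]) * scale[i]
    }
  }
  recording(data, fs, channel_ids = labels)
}
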