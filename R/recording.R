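#' Construct a multichannel EEG recording
#'
#' The basic container used by every stage of the pipeline: a channels x
#' samples matrix of amplitudes in microvolts plus the sampling rate and the
#' ordered 10-20 channel labels.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels (rownames of `data`
#'   are used when omitted).
#' @param subject_id subject identifier string.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = rownames(data),
                          subject_id = "S00") {
  if (!is.matrix(data) || !is.numeric(data)) stop("'data' must be a numeric matrix")
  stopifnot_scalar_pos(fs, "fs")
  if (is.null(channels) || length(channels) != nrow(data))
    stop("'channels' must match nrow(data)")
  rownames(data) <- channels
  structure(list(subject_id = subject_id, fs = fs,
                 channels = channels, data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Plain EDF (not EDF+), one 1-second data record per second, 16-bit samples,
#' physical range +/- `phys_max` microvolts. The sampling rate must give an
#' integer number of samples per 1 s record and the duration is truncated to
#' whole seconds.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param phys_max symmetric physical range in microvolts (default 200,
#'   headroom above the 70 uV artifact-rejection threshold).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_max = 200) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf needs an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- length(rec$channels)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one 1 s EDF record")
  dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field("eegdx synthetic cohort", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(rec$channels, pad_field, "", width = 16), collapse = ""),
    strrep(pad_field("AgAgCl electrode", 80), ns),
    strrep(pad_field("uV", 8), ns),
    strrep(pad_field(-phys_max, 8), ns),
    strrep(pad_field(phys_max, 8), ns),
    strrep(pad_field(-dig_max, 8), ns),
    strrep(pad_field(dig_max, 8), ns),
    strrep(pad_field("", 80), ns),
    strrep(pad_field(fs, 8), ns),
    strrep(pad_field("", 32), ns)
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  scl <- dig_max / phys_max
  dig <- matrix(as.integer(pmax(-dig_max, pmin(dig_max, round(x * scl)))),
                nrow = nrow(x))
  # record-major layout: record 1 signal 1..ns, record 2 signal 1..ns, ...
  out <- integer(ns * fs * n_rec)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    out[((r - 1) * ns * fs + 1):(r * ns * fs)] <- as.integer(t(dig[, cols]))
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file written by this package (or any plain EDF)
#'
#' @param path EDF file path.
#' @return an `eeg_recording` with amplitudes converted back to physical
#'   units (microvolts).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                               # version
  subject_id <- trimws(rd(80))
  rd(80); rd(8); rd(8)
  rd(8)                               # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  pmax_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmin_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmax_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  rd(80 * ns)
  spr <- as.integer(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  rd(32 * ns)
  if (length(unique(spr)) != 1L) stop("mixed sampling rates are not supported")
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2,
                 endian = "little")
  if (length(raw) < n_rec * sum(spr))
    stop("EDF payload shorter than the header promises (truncated file?)")
  dat <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[((r - 1) * ns * spr[1] + 1):(r * ns * spr[1])],
                    nrow = spr[1])
    dat[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  scl <- (pmax_ - pmin_) / (dmax_ - dmin_)
  off <- pmax_ - scl * dmax_
  dat <- dat * scl + off
  eeg_recording(dat, fs = fs, channels = labels, subject_id = subject_id)
}
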