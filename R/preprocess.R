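#' Segment a recording into fixed-length non-overlapping epochs
#'
#' Epochs are counted from t = 0; a trailing remainder shorter than one
#' epoch is discarded, so a 600 s recording yields exactly 300 two-second
#' epochs.
#'
#' @param rec an `eeg_recording`.
#' @param epoch_len_s epoch length in seconds (default 2).
#' @return an `eeg_epochs` object: list with `epochs` (list of channel x
#'   sample matrices), `epoch_len_s`, `keep_flags`, `fs`, `channels`,
#'   `subject_id`.
#' @export
make_epochs <- function(rec, epoch_len_s = 2) {
  stopifnot_scalar_pos(epoch_len_s, "epoch_len_s")
  spe <- round(epoch_len_s * rec$fs)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep == 0) warning("recording shorter than one epoch; zero epochs")
  eps <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    eps[[i]] <- rec$data[, ((i - 1) * spe + 1):(i * spe), drop = FALSE]
  }
  structure(list(epochs = eps, epoch_len_s = epoch_len_s,
                 keep_flags = rep(TRUE, n_ep), fs = rec$fs,
                 channels = rec$channels, subject_id = rec$subject_id),
            class = "eeg_epochs")
}

#' Detect bad channels
#'
#' A channel is flagged when it is flat (variance below `flat_var` uV^2) or
#' when its log-variance deviates from the montage median by more than
#' `z_max` robust z-units (median/MAD).
#'
#' @param rec an `eeg_recording` with at least 4 channels.
#' @param flat_var flat-line variance threshold (default 1e-12).
#' @param z_max robust z-score threshold (default 5).
#' @return character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, flat_var = 1e-12, z_max = 5) {
  if (nrow(rec$data) < 4) stop("need at least 4 channels")
  v <- apply(rec$data, 1, stats::var)
  flat <- v < flat_var
  lv <- log(pmax(v, flat_var))
  usable <- !flat
  bad_var <- rep(FALSE, length(v))
  if (sum(usable) >= 4) {
    med <- stats::median(lv[usable])
    madv <- stats::mad(lv[usable])
    if (madv > 0) bad_var <- usable & abs(lv - med) / madv > z_max
  }
  rec$channels[flat | bad_var]
}

# Legendre-polynomial series for the spherical-spline kernel
# (m = stiffness, n_terms Legendre terms).
spline_g <- function(cosang, m = 4, n_terms = 50) {
  out <- matrix(0, nrow(cosang), ncol(cosang))
  p_nm1 <- matrix(1, nrow(cosang), ncol(cosang))   # P_0
  p_n <- cosang                                     # P_1
  for (n in seq_len(n_terms)) {
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_n
    p_np1 <- ((2 * n + 1) * cosang * p_n - n * p_nm1) / (n + 1)
    p_nm1 <- p_n; p_n <- p_np1
  }
  out / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces flagged channels with a spherical-spline reconstruction from the
#' remaining channels at idealized 10-20 scalp positions (stiffness 4, 50
#' Legendre terms, ridge regularization 1e-5). Good channels are returned
#' unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param bad character vector of channel labels to rebuild.
#' @return the repaired `eeg_recording`.
#' @export
interpolate_channels <- function(rec, bad, reg = 1e-5) {
  if (length(bad) == 0) return(rec)
  if (!all(bad %in% rec$channels)) stop("'bad' contains unknown labels")
  good <- setdiff(rec$channels, bad)
  if (length(good) < 3) stop("fewer than 3 good channels remain")
  pos <- electrode_positions(rec$channels)
  gi <- match(good, rec$channels); bi <- match(bad, rec$channels)
  cg <- pos[gi, , drop = FALSE]; cb <- pos[bi, , drop = FALSE]
  G <- spline_g(tcrossprod(cg))                 # good x good
  Gb <- spline_g(cb %*% t(cg))                  # bad x good
  g <- length(gi)
  A <- rbind(cbind(G + diag(reg, g), rep(1, g)),
             c(rep(1, g), 0))
  X <- solve(A, rbind(diag(g), rep(0, g)))      # (g+1) x g
  M <- cbind(Gb, rep(1, length(bi))) %*% X      # bad x good mapping
  out <- rec$data
  out[bi, ] <- M %*% rec$data[gi, , drop = FALSE]
  eeg_recording(out, fs = rec$fs, channels = rec$channels,
                subject_id = rec$subject_id)
}

#' Reject epochs exceeding an amplitude threshold
#'
#' An epoch is marked not-kept when any sample on any channel is strictly
#' greater than `threshold_uv` in absolute value; a sample at exactly the
#' threshold survives. Already-rejected epochs stay rejected, so the
#' operation is idempotent.
#'
#' @param ep an `eeg_epochs`.
#' @param threshold_uv rejection threshold in microvolts (default 70).
#' @return the `eeg_epochs` with updated `keep_flags`.
#' @export
reject_amplitude <- function(ep, threshold_uv = 70) {
  stopifnot_scalar_pos(threshold_uv, "threshold_uv")
  over <- vapply(ep$epochs, function(e) max(abs(e)) > threshold_uv, logical(1))
  ep$keep_flags <- ep$keep_flags & !over
  ep
}

#' Build the per-recording screening report
#'
#' A recording is included when strictly more than `min_effective` of its
#' epochs survive rejection (the default reproduces the "more than 50%
#' effective segments" rule; exactly half is excluded).
#'
#' @param ep an `eeg_epochs` after rejection.
#' @param bad_channels labels interpolated earlier in the chain.
#' @param n_ica_removed blink components removed.
#' @param min_effective inclusion threshold on the effective fraction.
#' @return a one-row data.frame screening report.
#' @export
screen_recording <- function(ep, bad_channels = character(0),
                             n_ica_removed = 0L, min_effective = 0.5) {
  n_tot <- length(ep$keep_flags)
  n_eff <- sum(ep$keep_flags)
  if (n_tot == 0) {
    warning("recording has zero epochs; excluded")
    frac <- 0
  } else {
    frac <- n_eff / n_tot
  }
  data.frame(subject_id = ep$subject_id,
             n_epochs_total = n_tot,
             n_epochs_effective = n_eff,
             bad_channels = paste(bad_channels, collapse = ";"),
             n_ica_components_removed = as.integer(n_ica_removed),
             effective_fraction = frac,
             included = n_tot > 0 && frac > min_effective,
             stringsAsFactors = FALSE)
}

#' Concatenate kept epochs and export them as EDF
#'
#' The kept epochs are concatenated in temporal order, re-filtered with the
#' same bandpass + notch design as the first stage, and written to EDF with
#' the original labels and sampling rate. Refuses to write when screening
#' failed.
#'
#' @param ep an `eeg_epochs` after rejection.
#' @param report screening report from [screen_recording()].
#' @param path output EDF path (NULL returns the recording unwritten).
#' @param low,high,notch filter parameters, as in [bandpass_notch_filter()].
#' @return the cleaned `eeg_recording` (invisibly written to `path`).
#' @export
export_effective <- function(ep, report, path = NULL,
                             low = 0.5, high = 50, notch = 50) {
  if (!isTRUE(report$included))
    stop("recording failed effective-segment screening; refusing to export")
  kept <- ep$epochs[ep$keep_flags]
  dat <- do.call(cbind, kept)
  rec <- eeg_recording(dat, fs = ep$fs, channels = ep$channels,
                       subject_id = ep$subject_id)
  rec <- bandpass_notch_filter(rec, low = low, high = high, notch = notch)
  if (!is.null(path)) write_edf(rec, path)
  rec
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed stage order: bandpass + notch filter, 2 s epoching, bad-channel
#' detection and spherical-spline interpolation, ICA blink removal,
#' +/-70 uV amplitude rejection, effective-segment screening, and (when the
#' recording is included) export of the concatenated effective signal.
#'
#' @param rec a raw `eeg_recording`.
#' @param out_path optional EDF path for the cleaned signal.
#' @param threshold_uv amplitude-rejection threshold (default 70).
#' @param min_effective screening fraction (default 0.5, strict).
#' @param seed ICA seed.
#' @param low,high,notch filter settings.
#' @param epoch_len_s epoch length (default 2).
#' @return list with `report` (one-row data.frame), `clean` (the cleaned
#'   `eeg_recording`, or NULL when excluded) and `epochs` (the flagged
#'   `eeg_epochs`).
#' @export
preprocess_recording <- function(rec, out_path = NULL, threshold_uv = 70,
                                 min_effective = 0.5, seed = 1L,
                                 low = 0.5, high = 50, notch = 50,
                                 epoch_len_s = 2) {
  filt <- bandpass_notch_filter(rec, low = low, high = high, notch = notch)
  bad <- detect_bad_channels(filt)
  if (length(bad) > length(filt$channels) / 2) {
    warning(sprintf("%s: more than half of the channels are bad; excluded",
                    rec$subject_id))
    ep0 <- make_epochs(filt, epoch_len_s)
    ep0$keep_flags[] <- FALSE
    return(list(report = screen_recording(ep0, bad, 0L, min_effective),
                clean = NULL, epochs = ep0))
  }
  if (length(bad) > 0) filt <- interpolate_channels(filt, bad)
  ica <- remove_blinks_ica(filt, seed = seed)
  ep <- make_epochs(ica$recording, epoch_len_s)
  ep <- reject_amplitude(ep, threshold_uv)
  report <- screen_recording(ep, bad, ica$n_removed, min_effective)
  clean <- NULL
  if (isTRUE(report$included)) {
    clean <- export_effective(ep, report, out_path,
                              low = low, high = high, notch = notch)
  }
  list(report = report, clean = clean, epochs = ep)
}

#' Preprocess a directory (or list) of recordings
#'
#' @param recordings either a character vector of EDF paths or a named list
#'   of `eeg_recording` objects.
#' @param out_dir directory for cleaned EDF files (NULL keeps results in
#'   memory).
#' @param ... passed to [preprocess_recording()].
#' @param seed master seed; each subject gets a derived ICA seed.
#' @return list with `reports` (data.frame, one row per recording) and
#'   `clean` (named list of cleaned recordings, included subjects only).
#' @export
preprocess_cohort <- function(recordings, out_dir = NULL, seed = 1L, ...) {
  reports <- list(); clean <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  nm <- names(recordings)
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    if (is.character(rec)) rec <- read_edf(rec)
    out_path <- if (!is.null(out_dir))
      file.path(out_dir, paste0(rec$subject_id, "_clean.edf")) else NULL
    res <- preprocess_recording(
      rec, out_path = out_path,
      seed = derive_seed(seed, paste0("ica:", rec$subject_id)), ...)
    reports[[i]] <- res$report
    if (!is.null(res$clean)) clean[[rec$subject_id]] <- res$clean
  }
  list(reports = do.call(rbind, reports), clean = clean)
}
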