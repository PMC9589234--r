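#' Configuration for the synthetic EEG cohort generator
#'
#' Defines the study conditions emulated by the generator: a 19-channel
#' eyes-closed resting-state recording at 500 Hz with a 1/f background, a
#' band-limited alpha rhythm with occipital dominance, eye-blink transients
#' projected to the frontal-polar electrodes, 50 Hz mains interference,
#' occasional high-amplitude artifact bursts and (rarely) a dead channel.
#' The between-class effect is a frontal alpha-power asymmetry: the
#' F3/F4 alpha log-power ratio is shifted by `effect_size * latent_severity`
#' (natural-log units).
#'
#' @param n_healthy,n_nonmajor,n_major group sizes (defaults 30/16/16, the
#'   cohort composition the pipeline was designed around).
#' @param duration_s recording length in seconds (default 600).
#' @param fs sampling rate in Hz (default 500).
#' @param channels ordered 10-20 labels (19 required).
#' @param effect_size alpha-asymmetry shift per unit latent severity, in
#'   natural-log power units; 0 disables the between-class effect.
#' @param blink_rate eye blinks per minute on FP1/FP2 (default 12).
#' @param blink_amp_uv peak blink amplitude at the frontal pole (default 160).
#' @param line_noise_amp 50 Hz sinusoid amplitude in microvolts (default 5).
#' @param artifact_epoch_frac fraction of 2 s spans injected with >70 uV
#'   bursts (default 0.1).
#' @param bad_channel_prob per-subject probability of one dead (flat)
#'   channel (default 0.1); the frontal-polar pair is never chosen.
#' @param pink_amp_uv RMS of the per-channel 1/f background (default 10).
#' @param alpha_amp_uv named or unnamed base alpha RMS per region; scalar
#'   scales the built-in occipital-dominant profile (default 1).
#' @param subject_sd,channel_sd log-normal inter-subject and inter-channel
#'   amplitude variability (defaults 0.15 and 0.05).
#' @param seed master seed; every output is a pure function of the config.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_healthy = 30, n_nonmajor = 16, n_major = 16,
                             duration_s = 600, fs = 500,
                             channels = MONTAGE_1020,
                             effect_size = 1, blink_rate = 12,
                             blink_amp_uv = 160, line_noise_amp = 5,
                             artifact_epoch_frac = 0.1,
                             bad_channel_prob = 0.1,
                             pink_amp_uv = 10, alpha_amp_uv = 1,
                             subject_sd = 0.15, channel_sd = 0.05,
                             seed = 1L) {
  cfg <- list(n_healthy = n_healthy, n_nonmajor = n_nonmajor,
              n_major = n_major, duration_s = duration_s, fs = fs,
              channels = channels, effect_size = effect_size,
              blink_rate = blink_rate, blink_amp_uv = blink_amp_uv,
              line_noise_amp = line_noise_amp,
              artifact_epoch_frac = artifact_epoch_frac,
              bad_channel_prob = bad_channel_prob,
              pink_amp_uv = pink_amp_uv, alpha_amp_uv = alpha_amp_uv,
              subject_sd = subject_sd, channel_sd = channel_sd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot_scalar_pos(cfg$duration_s, "duration_s")
  stopifnot_scalar_pos(cfg$fs, "fs")
  if (abs(cfg$duration_s * cfg$fs - round(cfg$duration_s * cfg$fs)) > 1e-6)
    stop("duration_s * fs must be an integer number of samples", call. = FALSE)
  if (length(cfg$channels) != 19L || anyDuplicated(cfg$channels))
    stop("'channels' must be 19 unique 10-20 labels", call. = FALSE)
  for (f in c("artifact_epoch_frac", "bad_channel_prob")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be in [0, 1]", f), call. = FALSE)
  }
  for (f in c("effect_size", "blink_rate", "line_noise_amp"))
    if (cfg[[f]] < 0) stop(sprintf("'%s' must be >= 0", f), call. = FALSE)
  if (any(c(cfg$n_healthy, cfg$n_nonmajor, cfg$n_major) < 0))
    stop("group counts must be >= 0", call. = FALSE)
  invisible(cfg)
}

# Base alpha RMS (uV) per electrode: occipital-dominant gradient.
alpha_gain_profile <- function(channels) {
  g <- c(FP1 = 5, FP2 = 5, F3 = 7, F4 = 7, F7 = 7, F8 = 7, Fz = 7,
         T3 = 9, T4 = 9, T5 = 12, T6 = 12, P3 = 12, P4 = 12, Pz = 12,
         O1 = 18, O2 = 18, C3 = 9, C4 = 9, Cz = 9)
  names(g) <- toupper(names(g))
  out <- g[toupper(channels)]
  if (anyNA(out)) stop("alpha profile undefined for some channel labels")
  unname(out)
}

# 1/f ("pink") noise via spectral shaping, unit RMS.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1))           # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)             # mirror for negative frequencies
  shape <- 1 / sqrt(pmax(f, 1))
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited noise via FFT masking, unit RMS.
bandlimited_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(stats::fft(sp * mask, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < .Machine$double.eps) stop("empty frequency band")
  x / s
}

# 300 ms smooth biphasic blink template, peak amplitude 1.
blink_template <- function(fs, dur_s = 0.3) {
  n <- round(dur_s * fs)
  t <- seq_len(n) / n
  w <- sin(2 * pi * t) * (0.5 - 0.5 * cos(2 * pi * t))
  w / max(abs(w))
}

# Blink spatial projection: dominated by the frontal pole.
blink_projection <- function(channels) {
  p <- c(FP1 = 1, FP2 = 1, F7 = 0.35, F8 = 0.35, F3 = 0.3, F4 = 0.3,
         Fz = 0.3, C3 = 0.08, C4 = 0.08, Cz = 0.08, T3 = 0.05, T4 = 0.05,
         T5 = 0.02, T6 = 0.02, P3 = 0.02, P4 = 0.02, Pz = 0.02,
         O1 = 0.01, O2 = 0.01)
  names(p) <- toupper(names(p))
  unname(p[toupper(channels)])
}

#' Generate questionnaire scores from a latent severity
#'
#' Maps a latent severity in \[0, 1\] to SDS, SAS, nine SCL-90 subscales and
#' the four EPQ subscales. SDS, SAS, all SCL-90 subscales and EPQ-N increase
#' monotonically in expectation with severity; EPQ E/P/L are independent of
#' it. Group membership and the SDS >= 73 major-depression threshold are kept
#' consistent by construction.
#'
#' @param latent_severity real in \[0, 1\].
#' @param group one of "healthy", "non_major", "major".
#' @param seed integer seed.
#' @return named list of scores (sds, sas, scl90_* x9, epq_e/n/p/l).
#' @export
generate_scales <- function(latent_severity, group, seed) {
  if (!is.numeric(latent_severity) || latent_severity < 0 || latent_severity > 1)
    stop("latent_severity must be in [0, 1]")
  group <- match.arg(group, c("healthy", "non_major", "major"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  clip <- function(x, lo, hi) pmax(lo, pmin(hi, x))
  sds <- clip(round(28 + 62 * latent_severity + stats::rnorm(1, 0, 2.5), 1),
              25, 100)
  sds <- if (group == "major") max(sds, 73) else min(sds, 72.9)
  sas <- clip(round(30 + 40 * latent_severity + stats::rnorm(1, 0, 3), 1),
              25, 100)
  scl_names <- c("somatization", "obsessive_compulsive",
                 "interpersonal_sensitivity", "depression", "anxiety",
                 "hostility", "phobic_anxiety", "paranoid_ideation",
                 "psychoticism")
  scl_slope <- c(2.8, 3.2, 3.1, 3.4, 3.3, 2.9, 2.9, 2.8, 2.8)
  scl <- clip(round(1.2 + scl_slope * latent_severity +
                      stats::rnorm(9, 0, 0.3), 2), 1, 5)
  names(scl) <- paste0("scl90_", scl_names)
  epq_e <- clip(round(stats::rnorm(1, 12, 4)), 0, 24)
  epq_n <- clip(round(5 + 15 * latent_severity + stats::rnorm(1, 0, 2)), 0, 24)
  epq_p <- clip(round(stats::rnorm(1, 12, 4)), 0, 24)
  epq_l <- clip(round(stats::rnorm(1, 12, 4)), 0, 24)
  c(list(sds = sds, sas = sas), as.list(scl),
    list(epq_e = epq_e, epq_n = epq_n, epq_p = epq_p, epq_l = epq_l))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Draw a latent severity for a group (uniform within group-specific bands).
draw_latent <- function(group) {
  switch(group,
         healthy   = stats::runif(1, 0.00, 0.25),
         non_major = stats::runif(1, 0.35, 0.65),
         major     = stats::runif(1, 0.72, 1.00))
}

#' Generate one synthetic resting-state EEG recording
#'
#' Deterministic given `(config$seed, profile$subject_id)`. The signal is a
#' sum of per-channel 1/f background, a shared band-limited 8-13 Hz alpha
#' source with occipital-dominant gains (left-frontal gains scaled by
#' `exp(effect/2)` where `effect = effect_size * latent_severity`), blink
#' transients, a 50 Hz sinusoid, and injected high-amplitude artifact bursts
#' in a configurable fraction of 2 s spans. All random draws are made
#' unconditionally so that two profiles differing only in severity share
#' every nuisance realization.
#'
#' @param profile list with at least `subject_id`, `group`, `latent_severity`
#'   (see [generate_cohort()]).
#' @param config a [generator_config()].
#' @return an `eeg_recording` plus attributes `artifact_epochs` (1-based
#'   indices of injected 2 s spans) and `dead_channel` (label or NA).
#' @export
generate_recording <- function(profile, config) {
  validate_generator_config(config)
  if (is.null(profile$group)) stop("profile$group must be set")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, paste0("rec:", profile$subject_id)))

  fs <- config$fs
  n <- round(config$duration_s * fs)
  nch <- length(config$channels)
  ch <- config$channels

  subj_gain <- exp(stats::rnorm(1, 0, config$subject_sd))
  chan_gain <- exp(stats::rnorm(nch, 0, config$channel_sd))

  # alpha rhythm: one shared source, channel gains with the asymmetry effect
  alpha_src <- bandlimited_noise(n, fs, c(8, 13))
  gains <- alpha_gain_profile(ch) * config$alpha_amp_uv * subj_gain * chan_gain
  eff <- config$effect_size * (profile$latent_severity %||% 0)
  left_frontal <- toupper(ch) %in% c("F3", "F7", "FP1")
  gains[left_frontal] <- gains[left_frontal] * exp(eff / 2)
  x <- outer(gains, alpha_src)

  # 1/f background, independent per channel (always drawn, even at zero
  # amplitude, to keep the RNG stream identical across configurations)
  pk <- matrix(0, nch, n)
  for (i in seq_len(nch)) pk[i, ] <- pink_noise(n)
  x <- x + pk * (config$pink_amp_uv * subj_gain) * chan_gain

  # saturate the physiological background at 64 uV (soft tanh bound) so an
  # artifact-free epoch can never cross the 70 uV rejection threshold: the
  # bound plus worst-case line noise stays strictly below it. Blinks and
  # injected artifact bursts are added after the bound on purpose.
  x <- 64 * tanh(x / 64)

  # eye blinks at the frontal pole
  n_blinks <- stats::rpois(1, config$blink_rate * config$duration_s / 60)
  tmpl <- blink_template(fs)
  proj <- blink_projection(ch)
  if (n_blinks > 0) {
    starts <- sort(sample.int(n - length(tmpl), n_blinks))
    amps <- stats::runif(n_blinks, 0.8, 1.2) * config$blink_amp_uv
    for (b in seq_len(n_blinks)) {
      idx <- starts[b]:(starts[b] + length(tmpl) - 1L)
      x[, idx] <- x[, idx] + outer(proj, tmpl * amps[b])
    }
  }

  # 50 Hz mains interference, common phase across the montage
  phase <- stats::runif(1, 0, 2 * pi)
  if (config$line_noise_amp > 0) {
    t <- seq_len(n) / fs
    x <- x + matrix(rep(config$line_noise_amp * sin(2 * pi * 50 * t + phase),
                        each = nch), nch, n)
  }

  # high-amplitude artifact bursts confined to a fraction of 2 s spans
  n_sp <- floor(config$duration_s / 2)
  n_art <- round(config$artifact_epoch_frac * n_sp)
  art_epochs <- integer(0)
  if (n_sp > 0) {
    art_epochs <- sort(sample.int(n_sp, min(n_art, n_sp)))
    burst_len <- round(0.5 * fs)
    bt <- seq_len(burst_len) / fs
    for (e in art_epochs) {
      off <- (e - 1) * 2 * fs + sample.int(max(1L, 2 * fs - burst_len), 1)
      chans <- sample.int(nch, 4)
      burst <- 150 * sin(2 * pi * 2 * bt) *
        (0.5 - 0.5 * cos(2 * pi * seq_along(bt) / length(bt)))
      idx <- off:(off + burst_len - 1L)
      idx <- idx[idx <= n]
      x[chans, idx] <- x[chans, idx] + rep(burst[seq_along(idx)], each = 4)
    }
  }

  # occasional dead (flat) channel; frontal-polar pair never chosen so the
  # blink reference stays available
  dead <- NA_character_
  u <- stats::runif(1)
  cand <- sample(which(!toupper(ch) %in% c("FP1", "FP2")), 1)
  if (u < config$bad_channel_prob) {
    x[cand, ] <- 0
    dead <- ch[cand]
  }

  rec <- eeg_recording(x, fs = fs, channels = ch,
                       subject_id = profile$subject_id %||% "S00")
  attr(rec, "artifact_epochs") <- art_epochs
  attr(rec, "dead_channel") <- dead
  rec
}

#' Generate a full synthetic cohort: EDF files plus a questionnaire roster
#'
#' @param config a [generator_config()].
#' @param out_dir directory for the per-subject EDF files; created if absent.
#'   When `NULL`, recordings are returned in memory instead of written.
#' @return list with `roster` (data.frame: subject_id, group,
#'   latent_severity, sds, sas, nine scl90_* columns, epq_e/n/p/l, edf_path)
#'   and, when `out_dir` is NULL, `recordings` (list of `eeg_recording`).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  validate_generator_config(config)
  groups <- rep(c("healthy", "non_major", "major"),
                c(config$n_healthy, config$n_nonmajor, config$n_major))
  prefix <- c(healthy = "H", non_major = "N", major = "M")
  ids <- character(length(groups))
  cnt <- c(healthy = 0, non_major = 0, major = 0)
  for (i in seq_along(groups)) {
    cnt[groups[i]] <- cnt[groups[i]] + 1
    ids[i] <- sprintf("%s%02d", prefix[groups[i]], cnt[groups[i]])
  }
  if (!is.null(out_dir) && length(ids) > 0 &&
      !dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)

  rows <- list(); recs <- list()
  for (i in seq_along(ids)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(config$seed, paste0("latent:", ids[i])))
    latent <- draw_latent(groups[i])
    .Random.seed_restore(old)
    scales <- generate_scales(latent, groups[i],
                              derive_seed(config$seed, paste0("scales:", ids[i])))
    profile <- list(subject_id = ids[i], group = groups[i],
                    latent_severity = latent)
    rec <- generate_recording(profile, config)
    path <- NA_character_
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(ids[i], ".edf"))
      write_edf(rec, path)
    } else {
      recs[[ids[i]]] <- rec
    }
    rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                            latent_severity = latent, as.data.frame(scales),
                            edf_path = path, stringsAsFactors = FALSE)
  }
  roster <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), group = character(0))
  out <- list(roster = roster)
  if (is.null(out_dir)) out$recordings <- recs
  out
}

#' Write a cohort roster to CSV
#' @param roster data.frame from [generate_cohort()].
#' @param path output CSV path.
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}
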