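# Shared fixtures: small, fast, fully seeded synthetic inputs.

# A quiet generator config: no blinks, line noise, artifacts or dead
# channels, suitable for tests that need a clean signal path.
quiet_config <- function(duration_s = 30, fs = 250, seed = 11, ...) {
  args <- utils::modifyList(
    list(n_healthy = 1, n_nonmajor = 0, n_major = 0,
         duration_s = duration_s, fs = fs,
         blink_rate = 0, line_noise_amp = 0,
         artifact_epoch_frac = 0, bad_channel_prob = 0, seed = seed),
    list(...))
  do.call(generator_config, args)
}

quiet_recording <- function(subject_id = "H01", group = "healthy",
                            latent = 0, cfg = quiet_config(), ...) {
  generate_recording(list(subject_id = subject_id, group = group,
                          latent_severity = latent), cfg)
}

# A pure multi-channel sinusoid recording for filter tests.
sine_recording <- function(freq, amp = 10, duration_s = 40, fs = 250) {
  t <- seq(1 / fs, duration_s, by = 1 / fs)
  eeg_recording(matrix(rep(amp * sin(2 * pi * freq * t), 19),
                       nrow = 19, byrow = TRUE),
                fs = fs, channels = MONTAGE_1020, subject_id = "SINE")
}

# RMS of the steady-state mid-section (avoids filter edge transients).
mid_rms <- function(x, trim = 0.2) {
  n <- length(x)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  sqrt(mean(x[i]^2))
}

# Tiny toy image classes for CNN tests: dark vs bright noise patches.
toy_images <- function(n_per_class = 20, size = 100, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mk <- function(mu) matrix(pmin(pmax(round(stats::rnorm(size^2, mu, 20)), 0), 255),
                            size, size)
  list(images = c(replicate(n_per_class, mk(90), simplify = FALSE),
                  replicate(n_per_class, mk(165), simplify = FALSE)),
       labels = rep(c(0, 1), each = n_per_class))
}

# Manifest scaffold: one row per image for given per-group subject counts.
synthetic_manifest <- function(n_per_group = c(healthy = 30, non_major = 16,
                                               major = 16),
                               images_per_subject = 60) {
  groups <- rep(names(n_per_group), n_per_group)
  prefix <- c(healthy = "H", non_major = "N", major = "M")
  ids <- paste0(prefix[groups], stats::ave(seq_along(groups), groups,
                                           FUN = seq_along))
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(subject_id = ids[i], group = groups[i],
               window_index = seq_len(images_per_subject) - 1L)
  }))
}
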