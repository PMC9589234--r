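test_that("the bandpass passes 10 Hz and the notch suppresses 50 Hz", {
  pass <- bandpass_notch_filter(sine_recording(10))
  stop <- bandpass_notch_filter(sine_recording(50))
  in_rms <- mid_rms(sine_recording(10)$data[1, ])
  gain_10 <- mid_rms(pass$data[1, ]) / in_rms
  gain_50 <- mid_rms(stop$data[1, ]) / in_rms
  expect_gt(gain_10, 0.95)                    # <= 5% passband loss
  expect_lt(20 * log10(gain_50), -20)         # >= 20 dB mains suppression
})

test_that("the high-pass edge removes slow drift and DC", {
  rec <- sine_recording(0.05, amp = 50)
  drift <- bandpass_notch_filter(rec)
  expect_lt(mid_rms(drift$data[1, ]) / mid_rms(rec$data[1, ]), 0.1)
  dc <- eeg_recording(matrix(25, 19, 250 * 20), fs = 250,
                      channels = MONTAGE_1020)
  expect_lt(max(abs(bandpass_notch_filter(dc)$data[, 2500:2600])), 1)
})

test_that("filtering is zero-phase and length-preserving", {
  rec <- sine_recording(10)
  out <- bandpass_notch_filter(rec)
  expect_equal(dim(out$data), dim(rec$data))
  # zero phase: mid-section cross-correlation peaks at zero lag
  a <- rec$data[1, 3000:7000]; b <- out$data[1, 3000:7000]
  cc <- stats::ccf(a, b, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
})

test_that("epoch segmentation counts are exact and remainders are dropped", {
  zeros <- function(sec, fs = 100) eeg_recording(matrix(0, 19, sec * fs),
                                                 fs = fs,
                                                 channels = MONTAGE_1020)
  expect_length(make_epochs(zeros(600))$epochs, 300)
  expect_length(make_epochs(zeros(601))$epochs, 300)
  expect_length(make_epochs(zeros(599))$epochs, 299)
  ep <- make_epochs(zeros(10))
  expect_true(all(vapply(ep$epochs, ncol, 0L) == 200))
  expect_true(all(ep$keep_flags))
  expect_warning(make_epochs(zeros(1)), "zero epochs")
})

test_that("flat and outlier channels are detected, healthy montages are not", {
  rec <- quiet_recording(cfg = quiet_config(duration_s = 20, seed = 13))
  expect_length(detect_bad_channels(rec), 0)
  flat <- rec; flat$data["T5", ] <- 0
  expect_identical(detect_bad_channels(flat), "T5")
  noisy <- rec; noisy$data["P3", ] <- noisy$data["P3", ] * 2000
  expect_identical(detect_bad_channels(noisy), "P3")
})

test_that("spherical-spline interpolation rebuilds spatially smooth fields", {
  n <- 500
  pos <- electrode_positions(MONTAGE_1020)
  # constant potential field: reconstruction must be essentially exact
  const <- eeg_recording(matrix(7, 19, n), fs = 250, channels = MONTAGE_1020)
  fixed <- interpolate_channels(const, "Cz")
  expect_lt(max(abs(fixed$data["Cz", ] - 7)), 1e-3)
  # smooth gradient field (linear in the x coordinate times a waveform)
  w <- sin(2 * pi * 5 * seq_len(n) / 250)
  grad <- eeg_recording(outer(10 * (1 + pos[, 1]), w), fs = 250,
                        channels = MONTAGE_1020)
  bad <- "C3"
  fixed <- interpolate_channels(grad, bad)
  err <- fixed$data[bad, ] - grad$data[bad, ]
  expect_lt(sqrt(mean(err^2)), 0.2 * sqrt(mean(grad$data[bad, ]^2)))
  # good channels are untouched
  good <- setdiff(MONTAGE_1020, bad)
  expect_identical(fixed$data[good, ], grad$data[good, ])
  expect_error(interpolate_channels(grad, "XX"), "unknown")
})

test_that("ICA removes blinks and leaves blink-free recordings intact", {
  cfg_b <- quiet_config(duration_s = 60, seed = 19, blink_rate = 12)
  blinky <- quiet_recording(cfg = cfg_b)
  blinky <- bandpass_notch_filter(blinky)
  res <- remove_blinks_ica(blinky, seed = 5)
  expect_gte(res$n_removed, 1L)
  expect_lt(max(abs(res$recording$data["FP1", ])),
            0.5 * max(abs(blinky$data["FP1", ])))
  # occipital channels barely change (blink projection is tiny there)
  expect_gt(stats::cor(res$recording$data["O1", ], blinky$data["O1", ]), 0.98)

  clean <- bandpass_notch_filter(
    quiet_recording(cfg = quiet_config(duration_s = 60, seed = 23)))
  res0 <- remove_blinks_ica(clean, seed = 5)
  expect_identical(res0$n_removed, 0L)
  expect_identical(res0$recording$data, clean$data)
})

test_that("amplitude rejection uses a strict threshold and conserves epochs", {
  base <- matrix(0, 19, 200 * 6)
  base[3, 150] <- 70          # epoch 1, exactly at threshold: kept
  base[5, 450] <- 71          # epoch 3 (samples 401-600), above: rejected
  base[9, 1000] <- -80        # epoch 5, negative excursion: rejected
  rec <- eeg_recording(base, fs = 100, channels = MONTAGE_1020)
  ep <- reject_amplitude(make_epochs(rec))
  expect_identical(ep$keep_flags, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(length(ep$keep_flags) - sum(!ep$keep_flags), sum(ep$keep_flags))
  # idempotent
  expect_identical(reject_amplitude(ep)$keep_flags, ep$keep_flags)
  # monotone: a lower threshold rejects a superset
  stricter <- reject_amplitude(make_epochs(rec), threshold_uv = 60)
  expect_true(all(!stricter$keep_flags | ep$keep_flags))
})

test_that("screening applies the strict >50% effective-segment rule", {
  mk <- function(n_eff, n_tot) {
    ep <- make_epochs(eeg_recording(matrix(0, 19, 200 * n_tot), fs = 100,
                                    channels = MONTAGE_1020))
    ep$keep_flags <- rep(c(TRUE, FALSE), c(n_eff, n_tot - n_eff))
    screen_recording(ep)
  }
  expect_false(mk(150, 300)$included)   # exactly half: excluded
  expect_true(mk(151, 300)$included)
  expect_equal(mk(151, 300)$n_epochs_effective, 151)
  expect_equal(mk(151, 300)$n_epochs_total, 300)
})

test_that("export concatenates exactly the kept epochs", {
  cfg <- quiet_config(duration_s = 60, seed = 29)
  rec <- bandpass_notch_filter(quiet_recording(cfg = cfg))
  ep <- reject_amplitude(make_epochs(rec))
  # drop a few epochs manually to make the arithmetic non-trivial
  ep$keep_flags[c(2, 7, 11)] <- FALSE
  rep_ <- screen_recording(ep)
  out <- export_effective(ep, rep_)
  expect_equal(ncol(out$data), sum(ep$keep_flags) * 2 * rec$fs)
  bad <- ep; bad$keep_flags[] <- FALSE
  expect_error(export_effective(bad, screen_recording(bad)), "refusing")
})

test_that("the full chain screens artifact recordings consistently", {
  cfg <- generator_config(n_healthy = 1, n_nonmajor = 0, n_major = 0,
                          duration_s = 60, fs = 250,
                          artifact_epoch_frac = 0.2, bad_channel_prob = 0,
                          seed = 37)
  rec <- generate_recording(list(subject_id = "H01", group = "healthy",
                                 latent_severity = 0.1), cfg)
  res <- preprocess_recording(rec, seed = 3)
  rep_ <- res$report
  expect_equal(rep_$n_epochs_total, 30)
  # every injected artifact span is rejected; nothing else is
  expect_equal(rep_$n_epochs_effective, 30 - length(attr(rec, "artifact_epochs")))
  expect_true(rep_$included)
  expect_equal(ncol(res$clean$data), rep_$n_epochs_effective * 2 * 250)
})

test_that("a mostly-dead montage is excluded instead of repaired", {
  rec <- quiet_recording(cfg = quiet_config(duration_s = 20, seed = 43))
  rec$data[1:11, ] <- 0
  expect_warning(res <- preprocess_recording(rec, seed = 3), "excluded")
  expect_false(res$report$included)
  expect_null(res$clean)
})
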