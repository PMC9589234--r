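test_that("generator configuration is validated", {
  expect_error(generator_config(artifact_epoch_frac = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(bad_channel_prob = -0.1), "\\[0, 1\\]")
  expect_error(generator_config(duration_s = -5))
  expect_error(generator_config(channels = LETTERS[1:5]), "19")
  expect_error(generator_config(effect_size = -1))
  expect_silent(generator_config(effect_size = 0))
})

test_that("a recording has the configured shape and is finite", {
  cfg <- quiet_config(duration_s = 30, fs = 250)
  rec <- quiet_recording(cfg = cfg)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$data), c(19, 30 * 250))
  expect_identical(rec$channels, MONTAGE_1020)
  expect_true(all(is.finite(rec$data)))
  expect_equal(duration_s(rec), 30)
})

test_that("generation is a pure function of (config, subject)", {
  cfg <- generator_config(duration_s = 20, fs = 250, seed = 9)
  prof <- list(subject_id = "M01", group = "major", latent_severity = 0.8)
  a <- generate_recording(prof, cfg)
  b <- generate_recording(prof, cfg)
  expect_identical(a$data, b$data)
  # a different subject id gives a different realization
  prof2 <- prof; prof2$subject_id <- "M02"
  expect_false(identical(generate_recording(prof2, cfg)$data, a$data))
})

test_that("the severity effect touches only the left-frontal alpha gains", {
  cfg0 <- quiet_config(duration_s = 20, seed = 21, effect_size = 0)
  cfg2 <- quiet_config(duration_s = 20, seed = 21, effect_size = 2)
  prof <- list(subject_id = "M01", group = "major", latent_severity = 1)
  r0 <- generate_recording(prof, cfg0)
  r2 <- generate_recording(prof, cfg2)
  lf <- toupper(MONTAGE_1020) %in% c("F3", "F7", "FP1")
  # nuisance realizations are shared: non-left-frontal channels identical
  expect_identical(r0$data[!lf, ], r2$data[!lf, ])
  expect_false(identical(r0$data[lf, ], r2$data[lf, ]))
})

test_that("artifact-free recordings stay within the rejection threshold", {
  rec <- quiet_recording(cfg = quiet_config(duration_s = 60, seed = 31,
                                            line_noise_amp = 5))
  expect_lt(max(abs(rec$data)), 70)
})

test_that("the F3/F4 alpha log-power ratio shifts by the configured effect", {
  # noise-free recordings so the band-power oracle sees the alpha rhythm
  # alone (any in-band noise floor dilutes the log ratio toward zero)
  mk <- function(es) {
    cfg <- quiet_config(duration_s = 60, seed = 41, effect_size = es,
                        pink_amp_uv = 0)
    generate_recording(list(subject_id = "S01", group = "major",
                            latent_severity = 1), cfg)
  }
  ratio <- function(rec) {
    log(band_power(rec$data["F3", ], rec$fs) /
          band_power(rec$data["F4", ], rec$fs))
  }
  shift <- ratio(mk(1)) - ratio(mk(0))
  expect_equal(shift, 1, tolerance = 0.1)
})

test_that("questionnaire scales respect their ranges and the SDS threshold", {
  for (i in 1:50) {
    grp <- c("healthy", "non_major", "major")[i %% 3 + 1]
    lat <- switch(grp, healthy = 0.1, non_major = 0.5, major = 0.85)
    sc <- generate_scales(lat, grp, seed = i)
    expect_gte(sc$sds, 25); expect_lte(sc$sds, 100)
    if (grp == "major") expect_gte(sc$sds, 73) else expect_lte(sc$sds, 72.9)
    expect_gte(sc$sas, 25); expect_lte(sc$sas, 100)
    scl <- unlist(sc[grep("^scl90_", names(sc))])
    expect_length(scl, 9)
    expect_true(all(scl >= 1 & scl <= 5))
    epq <- unlist(sc[c("epq_e", "epq_n", "epq_p", "epq_l")])
    expect_true(all(epq >= 0 & epq <= 24))
  }
  expect_error(generate_scales(1.2, "major", 1), "\\[0, 1\\]")
})

test_that("SDS increases monotonically with the latent severity", {
  lat <- seq(0, 1, length.out = 200)
  sds <- vapply(seq_along(lat), function(i) {
    generate_scales(lat[i], if (lat[i] > 0.7) "major" else "non_major",
                    seed = 1000 + i)$sds
  }, 0)
  expect_gt(cor(lat, sds, method = "spearman"), 0.8)
})

test_that("cohort roster has consistent ids, groups and scale columns", {
  cfg <- generator_config(n_healthy = 2, n_nonmajor = 1, n_major = 1,
                          duration_s = 5, fs = 250, seed = 17)
  coh <- generate_cohort(cfg, out_dir = NULL)
  expect_identical(coh$roster$subject_id, c("H01", "H02", "N01", "M01"))
  expect_identical(coh$roster$group,
                   c("healthy", "healthy", "non_major", "major"))
  expect_true(all(c("sds", "sas", "epq_n", "scl90_depression") %in%
                    names(coh$roster)))
  expect_identical(names(coh$recordings), coh$roster$subject_id)
  # latent severities sit in their group bands
  with(coh$roster, {
    expect_true(all(latent_severity[group == "healthy"] <= 0.25))
    expect_true(all(latent_severity[group == "non_major"] >= 0.35 &
                      latent_severity[group == "non_major"] <= 0.65))
    expect_true(all(latent_severity[group == "major"] >= 0.72))
  })
})

test_that("alpha asymmetry separates groups at cohort scale", {
  # 8 healthy vs 8 major subjects, strong effect: the F3/F4 alpha
  # log-ratio oracle must separate the groups decisively
  cfg <- quiet_config(duration_s = 30, seed = 71, effect_size = 2)
  ratio <- function(id, grp, lat) {
    rec <- generate_recording(list(subject_id = id, group = grp,
                                   latent_severity = lat), cfg)
    log(band_power(rec$data["F3", ], rec$fs) /
          band_power(rec$data["F4", ], rec$fs))
  }
  healthy <- vapply(1:8, function(i) ratio(sprintf("H%02d", i), "healthy", 0.1), 0)
  major <- vapply(1:8, function(i) ratio(sprintf("M%02d", i), "major", 0.9), 0)
  expect_lt(stats::t.test(healthy, major)$p.value, 0.01)
})

test_that("a dead channel is flat and never the frontal pole", {
  cfg <- generator_config(n_healthy = 1, n_nonmajor = 0, n_major = 0,
                          duration_s = 10, fs = 250, bad_channel_prob = 1,
                          seed = 53)
  rec <- generate_recording(list(subject_id = "H01", group = "healthy",
                                 latent_severity = 0.1), cfg)
  dead <- attr(rec, "dead_channel")
  expect_false(is.na(dead))
  expect_false(toupper(dead) %in% c("FP1", "FP2"))
  expect_equal(stats::var(rec$data[dead, ]), 0)
})
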