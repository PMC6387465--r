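test_that("cohort structure matches the protocol: blocks, labels, IAF ground truth", {
  cfg <- sim_config(n_subjects = 12, block_length = 2, n_repetitions = 4,
                    channels = c("Oz", "Neck4"), seed = 5)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 12)
  for (rec in cohort) {
    expect_equal(nrow(rec$blocks), 8)
    expect_equal(sum(rec$blocks$condition == "OC"), 4)
    expect_equal(sum(rec$blocks$condition == "OA"), 4)
    expect_equal(sort(rec$blocks$repetition[rec$blocks$condition == "OC"]),
                 1:4)
  }
  iafs <- attr(cohort, "true_iaf")
  expect_length(iafs, 12)
  expect_true(all(iafs >= 8 & iafs <= 12))
  expect_true(all(abs(iafs * 4 - round(iafs * 4)) < 1e-9))  # 0.25 Hz grid
  # block order varies across subjects under the same master seed
  orders <- vapply(cohort, function(r) paste(r$blocks$condition,
                                             collapse = ""), character(1))
  expect_gt(length(unique(orders)), 1)
  # single-subject degenerate case
  expect_length(generate_cohort(sim_config(n_subjects = 1, block_length = 2,
                                           channels = "Oz", seed = 1)), 1)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- tiny_cfg(seed = 99)
  r1 <- generate_subject(cfg, 2)
  r2 <- generate_subject(cfg, 2)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$blocks, r2$blocks)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(attr(c1, "true_iaf"), attr(c2, "true_iaf"))
  expect_identical(c1[[1]]$samples, c2[[1]]$samples)
  # and differs under a different seed
  expect_false(identical(generate_subject(tiny_cfg(seed = 100), 2)$samples,
                         r1$samples))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(alpha_amp_oc = -1), "amplitudes")
  expect_error(sim_config(coupling = c(Neck2 = 1.5)), "coupling")
  expect_error(sim_config(artifact_rates = list(blinks_per_min = -2)),
               "rates")
  expect_error(sim_config(sampling_rate = 20), "Nyquist|twice",
               ignore.case = TRUE)
  expect_error(generate_subject(tiny_cfg(), 99), "subject_index")
})

test_that("alpha power is higher in OC than OA at posterior and coupled channels", {
  cfg <- tiny_cfg(seed = 7)
  rec <- generate_subject(cfg, 1)
  es <- preprocess_recording(rec)
  ps <- epoch_psd(es, channels = c("Oz", "Neck4"), fmax = 30)
  oc <- condition_mean(ps, "OC", n_expected = 2)
  oa <- condition_mean(ps, "OA", n_expected = 2)
  alpha <- oc$frequencies >= 9 & oc$frequencies <= 13
  for (ch in c("Oz", "Neck4")) {
    expect_gt(mean(channel_spectrum(oc, ch)[alpha]),
              mean(channel_spectrum(oa, ch)[alpha]))
  }
})

test_that("uncoupled noEEG channels show no systematic alpha-profile correlation", {
  cfg <- sim_config(n_subjects = 8, block_length = 20, n_repetitions = 2,
                    subject_iaf = c(8, 12),
                    channels = c("Oz", "POz", "Neck4", "Neck7", "WrR3"),
                    seed = 31)
  cohort <- generate_cohort(cfg)
  res <- lapply(cohort, function(rec) {
    oc <- condition_mean(epoch_psd(preprocess_recording(rec), fmax = 15),
                         "OC", n_expected = 2)
    couple_correlations(oc, eeg_channels = c("Oz", "POz"),
                        noeeg_channels = c("Neck7", "WrR3"))
  })
  all_r <- unlist(lapply(res, function(d) d$R))
  all_p <- unlist(lapply(res, function(d) d$p))
  expect_lt(abs(mean(all_r)), 0.35)          # centred near zero
  expect_lt(mean(all_p < 0.05), 0.35)        # no systematic significance
  # by contrast the coupled channel correlates strongly in every subject
  coupled <- vapply(cohort, function(rec) {
    oc <- condition_mean(epoch_psd(preprocess_recording(rec),
                                   channels = c("Oz", "Neck4"), fmax = 15),
                         "OC", n_expected = 2)
    alpha_profile_correlation(oc, "Oz", "Neck4")$R
  }, numeric(1))
  expect_true(all(coupled > 0.9))
})

test_that("a zero-contrast configuration yields chance-level discrimination", {
  cfg <- sim_config(n_subjects = 1, block_length = 30, n_repetitions = 2,
                    subject_iaf = 10, alpha_amp_oc = 4, alpha_amp_oa = 4,
                    theta_amp_oc = 2, theta_amp_oa = 2,
                    background = list(oa_ratio = 1),
                    channels = c("O1", "Oz", "P3"), seed = 11)
  es <- preprocess_recording(generate_subject(cfg, 1))
  es$meta <- es$meta[seq(1, nrow(es$meta), by = 5), ]  # decorrelate epochs
  ps <- epoch_psd(es, fmax = 20)
  cv <- run_band_cv(ps, 8, 12, c("O1", "Oz", "P3"))
  expect_lt(abs(mean(cv$auc) - 0.5), 0.15)
})

test_that("artifact injection is seeded, honest about ground truth, and inert at zero rates", {
  cfg <- tiny_cfg(seed = 17)
  rec <- generate_subject(cfg, 1)
  same <- inject_artifacts(rec, cfg)  # default rates are all zero
  expect_identical(same$samples, rec$samples)
  expect_equal(nrow(attr(same, "artifact_events")), 0)

  cfg2 <- tiny_cfg(seed = 17,
                   artifact_rates = list(blinks_per_min = 3, blink_amp = 150))
  dirty <- inject_artifacts(rec, cfg2)
  ev <- attr(dirty, "artifact_events")
  expect_gt(nrow(ev), 0)
  expect_identical(inject_artifacts(rec, cfg2)$samples, dirty$samples)

  # a 150 uV blink must still trip the +/-100 uV rule after filtering
  es <- segment_epochs(bandpass(dirty), 4, 0.1)
  es <- flag_amplitude(es)
  for (i in seq_len(nrow(ev))) {
    overlap <- es$meta$start_time < ev$onset[i] + ev$duration[i] &
      es$meta$start_time + 4 > ev$onset[i]
    if (any(overlap)) expect_true(any(es$meta$flagged[overlap]))
  }
})

test_that("flags from a single localized burst stay confined to its epochs", {
  cfg <- sim_config(n_subjects = 1, block_length = 20, n_repetitions = 1,
                    subject_iaf = 10, channels = c("Oz", "Neck1"),
                    artifact_rates = list(emg_per_min = 2, emg_amp = 500),
                    seed = 23)
  rec <- inject_artifacts(generate_subject(cfg, 1), cfg)
  ev <- attr(rec, "artifact_events")
  expect_gt(nrow(ev), 0)
  es <- flag_amplitude(segment_epochs(bandpass(rec), 4, 0.1))
  flagged_t <- es$meta$start_time[es$meta$flagged]
  # every flagged epoch overlaps some ground-truth event window
  # (padded by the filter's transient spread)
  ok <- vapply(flagged_t, function(t0) any(
    t0 < ev$onset + ev$duration + 0.2 & t0 + 4 > ev$onset - 0.2),
    logical(1))
  expect_true(all(ok))
  expect_gt(sum(es$meta$flagged), 0)
})

test_that("YAML configuration round-trips through read_sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 3", "block_length: 10", "seed: 42",
               "subject_iaf: 10.5",
               "coupling:", "  Neck4: 0.5",
               "background:", "  scale: 2.0"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_subjects, 3)
  expect_equal(cfg$subject_iaf, 10.5)
  expect_equal(cfg$coupling, c(Neck4 = 0.5))
  expect_equal(cfg$background$scale, 2.0)
  expect_equal(cfg$background$oa_ratio, 1.35)  # defaults preserved
  writeLines("n_subjects: 3", path)
  expect_error(read_sim_config(path), "seed")
})
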