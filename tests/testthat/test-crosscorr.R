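make_two_channel <- function(x, y, freqs = seq(0, 30, by = 0.25)) {
  m <- rbind(Oz = x, Neck4 = y)
  mean_spectrum_set(m, freqs)
}

test_that("alpha-profile correlation matches the closed-form Pearson/t transform", {
  freqs <- seq(0, 30, by = 0.25)
  set.seed(14)
  x <- 1 + stats::runif(length(freqs))
  y <- 0.5 * x + stats::rnorm(length(freqs), 0, 0.1)
  ss <- make_two_channel(x, y, freqs)
  r <- alpha_range(7.5, 12.5)
  out <- alpha_profile_correlation(ss, "Oz", "Neck4", r)
  bins <- freqs >= 7.5 & freqs <= 12.5
  n <- sum(bins)
  expect_equal(out$n_points, 21)
  # closed-form Pearson and exact t transform, computed independently
  xx <- x[bins]; yy <- y[bins]
  r_cf <- sum((xx - mean(xx)) * (yy - mean(yy))) /
    sqrt(sum((xx - mean(xx))^2) * sum((yy - mean(yy))^2))
  t_cf <- r_cf * sqrt((n - 2) / (1 - r_cf^2))
  p_cf <- 2 * stats::pt(-abs(t_cf), n - 2)
  expect_equal(out$R, r_cf, tolerance = 1e-12)
  expect_equal(out$p, p_cf, tolerance = 1e-12)
})

test_that("correlation obeys the identity, negation and affine-invariance properties", {
  freqs <- seq(0, 30, by = 0.25)
  set.seed(15)
  x <- 2 + stats::runif(length(freqs))
  expect_equal(alpha_profile_correlation(make_two_channel(x, x, freqs),
                                         "Oz", "Neck4")$R, 1)
  neg <- 2 * mean(x) - x
  expect_equal(alpha_profile_correlation(make_two_channel(x, neg, freqs),
                                         "Oz", "Neck4")$R, -1)
  # proportional profiles (1,2,3,4) vs (2,4,6,8) pattern: R = 1
  y <- 2 * x
  expect_equal(alpha_profile_correlation(make_two_channel(x, y, freqs),
                                         "Oz", "Neck4")$R, 1)
  # symmetric in channel order; invariant under positive affine rescaling
  ss <- make_two_channel(x, 3 + 0.5 * sin(freqs) + x / 3, freqs)
  a <- alpha_profile_correlation(ss, "Oz", "Neck4")
  ss_sw <- make_two_channel(3 + 0.5 * sin(freqs) + x / 3, x, freqs)
  b <- alpha_profile_correlation(ss_sw, "Oz", "Neck4")
  expect_equal(a$R, b$R)
  ss_sc <- make_two_channel(x, 10 + 7 * (3 + 0.5 * sin(freqs) + x / 3), freqs)
  expect_equal(alpha_profile_correlation(ss_sc, "Oz", "Neck4")$R, a$R)
  # zero variance is an error
  flat <- make_two_channel(x, rep(1, length(freqs)), freqs)
  expect_error(alpha_profile_correlation(flat, "Oz", "Neck4"),
               "zero variance")
})

fake_corr <- function(R, p) data.frame(
  eeg_channel = c("Oz", "Pz"), noeeg_channel = c("Neck4", "Neck4"),
  R = R, p = p, n_points = 21)

test_that("common pattern requires positivity and significance in every subject", {
  good <- fake_corr(c(0.9, 0.8), c(0.001, 0.002))
  one_bad <- fake_corr(c(0.9, -0.1), c(0.001, 0.002))
  pat <- common_pattern(list(good, good, good))
  expect_equal(nrow(pat), 2)
  pat2 <- common_pattern(list(good, good, one_bad))
  expect_equal(pat2$eeg_channel, "Oz")
  # non-significant in one subject also excludes
  pat3 <- common_pattern(list(good, fake_corr(c(0.9, 0.8), c(0.2, 0.001))))
  expect_equal(pat3$eeg_channel, "Pz")
  # mismatched couple sets are an error
  other <- data.frame(eeg_channel = "Cz", noeeg_channel = "Neck1",
                      R = 1, p = 0, n_points = 21)
  expect_error(common_pattern(list(good, other)), "different couple sets")
  # empty couple list propagates to an empty pattern
  empty <- good[0, ]
  expect_equal(nrow(common_pattern(list(empty, empty))), 0)
})

test_that("IAF difference map categorizes means per the 0.25 Hz convention", {
  pattern <- data.frame(eeg_channel = c("Oz", "Pz", "Cz", "Fz"),
                        noeeg_channel = c("Neck4", "Neck2", "Neck5", "Neck6"))
  iafs <- rbind(
    data.frame(subject = 1, channel = c("Oz", "Pz", "Cz", "Fz", "Neck4",
                                        "Neck2", "Neck5", "Neck6"),
               iaf = c(11, 11.25, 10, 10.3, 11, 11.05, 10.25, 10),
               method = "peak"),
    data.frame(subject = 2, channel = c("Oz", "Pz", "Cz", "Fz", "Neck4",
                                        "Neck2", "Neck5", "Neck6"),
               iaf = c(10, 10.25, 10, 10.3, 10, 10.05, 10.25, 10),
               method = "peak"))
  map <- iaf_difference_map(pattern, iafs)
  expect_equal(map$category,
               c("equal", "eeg_higher", "eeg_lower", "out_of_range"))
  expect_equal(map$mean_d, c(0, 0.2, -0.25, 0.3))
  expect_equal(map$d_s1, c(0, 0.2, -0.25, 0.3))
  # missing IAF errors
  expect_error(iaf_difference_map(pattern, iafs[iafs$channel != "Neck4", ]),
               "missing IAF")
})

test_that("coupled channel pairs are detected and uncoupled pairs excluded on synthetic data", {
  cfg <- sim_config(n_subjects = 4, block_length = 20, n_repetitions = 2,
                    subject_iaf = c(9, 11),
                    channels = c("Oz", "POz", "Neck4", "Neck7"), seed = 77)
  cohort <- generate_cohort(cfg)
  per_subject <- lapply(cohort, function(rec) {
    oc <- condition_mean(epoch_psd(preprocess_recording(rec), fmax = 15),
                         "OC", n_expected = 2)
    couple_correlations(oc)
  })
  pat <- common_pattern(per_subject)
  keys <- paste(pat$eeg_channel, pat$noeeg_channel)
  expect_true("Oz Neck4" %in% keys)
  expect_false("Oz Neck7" %in% keys)
  # zero-difference couples share the same alpha source by construction
  oc_means <- lapply(cohort, function(rec)
    condition_mean(epoch_psd(preprocess_recording(rec), fmax = 15),
                   "OC", n_expected = 2))
  map <- iaf_difference_map(pat, iaf_table(oc_means))
  eq <- map[map$category == "equal", ]
  expect_true(all(eq$noeeg_channel == "Neck4"))
  expect_gt(nrow(eq), 0)
})
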