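test_that("repetition-paired folds use each couple as calibration exactly once", {
  folds <- make_folds(1:4)
  expect_length(folds, 4)
  for (f in folds) {
    expect_length(f$test, 3)
    expect_false(f$train %in% f$test)
  }
  expect_equal(sort(vapply(folds, `[[`, numeric(1), "train")), 1:4)
  f2 <- make_folds(c(2, 1))
  expect_length(f2, 2)
  expect_length(f2[[1]]$test, 1)
  expect_error(make_folds(1), "at least 2")
})

test_that("rank AUC equals brute-force pair counting, including ties", {
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(compute_auc(1:10, rep(c(0, 1), each = 5)), 1)
  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(compute_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(compute_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    n <- 80
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- labels + stats::rnorm(n)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(compute_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and ~0.5 under the null", {
  set.seed(17)
  scores <- stats::rnorm(500)
  labels <- rep(0:1, 250)
  a <- compute_auc(scores, labels)
  expect_equal(compute_auc(exp(scores), labels), a)
  expect_equal(compute_auc(qnorm(rank(scores) / 501), labels), a)
  null_scores <- stats::rnorm(10000)
  null_labels <- rep(0:1, 5000)
  expect_lt(abs(compute_auc(null_scores, null_labels) - 0.5), 0.02)
})

test_that("accuracy at the fixed threshold behaves and is symmetric under relabeling", {
  expect_equal(compute_acc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(compute_acc(c(0.9, 0.1, 0.8, 0.2), c(1, 1, 0, 0)), 0.5)
  set.seed(19)
  scores <- stats::runif(5000)
  labels <- sample(0:1, 5000, replace = TRUE)
  expect_lt(abs(compute_acc(scores, labels) - 0.5), 0.03)
  # relabeling symmetry: swap classes and the threshold side
  s <- c(0.2, 0.6, 0.7, 0.4)
  y <- c(0, 1, 0, 1)
  expect_equal(compute_acc(s, y, 0.5), compute_acc(-s, 1 - y, -0.5 + 1e-12))
})

test_that("paired t-test matches the closed form and handles degenerate input", {
  a <- c(0.81, 0.74, 0.69, 0.77, 0.83)
  b <- c(0.78, 0.75, 0.66, 0.73, 0.80)
  out <- paired_ttest(a, b)
  d <- a - b
  t_cf <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(out$t, t_cf)
  expect_equal(out$p, 2 * stats::pt(-abs(t_cf), length(d) - 1))
  sym <- paired_ttest(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  expect_error(paired_ttest(a, a), "zero-variance")
  expect_error(paired_ttest(1, 2), "at least 2")
  expect_error(paired_ttest(a, b[1:3]), "paired")
})

test_that("band CV bookkeeping yields folds x test-couples evaluations", {
  cfg <- sim_config(n_subjects = 1, block_length = 10, n_repetitions = 4,
                    subject_iaf = 10, channels = c("O1", "Oz", "P3"),
                    seed = 3)
  es <- preprocess_recording(generate_subject(cfg, 1), step = 0.5)
  ps <- epoch_psd(es, fmax = 20)
  cv <- run_band_cv(ps, 8, 12, c("O1", "Oz", "P3"))
  expect_equal(nrow(cv), 12)  # 4 folds x 3 test couples
  expect_equal(sort(unique(cv$fold)), 1:4)
  for (f in 1:4)
    expect_equal(sort(cv$test_rep[cv$fold == f]), setdiff(1:4, f))
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  expect_true(all(cv$acc >= 0 & cv$acc <= 1))
  expect_error(suppressWarnings(run_band_cv(ps, 25, 30, "Oz")), "no bins")
})

test_that("paired t-test rejects at about the nominal rate on zero-effect data", {
  # scaled-down zero-effect calibration: feature matrices independent of
  # the labels, run through the same fold-CV + SWLDA + paired-test path
  set.seed(41)
  n_rep <- 200; n_sub <- 8
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    auc_e <- numeric(n_sub); auc_n <- numeric(n_sub)
    for (s in seq_len(n_sub)) {
      one_set <- function() {
        rep_id <- rep(1:2, each = 30)
        y <- rep(rep(0:1, each = 15), 2)
        X <- matrix(stats::rnorm(60 * 4), 60, 4,
                    dimnames = list(NULL, paste0("f", 1:4)))
        aucs <- vapply(make_folds(rep_id), function(f) {
          tr <- rep_id == f$train
          m <- fit_swlda(X[tr, , drop = FALSE], y[tr])
          compute_auc(discriminant_scores(
            m, X[!tr, , drop = FALSE]), y[!tr])
        }, numeric(1))
        mean(aucs)
      }
      auc_e[s] <- one_set(); auc_n[s] <- one_set()
    }
    reject[r] <- paired_ttest(auc_e, auc_n)$p < 0.05
  }
  expect_lt(abs(mean(reject) - 0.05), 0.045)
})

test_that("evaluation summary has the band x feature-set shape with per-band tests", {
  set.seed(51)
  grid <- expand.grid(subject = 1:6, band = c("Delta", "Theta", "Alpha",
                                              "Beta"),
                      feature_set = c("EEG", "noEEG"),
                      stringsAsFactors = FALSE)
  grid$auc <- 0.75 + stats::rnorm(nrow(grid), 0, 0.03)
  grid$acc <- 0.80 + stats::rnorm(nrow(grid), 0, 0.03)
  out <- summarize_evaluation(grid)
  expect_equal(nrow(out$table), 8)       # 2 sets x 4 bands
  expect_equal(nrow(out$tests), 4)       # one paired test per band
  expect_true(all(out$tests$p_auc >= 0 & out$tests$p_auc <= 1))
  expect_error(summarize_evaluation(grid[grid$feature_set == "EEG", ]),
               "missing result cells")
  single <- grid[grid$subject == 1, ]
  expect_warning(out1 <- summarize_evaluation(single), "single subject")
  expect_null(out1$tests)
})
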