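#' Repetition-paired cross-validation scheme
#'
#' Each `(OC_i, OA_i)` repetition couple serves as the calibration set of
#' exactly one fold; the remaining couples are test sets, evaluated
#' separately. With 4 repetitions this yields 4 folds x 3 test couples =
#' 12 evaluations.
#'
#' @param repetitions Vector of repetition indices (>= 2 distinct).
#' @return List of folds, each `list(train = i, test = <other indices>)`.
#' @export
make_folds <- function(repetitions) {
  reps <- sort(unique(repetitions))
  if (length(reps) < 2)
    stop("need at least 2 repetition couples for cross-validation")
  lapply(reps, function(r) list(train = r, test = setdiff(reps, r)))
}

#' Rank-based AUC
#'
#' The Mann-Whitney form of the area under the ROC curve: the probability
#' that a randomly chosen positive-class score exceeds a randomly chosen
#' negative-class score, with ties counted half (midranks).
#'
#' @param scores Numeric scores (higher = more positive-class).
#' @param labels Binary labels (1/TRUE = positive class).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a fixed threshold
#'
#' Fraction of epochs whose thresholded score (`score >= threshold`
#' predicts the positive class) matches the label. With 0/1-coded
#' regression output the natural threshold is 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive class).
#' @param threshold Decision threshold (default 0.5).
#' @return Accuracy in `[0, 1]`.
#' @export
compute_acc <- function(scores, labels, threshold = 0.5) {
  if (is.logical(labels)) labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(scores) != length(labels)) stop("length mismatch")
  mean((scores >= threshold) == (labels == 1))
}

#' Build a spectral feature matrix
#'
#' Columns are (channel, frequency-bin) linear-PSD features named
#' `"<channel>@<freq>"`; rows are epochs.
#'
#' @param ss A per-epoch `spectrum_set`.
#' @param channels Channel labels to include.
#' @param bins Bin frequencies (Hz), e.g. from [band_bins()].
#' @return List: `X` (matrix), `labels` (0/1, OC = 1), `meta`.
#' @export
feature_matrix <- function(ss, channels, bins) {
  stopifnot(inherits(ss, "spectrum_set"), ss$level == "per_epoch")
  if (length(bins) == 0) stop("empty frequency-bin set")
  miss <- setdiff(channels, ss$channels)
  if (length(miss)) stop("channels not in spectra: ",
                         paste(miss, collapse = ", "))
  bi <- match(round(bins * 400), round(ss$frequencies * 400))
  if (anyNA(bi)) stop("requested bins not on the spectrum grid")
  ci <- match(channels, ss$channels)
  v <- ss$values[, ci, bi, drop = FALSE]
  n_ep <- dim(v)[1]
  X <- matrix(v, n_ep, length(ci) * length(bi))
  colnames(X) <- as.vector(outer(channels, bins,
                                 function(c, b) sprintf("%s@%g", c, b)))
  list(X = X, labels = as.numeric(ss$meta$condition == "OC"),
       meta = ss$meta)
}

#' Cross-validated band classification
#'
#' For one frequency band and one feature channel set, builds the spectral
#' feature matrix, fits SWLDA on each fold's calibration repetition couple
#' and scores each test couple separately, returning AUC and accuracy per
#' (fold, test couple) evaluation.
#'
#' @param ss A per-epoch `spectrum_set` covering the feature channels.
#' @param band_f1,band_f2 Band edges in Hz.
#' @param channels Feature channel labels.
#' @param scheme Folds from [make_folds()] (default: folds over the
#'   repetitions present in `ss`).
#' @param config A [swlda_config()].
#' @param analysis_range Passed to [band_bins()].
#' @param resolution Grid resolution (Hz).
#' @return Data frame `fold`, `test_rep`, `auc`, `acc`, `n_features`,
#'   `n_train`, `n_test`.
#' @export
run_band_cv <- function(ss, band_f1, band_f2, channels, scheme = NULL,
                        config = swlda_config(),
                        analysis_range = c(1, 20), resolution = 0.25) {
  bins <- band_bins(band_f1, band_f2, resolution, analysis_range)
  if (length(bins) == 0) stop("band has no bins inside the analysis range")
  fm <- feature_matrix(ss, channels, bins)
  if (is.null(scheme)) scheme <- make_folds(ss$meta$repetition)
  rep_of <- fm$meta$repetition
  out <- list()
  for (fi in seq_along(scheme)) {
    fold <- scheme[[fi]]
    tr <- rep_of == fold$train
    model <- fit_swlda(fm$X[tr, , drop = FALSE], fm$labels[tr], config)
    for (te_rep in fold$test) {
      te <- rep_of == te_rep
      sc <- discriminant_scores(model, fm$X[te, , drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        fold = fold$train, test_rep = te_rep,
        auc = compute_auc(sc, fm$labels[te]),
        acc = compute_acc(sc, fm$labels[te]),
        n_features = length(model$features),
        n_train = sum(tr), n_test = sum(te))
    }
  }
  do.call(rbind, out)
}

#' Paired two-tailed t-test
#'
#' Standard paired t statistic on per-subject metric differences,
#' `t = mean(d) / (sd(d)/sqrt(n))`, with the two-tailed p-value.
#'
#' @param values_a,values_b Equal-length (`>= 2`) numeric vectors paired
#'   by subject.
#' @return List `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("vectors must be paired")
  if (length(values_a) < 2) stop("need at least 2 pairs")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      stop("zero-variance differences: metrics identical for all subjects")
    stop("zero-variance differences: paired t-test undefined")
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' Band x feature-set evaluation summary
#'
#' From per-subject averaged metrics, builds the band-by-feature-set table
#' of cohort-mean AUC and accuracy, plus per-band paired t-tests between
#' the EEG and noEEG feature sets. With a single subject the t-tests are
#' skipped with a warning.
#'
#' @param results Data frame with columns `subject`, `band`,
#'   `feature_set` ("EEG"/"noEEG"), `auc`, `acc` (one row per
#'   subject/band/set, already averaged over the fold evaluations).
#' @return List: `table` (band x set means), `tests` (per-band t/p for
#'   AUC and ACC differences), `per_subject` (the input).
#' @export
summarize_evaluation <- function(results) {
  need <- c("subject", "band", "feature_set", "auc", "acc")
  if (!all(need %in% names(results))) stop("missing result columns")
  grid <- expand.grid(band = unique(results$band),
                      feature_set = c("EEG", "noEEG"),
                      stringsAsFactors = FALSE)
  missing_cells <- grid[!paste(grid$band, grid$feature_set) %in%
                          paste(results$band, results$feature_set), ]
  if (nrow(missing_cells))
    stop("missing result cells: ",
         paste(missing_cells$band, missing_cells$feature_set,
               collapse = "; "))
  agg <- stats::aggregate(cbind(auc, acc) ~ band + feature_set,
                          data = results, FUN = mean)
  n_sub <- length(unique(results$subject))
  tests <- NULL
  if (n_sub >= 2) {
    for (b in unique(results$band)) {
      sub <- results[results$band == b, ]
      sub <- sub[order(sub$subject), ]
      e <- sub[sub$feature_set == "EEG", ]
      ne <- sub[sub$feature_set == "noEEG", ]
      t_auc <- paired_ttest(e$auc, ne$auc)
      t_acc <- paired_ttest(e$acc, ne$acc)
      tests <- rbind(tests, data.frame(
        band = b, p_auc = t_auc$p, t_auc = t_auc$t,
        p_acc = t_acc$p, t_acc = t_acc$t))
    }
  } else {
    warning("single subject: paired t-tests skipped")
  }
  list(table = agg, tests = tests, per_subject = results,
       n_subjects = n_sub)
}
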