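# Shared fixtures: small configurations and hand-built objects used across
# the module tests. Everything is generated in code at test time.

# Reduced montage containing a posterior/frontal spread, coupled and
# uncoupled noEEG channels; keeps filtering and FFT costs small.
tiny_channels <- function() {
  c("Fp1", "F3", "Fz", "C3", "Cz", "CP3", "CPz", "P3", "O1", "Oz", "POz",
    "Neck2", "Neck4", "Neck7", "WrL2", "WrR1")
}

tiny_cfg <- function(..., seed = 123) {
  sim_config(n_subjects = 2, block_length = 20, n_repetitions = 2,
             subject_iaf = 11, channels = tiny_channels(), seed = seed, ...)
}

# Single-channel recording with one annotated block; samples supplied or
# zeros. Convenient for epoching/flag-rule boundary tests.
block_recording <- function(duration, fs = 250, samples = NULL,
                            condition = "OC", n_channels = 1) {
  n <- round(duration * fs)
  if (is.null(samples)) samples <- matrix(0, n_channels, n)
  rownames(samples) <- paste0("C", seq_len(nrow(samples)))
  recording(samples, fs,
            blocks = data.frame(condition = condition, repetition = 1L,
                                onset = 0, duration = ncol(samples) / fs))
}

# Hand-built condition-mean spectrum_set over a given frequency grid.
mean_spectrum_set <- function(values, frequencies,
                              channels = rownames(values)) {
  structure(list(frequencies = frequencies, values = values,
                 level = "condition_mean", channels = channels,
                 provenance = list(condition = "OC"), sampling_rate = 250),
            class = "spectrum_set")
}

# Hand-built per-epoch spectrum_set (epoch x channel x frequency array).
per_epoch_spectrum_set <- function(values, frequencies, meta) {
  structure(list(frequencies = frequencies, values = values,
                 level = "per_epoch",
                 channels = dimnames(values)[[2]], meta = meta,
                 sampling_rate = 250),
            class = "spectrum_set")
}

# Brute-force stepwise oracle: the same forward-entry/backward-removal
# rules, implemented naively with lm() refits at every step. Independent
# of the package's incremental-residualization fast path.
oracle_swlda <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.1,
                         max_iterations = 50) {
  selected <- integer(0)
  for (it in seq_len(max_iterations)) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    cand <- cand[vapply(cand, function(j) stats::sd(X[, j]) > 0, logical(1))]
    if (length(cand) == 0) break
    pv <- vapply(cand, function(j) {
      d <- data.frame(y = y, X[, c(selected, j), drop = FALSE])
      fit <- stats::lm(y ~ ., data = d)
      cf <- summary(fit)$coefficients
      if (nrow(cf) < length(selected) + 2) return(NA_real_)  # rank deficient
      cf[nrow(cf), 4]
    }, numeric(1))
    if (all(is.na(pv))) break
    best <- which.min(pv)
    if (!(pv[best] < alpha_enter)) break
    selected <- c(selected, cand[best])
    repeat {
      d <- data.frame(y = y, X[, selected, drop = FALSE])
      cf <- summary(stats::lm(y ~ ., data = d))$coefficients
      p_inc <- cf[-1, 4]
      worst <- which.max(p_inc)
      if (p_inc[worst] > alpha_remove) selected <- selected[-worst]
      else break
      if (length(selected) == 0) break
    }
  }
  colnames(X)[selected]
}

# Brute-force AUC: count concordant positive-negative pairs, ties half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
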