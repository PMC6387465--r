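#' Band-pass filter specification
#'
#' An 8th-order Butterworth band-pass realized as a low-pass and a
#' high-pass cascade (each of the stated order). By default the filters
#' are applied zero-phase (forwardbackward, so the effective magnitude
#' response is squared); set `zero_phase = FALSE` for single-pass
#' application.
#'
#' @param order Filter order for each section (default 8).
#' @param low_cut High-pass cut-off in Hz (default 1).
#' @param high_cut Low-pass cut-off in Hz (default 20).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(order = 8, low_cut = 1, high_cut = 20,
                        zero_phase = TRUE) {
  if (low_cut <= 0 || high_cut <= low_cut)
    stop("need 0 < low_cut < high_cut")
  structure(list(order = order, low_cut = low_cut, high_cut = high_cut,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Band-pass filter a recording
#'
#' Applies the Butterworth low-pass then high-pass to every channel of the
#' continuous recording (before any segmentation). The low-pass is applied
#' first: the high-pass stage has poles very close to the unit circle and
#' running it first injects low-frequency rounding noise that the low-pass
#' would then pass; the adopted order keeps the stopband floor below
#' -100 dB.
#'
#' @param rec A [recording()].
#' @param spec A [filter_spec()].
#' @return A filtered [recording()] with identical shape and annotations.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "filter_spec"))
  nyq <- rec$sampling_rate / 2
  if (spec$high_cut >= nyq)
    stop("high_cut must be below the Nyquist frequency")
  lp <- signal::butter(spec$order, spec$high_cut / nyq, type = "low")
  hp <- signal::butter(spec$order, spec$low_cut / nyq, type = "high")
  app <- if (spec$zero_phase) {
    function(x) signal::filtfilt(hp, signal::filtfilt(lp, x))
  } else {
    function(x) signal::filter(hp, signal::filter(lp, x))
  }
  out <- rec
  for (i in seq_len(nrow(rec$samples)))
    out$samples[i, ] <- app(rec$samples[i, ])
  out
}

#' Segment a recording into overlapping fixed-length epochs
#'
#' Within each annotated block, epochs start at `0, step, 2*step, ...`
#' relative to the block onset; the number of epochs per block is
#' `floor((block_duration - epoch_length) / step)` — the convention in
#' which a 120 s block at 4 s / 0.1 s yields `(120 - 4)/0.1 = 1160`
#' epochs (no `+ 1` term). Blocks shorter than `epoch_length + step`
#' contribute zero epochs with a warning.
#'
#' @param rec A [recording()] with block annotations.
#' @param epoch_length Epoch length in seconds (default 4).
#' @param step Start-to-start step in seconds (default 0.1, i.e. 3.9 s
#'   overlap for 4 s epochs).
#' @return An object of class `epoch_set`: the sample matrix plus a
#'   per-epoch metadata table (`condition`, `repetition`, `start_time`,
#'   0-based `start_sample`) and artifact flags (initially all clear).
#' @export
segment_epochs <- function(rec, epoch_length = 4, step = 0.1) {
  stopifnot(inherits(rec, "recording"))
  if (step <= 0) stop("step must be positive")
  fs <- rec$sampling_rate
  k <- epoch_length * fs
  if (abs(k - round(k)) > 1e-9)
    stop("epoch_length times sampling rate must be integral")
  k <- as.integer(round(k))
  meta <- NULL
  for (b in seq_len(nrow(rec$blocks))) {
    blk <- rec$blocks[b, ]
    n_ep <- floor((blk$duration - epoch_length) / step + 1e-9)
    if (n_ep < 1) {
      warning(sprintf("block %s_%d (%.3g s) shorter than needed; 0 epochs",
                      blk$condition, blk$repetition, blk$duration))
      next
    }
    starts <- blk$onset + (0:(n_ep - 1)) * step
    meta <- rbind(meta, data.frame(
      condition = blk$condition, repetition = blk$repetition,
      start_time = starts,
      start_sample = as.integer(round(starts * fs))))
  }
  if (is.null(meta))
    meta <- data.frame(condition = character(), repetition = integer(),
                       start_time = numeric(), start_sample = integer())
  meta$flagged <- rep(FALSE, nrow(meta))
  meta$reason <- rep("", nrow(meta))
  structure(list(samples = rec$samples, sampling_rate = fs,
                 channels = rec$channels, epoch_samples = k,
                 epoch_length = epoch_length, step = step, meta = meta),
            class = "epoch_set")
}

#' Number of epochs in an epoch set
#' @param es An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(es) nrow(es$meta)

#' Extract one epoch's sample matrix
#' @param es An `epoch_set`.
#' @param i Epoch index.
#' @return Channels x samples matrix.
#' @export
epoch_data <- function(es, i) {
  s <- es$meta$start_sample[i]
  es$samples[, (s + 1):(s + es$epoch_samples), drop = FALSE]
}

#' Subset an epoch set by epoch index
#' @param es An `epoch_set`.
#' @param idx Integer or logical index over epochs.
#' @return An `epoch_set` with the selected epochs.
#' @export
subset_epochs <- function(es, idx) {
  es$meta <- es$meta[idx, , drop = FALSE]
  rownames(es$meta) <- NULL
  es
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (step %g s), %d channels, %d flagged\n",
              n_epochs(x), x$epoch_length, x$step, nrow(x$channels),
              sum(x$meta$flagged)))
  invisible(x)
}

add_flag <- function(es, hit, code) {
  new <- hit & !grepl(code, es$meta$reason, fixed = TRUE)
  es$meta$flagged <- es$meta$flagged | hit
  es$meta$reason[new] <- trimws(paste(es$meta$reason[new], code))
  es
}

#' Flag epochs exceeding an absolute amplitude limit
#'
#' An epoch is marked as artifact when any sample on any channel is
#' strictly larger than `limit` in absolute value (`|x| > limit`; a sample
#' at exactly the limit does not flag). Flags accumulate across rules and
#' are idempotent.
#'
#' @param es An `epoch_set`.
#' @param limit Amplitude limit in microvolts (default 100).
#' @return The `epoch_set` with updated flags (reason code `"amplitude"`).
#' @export
flag_amplitude <- function(es, limit = 100) {
  stopifnot(inherits(es, "epoch_set"))
  if (limit <= 0) stop("limit must be positive")
  if (n_epochs(es) == 0) return(es)
  bad <- colSums(abs(es$samples) > limit) > 0
  cs <- c(0, cumsum(bad))
  s <- es$meta$start_sample
  hit <- (cs[s + es$epoch_samples + 1] - cs[s + 1]) > 0
  add_flag(es, hit, "amplitude")
}

#' Flag epochs with a linear trend steeper than a slope limit
#'
#' Fits a least-squares line to each epoch on each channel and marks the
#' epoch as artifact when the absolute slope exceeds `max_slope`
#' (strictly; exactly the limit does not flag) on any channel.
#'
#' @param es An `epoch_set`.
#' @param max_slope Slope limit in microvolts per second (default 10).
#' @return The `epoch_set` with updated flags (reason code `"trend"`).
#' @export
flag_trend <- function(es, max_slope = 10) {
  stopifnot(inherits(es, "epoch_set"))
  if (max_slope <= 0) stop("max_slope must be positive")
  if (n_epochs(es) == 0) return(es)
  k <- es$epoch_samples
  fs <- es$sampling_rate
  s <- es$meta$start_sample
  ibar <- (k + 1) / 2
  den <- k * (k^2 - 1) / 12       # sum over (i - ibar)^2, i = 1..k
  hit <- rep(FALSE, n_epochs(es))
  for (ch in seq_len(nrow(es$samples))) {
    x <- es$samples[ch, ]
    s1 <- c(0, cumsum(x))
    s2 <- c(0, cumsum(seq_along(x) * x))
    sum_x <- s1[s + k + 1] - s1[s + 1]
    sum_jx <- s2[s + k + 1] - s2[s + 1]
    sum_ix <- sum_jx - s * sum_x              # local index i = j - s
    slope <- (sum_ix - ibar * sum_x) / den * fs  # uV per second
    hit <- hit | (abs(slope) > max_slope)
  }
  add_flag(es, hit, "trend")
}

#' Drop flagged epochs
#'
#' Returns only the unflagged epochs; an epoch flagged on any channel is
#' removed for all channels. Errors if nothing survives.
#'
#' @param es An `epoch_set`.
#' @param context Optional label (e.g. subject id) used in the error
#'   message when all epochs are flagged.
#' @return An `epoch_set` containing only clean epochs.
#' @export
drop_flagged <- function(es, context = "recording") {
  stopifnot(inherits(es, "epoch_set"))
  keep <- !es$meta$flagged
  if (n_epochs(es) > 0 && !any(keep))
    stop(sprintf("all %d epochs flagged as artifact in %s",
                 n_epochs(es), context))
  subset_epochs(es, keep)
}

#' Full preprocessing chain
#'
#' Filter the continuous recording, segment it into overlapping epochs,
#' apply the amplitude and trend artifact rules, and drop flagged epochs.
#'
#' @param rec A [recording()].
#' @param spec A [filter_spec()].
#' @param epoch_length,step Epoching parameters in seconds.
#' @param amp_limit Amplitude rule limit (uV).
#' @param slope_limit Trend rule limit (uV/s).
#' @param context Label for error messages.
#' @return A clean `epoch_set`; the attribute `n_flagged` records how many
#'   epochs were removed.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(),
                                 epoch_length = 4, step = 0.1,
                                 amp_limit = 100, slope_limit = 10,
                                 context = "recording") {
  es <- segment_epochs(bandpass(rec, spec), epoch_length, step)
  es <- flag_trend(flag_amplitude(es, amp_limit), slope_limit)
  out <- drop_flagged(es, context)
  attr(out, "n_flagged") <- sum(es$meta$flagged)
  out
}
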