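#' Per-epoch power spectral density
#'
#' One Hanning-windowed periodogram per epoch and channel. The estimate is
#' window-power corrected (`PSD = 2 |FFT(w x)|^2 / (fs * sum(w^2))`, with
#' no doubling at DC/Nyquist) so that white noise of variance `sigma^2`
#' integrates back to `sigma^2`. With the default 4 s epochs at 250 Hz the
#' frequency grid spacing is exactly 0.25 Hz.
#'
#' @param es An `epoch_set` (typically artifact-free).
#' @param channels Optional character vector restricting the channels.
#' @param fmax Optional upper frequency bound (Hz) to truncate the stored
#'   grid (saves memory for large epoch sets).
#' @return An object of class `spectrum_set` with fields `frequencies`
#'   (Hz), `values` (epoch x channel x frequency array, uV^2/Hz),
#'   `level = "per_epoch"`, `channels`, and the epoch metadata in `meta`.
#' @export
epoch_psd <- function(es, channels = NULL, fmax = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  if (n_epochs(es) == 0) stop("no epochs to transform")
  k <- es$epoch_samples
  fs <- es$sampling_rate
  labs <- es$channels$label
  if (!is.null(channels)) {
    if (!all(channels %in% labs)) stop("unknown channel in `channels`")
    labs <- channels
  }
  w <- hann_window(k)
  scale <- 1 / (fs * sum(w^2))
  nf <- k %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / k
  keep <- if (is.null(fmax)) seq_len(nf) else which(freqs <= fmax + 1e-9)
  n_ep <- n_epochs(es)
  vals <- array(NA_real_, c(n_ep, length(labs), length(keep)),
                dimnames = list(NULL, labs, NULL))
  idx <- outer(seq_len(k), es$meta$start_sample, "+")  # k x n_ep
  for (ci in seq_along(labs)) {
    m <- matrix(es$samples[labs[ci], idx], k, n_ep) * w
    ft <- stats::mvfft(m)[seq_len(nf), , drop = FALSE]
    p <- (Mod(ft)^2) * scale
    dbl <- if (k %% 2 == 0) 2:(nf - 1) else 2:nf  # no doubling at DC/Nyquist
    p[dbl, ] <- 2 * p[dbl, ]
    vals[, ci, ] <- t(p[keep, , drop = FALSE])
  }
  structure(list(frequencies = freqs[keep], values = vals,
                 level = "per_epoch", channels = labs, meta = es$meta,
                 sampling_rate = fs),
            class = "spectrum_set")
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' @export
print.spectrum_set <- function(x, ...) {
  n <- if (x$level == "per_epoch") dim(x$values)[1] else 1L
  cat(sprintf("<spectrum_set> level=%s, %d channels, %d bins (%g-%g Hz, d=%g)%s\n",
              x$level, length(x$channels), length(x$frequencies),
              min(x$frequencies), max(x$frequencies),
              diff(x$frequencies[1:2]),
              if (x$level == "per_epoch") sprintf(", %d epochs", n) else ""))
  invisible(x)
}

mean_spectrum <- function(ss, rows, level, provenance) {
  if (length(rows) == 0) stop("no epochs selected for averaging")
  v <- ss$values[rows, , , drop = FALSE]
  m <- apply(v, c(2, 3), mean)
  dimnames(m) <- list(ss$channels, NULL)
  structure(list(frequencies = ss$frequencies, values = m, level = level,
                 channels = ss$channels, provenance = provenance,
                 sampling_rate = ss$sampling_rate),
            class = "spectrum_set")
}

#' Mean spectrum of one repetition
#'
#' Arithmetic mean across the epochs of one `condition`/`repetition`
#' block, per channel and frequency bin.
#'
#' @param ss A per-epoch `spectrum_set`.
#' @param condition "OC" or "OA".
#' @param repetition Repetition index.
#' @return A `spectrum_set` with `level = "repetition_mean"` and a
#'   channel x frequency `values` matrix.
#' @export
repetition_mean <- function(ss, condition, repetition) {
  stopifnot(inherits(ss, "spectrum_set"), ss$level == "per_epoch")
  rows <- which(ss$meta$condition == condition &
                ss$meta$repetition == repetition)
  if (length(rows) == 0)
    stop(sprintf("no epochs for %s_%d", condition, repetition))
  mean_spectrum(ss, rows, "repetition_mean",
                list(condition = condition, repetition = repetition,
                     n_epochs = length(rows)))
}

#' Condition-mean spectrum
#'
#' The unweighted mean of the per-repetition mean spectra of one
#' condition (each repetition counts equally regardless of how many of
#' its epochs survived artifact rejection).
#'
#' @param x Either a per-epoch `spectrum_set` or a list of
#'   `repetition_mean` spectrum sets of the same condition.
#' @param condition "OC" or "OA" (required for the per-epoch form).
#' @param n_expected Number of repetitions expected (warn when fewer are
#'   present; default 4).
#' @return A `spectrum_set` with `level = "condition_mean"`.
#' @export
condition_mean <- function(x, condition = NULL, n_expected = 4) {
  if (inherits(x, "spectrum_set")) {
    stopifnot(x$level == "per_epoch", !is.null(condition))
    reps <- sort(unique(x$meta$repetition[x$meta$condition == condition]))
    if (length(reps) == 0)
      stop(sprintf("no repetitions for condition %s", condition))
    x <- lapply(reps, function(r) repetition_mean(x, condition, r))
  }
  stopifnot(is.list(x), length(x) >= 1,
            all(vapply(x, function(s) s$level == "repetition_mean",
                       logical(1))))
  if (is.null(condition)) condition <- x[[1]]$provenance$condition
  if (length(x) < n_expected)
    warning(sprintf("condition %s has %d repetition(s), expected %d",
                    condition, length(x), n_expected))
  m <- Reduce(`+`, lapply(x, function(s) s$values)) / length(x)
  structure(list(frequencies = x[[1]]$frequencies, values = m,
                 level = "condition_mean", channels = x[[1]]$channels,
                 provenance = list(condition = condition,
                                   repetitions = vapply(x, function(s)
                                     s$provenance$repetition, numeric(1))),
                 sampling_rate = x[[1]]$sampling_rate),
            class = "spectrum_set")
}

#' Convert a PSD to decibels
#'
#' Elementwise `20 * log10(PSD)`. This scaling is used for display only;
#' all analysis (IAF, correlation, classification features) operates on
#' the linear PSD. Zero or negative values raise an error unless an
#' explicit `floor` is supplied.
#'
#' @param ss A `spectrum_set`.
#' @param floor Optional positive value at which the PSD is floored before
#'   the transform.
#' @return The `spectrum_set` with transformed values and attribute
#'   `unit = "dB"`.
#' @export
psd_to_db <- function(ss, floor = NULL) {
  stopifnot(inherits(ss, "spectrum_set"))
  v <- ss$values
  if (!is.null(floor)) {
    if (floor <= 0) stop("floor must be positive")
    v <- pmax(v, floor)
  }
  if (any(v <= 0))
    stop("PSD must be strictly positive for dB conversion (set `floor`)")
  ss$values <- 20 * log10(v)
  attr(ss, "unit") <- "dB"
  ss
}

#' Slice one channel's spectrum
#' @param ss A mean-level `spectrum_set`.
#' @param channel Channel label.
#' @return Numeric vector of PSD values along `ss$frequencies`.
#' @export
channel_spectrum <- function(ss, channel) {
  stopifnot(inherits(ss, "spectrum_set"),
            ss$level %in% c("repetition_mean", "condition_mean"))
  if (!channel %in% ss$channels) stop("unknown channel: ", channel)
  ss$values[match(channel, ss$channels), ]
}
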