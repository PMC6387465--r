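#' Alpha search range
#'
#' The traditional alpha window within which the individual alpha
#' frequency (IAF) is sought.
#'
#' @param f1,f2 Lower and upper bounds in Hz (defaults 7.5 and 12.5).
#' @return Object of class `alpha_range`.
#' @export
alpha_range <- function(f1 = 7.5, f2 = 12.5) {
  if (!(f1 < f2)) stop("need f1 < f2")
  structure(list(f1 = f1, f2 = f2), class = "alpha_range")
}

range_bins <- function(freqs, range) {
  which(freqs >= range$f1 - 1e-9 & freqs <= range$f2 + 1e-9)
}

# Count strict local maxima of y (greater than both neighbours), treating
# the bins just outside the range as neighbours where available.
local_maxima_in_range <- function(y_full, bins) {
  n <- length(y_full)
  is_max <- vapply(bins, function(i) {
    left <- if (i > 1) y_full[i - 1] else -Inf
    right <- if (i < n) y_full[i + 1] else -Inf
    y_full[i] > left && y_full[i] > right
  }, logical(1))
  bins[is_max]
}

new_iaf <- function(value, method, n_local_maxima, channel, degenerate = FALSE) {
  structure(list(value = value, method = method,
                 n_local_maxima = n_local_maxima, channel = channel,
                 degenerate = degenerate),
            class = "iaf_estimate")
}

#' @export
print.iaf_estimate <- function(x, ...) {
  cat(sprintf("<iaf> %.2f Hz (%s%s%s, %d local maxima)\n", x$value, x$method,
              if (is.null(x$channel)) "" else paste0(", ", x$channel),
              if (x$degenerate) ", degenerate" else "", x$n_local_maxima))
  invisible(x)
}

#' IAF by the peak method
#'
#' The frequency of the largest PSD bin within the alpha search range.
#' When the spectrum has no interior local maximum in the range (e.g. a
#' monotone 1/f profile), the estimate is flagged degenerate and the
#' gravity method is recommended instead. Ties between equal maximal bins
#' are also flagged (and resolved toward the gravity method by
#' [estimate_iaf()]).
#'
#' `n_local_maxima` counts the *comparable* local maxima: strict local
#' maxima whose height is at least `prominence` times the range maximum.
#' Small noise wiggles on the flanks of a dominant peak are therefore not
#' treated as competing alpha peaks; genuinely split alpha peaks are.
#'
#' @param ss A mean-level `spectrum_set` (typically the mean-OC spectrum).
#' @param channel Channel label.
#' @param range An [alpha_range()].
#' @param smooth Apply a 3-bin moving average before peak picking
#'   (default `FALSE`).
#' @param prominence Relative height (fraction of the range maximum) above
#'   which a local maximum counts as a competing peak (default 0.25).
#' @return An `iaf_estimate` (`value` lies on the frequency grid).
#' @export
iaf_peak <- function(ss, channel, range = alpha_range(), smooth = FALSE,
                     prominence = 0.25) {
  y <- channel_spectrum(ss, channel)
  if (smooth)
    y <- as.numeric(stats::filter(y, rep(1 / 3, 3))) |>
      (\(z) { z[is.na(z)] <- y[is.na(z)]; z })()
  bins <- range_bins(ss$frequencies, range)
  if (length(bins) == 0) stop("spectrum does not cover the alpha range")
  lm_bins <- local_maxima_in_range(y, bins)
  peak_bin <- bins[which.max(y[bins])]
  lm_bins <- lm_bins[y[lm_bins] >= prominence * y[peak_bin]]
  tied <- sum(abs(y[bins] - y[peak_bin]) < .Machine$double.eps * 100) > 1
  new_iaf(ss$frequencies[peak_bin], "peak", length(lm_bins), channel,
          degenerate = length(lm_bins) == 0 || tied)
}

#' IAF by the gravity (mean-frequency) method
#'
#' The PSD-weighted mean frequency over the alpha search range:
#' `sum(a(f) * f) / sum(a(f))` with `a(f)` the linear PSD. Scale-free in
#' the PSD and always inside the range.
#'
#' @inheritParams iaf_peak
#' @return An `iaf_estimate`.
#' @export
iaf_gravity <- function(ss, channel, range = alpha_range()) {
  y <- channel_spectrum(ss, channel)
  bins <- range_bins(ss$frequencies, range)
  if (length(bins) == 0) stop("spectrum does not cover the alpha range")
  a <- y[bins]
  if (sum(a) <= 0) stop("zero alpha power; gravity IAF undefined")
  new_iaf(sum(a * ss$frequencies[bins]) / sum(a), "gravity",
          length(local_maxima_in_range(y, bins)), channel)
}

#' IAF with the combined peak/gravity policy
#'
#' Uses the peak method when the range contains a unique interior local
#' maximum; falls back to the gravity method when there are multiple local
#' maxima (where the mean frequency is the more adequate estimate) or none
#' at all. The policy can be forced.
#'
#' @inheritParams iaf_peak
#' @param policy `"auto"` (default), `"peak"` or `"gravity"`.
#' @return An `iaf_estimate`.
#' @export
estimate_iaf <- function(ss, channel, range = alpha_range(),
                         policy = c("auto", "peak", "gravity")) {
  policy <- match.arg(policy)
  if (policy == "peak") return(iaf_peak(ss, channel, range))
  if (policy == "gravity") return(iaf_gravity(ss, channel, range))
  pk <- iaf_peak(ss, channel, range)
  if (pk$n_local_maxima == 1 && !pk$degenerate) pk
  else iaf_gravity(ss, channel, range)
}

#' IAF-anchored frequency band table
#'
#' The five bands defined as offsets from the IAF:
#' Delta `(0, IAF-6)`, Theta `(IAF-6, IAF-2)`, Alpha `(IAF-2, IAF+2)`,
#' Beta `(IAF+2, IAF+16)`, Gamma `(IAF+16, IAF+25)`. Contiguous and
#' ordered; requires `IAF > 6` so Delta is non-empty.
#'
#' @param iaf An `iaf_estimate` or a numeric IAF in Hz.
#' @return Data frame with columns `band`, `f1`, `f2`.
#' @export
define_bands <- function(iaf) {
  v <- if (inherits(iaf, "iaf_estimate")) iaf$value else iaf
  if (!is.numeric(v) || length(v) != 1) stop("iaf must be a scalar")
  if (v <= 6) stop("IAF must exceed 6 Hz for a non-empty Delta band")
  data.frame(band = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
             f1 = c(0, v - 6, v - 2, v + 2, v + 16),
             f2 = c(v - 6, v - 2, v + 2, v + 16, v + 25))
}

#' Frequency bins of a band on the analysis grid
#'
#' Grid frequencies `f` with `f1 <= f < f2` (half-open, so a 4 Hz band at
#' 0.25 Hz resolution has exactly 16 bins), intersected with the analysis
#' range (itself half-open, default the 1-20 Hz band-pass).
#'
#' @param f1,f2 Band edges in Hz.
#' @param resolution Grid spacing in Hz (default 0.25).
#' @param analysis_range Length-2 numeric, default `c(1, 20)`.
#' @return Numeric vector of bin frequencies (possibly empty, with a
#'   warning).
#' @export
band_bins <- function(f1, f2, resolution = 0.25, analysis_range = c(1, 20)) {
  if (!(f1 < f2)) stop("need f1 < f2")
  lo <- max(f1, analysis_range[1])
  hi <- min(f2, analysis_range[2])
  if (lo >= hi - 1e-9) {
    warning(sprintf("band (%g, %g) has no bins inside the analysis range",
                    f1, f2))
    return(numeric(0))
  }
  first <- ceiling(lo / resolution - 1e-9) * resolution
  out <- seq(first, hi, by = resolution)
  out[out < hi - 1e-9]
}

#' Per-channel IAF table for a cohort
#'
#' Applies [estimate_iaf()] to the mean-OC spectrum of every channel of
#' every subject.
#'
#' @param oc_means List (one per subject) of condition-mean
#'   `spectrum_set`s.
#' @param range An [alpha_range()].
#' @param policy Passed to [estimate_iaf()].
#' @return Data frame `subject`, `channel`, `iaf`, `method`.
#' @export
iaf_table <- function(oc_means, range = alpha_range(), policy = "auto") {
  do.call(rbind, lapply(seq_along(oc_means), function(s) {
    ss <- oc_means[[s]]
    ests <- lapply(ss$channels, function(ch)
      estimate_iaf(ss, ch, range, policy))
    data.frame(subject = s, channel = ss$channels,
               iaf = vapply(ests, function(e) e$value, numeric(1)),
               method = vapply(ests, function(e) e$method, character(1)))
  }))
}
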