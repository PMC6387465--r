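#' Alpha-profile correlation between an EEG and a noEEG channel
#'
#' Pearson correlation between the two channels' mean-OC linear PSD
#' profiles, taking the alpha-range frequency bins as the paired
#' observations (one correlation per channel couple). The two-sided
#' p-value comes from the exact t transform with `n_points - 2` degrees of
#' freedom.
#'
#' @param ss A condition-mean `spectrum_set` (mean OC).
#' @param eeg_channel,noeeg_channel Channel labels.
#' @param range An [alpha_range()] (default the fixed 7.5-12.5 Hz window).
#' @return A one-row data frame: `eeg_channel`, `noeeg_channel`, `R`, `p`,
#'   `n_points`.
#' @export
alpha_profile_correlation <- function(ss, eeg_channel, noeeg_channel,
                                      range = alpha_range()) {
  bins <- range_bins(ss$frequencies, range)
  if (length(bins) < 3) stop("need at least 3 alpha bins for correlation")
  x <- channel_spectrum(ss, eeg_channel)[bins]
  y <- channel_spectrum(ss, noeeg_channel)[bins]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in an alpha profile; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(eeg_channel = eeg_channel, noeeg_channel = noeeg_channel,
             R = unname(ct$estimate), p = ct$p.value,
             n_points = length(bins))
}

#' All EEG x noEEG alpha-profile correlations for one subject
#'
#' @param ss A condition-mean `spectrum_set` (mean OC) covering all
#'   channels.
#' @param eeg_channels,noeeg_channels Label vectors; defaults are all EEG
#'   and all neck/wrist channels present in `ss`.
#' @param range An [alpha_range()].
#' @return Data frame with one row per couple.
#' @export
couple_correlations <- function(ss, eeg_channels = NULL,
                                noeeg_channels = NULL,
                                range = alpha_range()) {
  roles <- channel_role(ss$channels)
  if (is.null(eeg_channels)) eeg_channels <- ss$channels[roles == "EEG"]
  if (is.null(noeeg_channels)) noeeg_channels <- ss$channels[roles != "EEG"]
  grid <- expand.grid(eeg_channel = eeg_channels,
                      noeeg_channel = noeeg_channels,
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    alpha_profile_correlation(ss, grid$eeg_channel[i],
                              grid$noeeg_channel[i], range)))
}

#' Common correlation pattern across all subjects
#'
#' A channel couple enters the common pattern only when its correlation is
#' positive (`R > 0`) and significant (`p < alpha`) in every subject; a
#' single failing subject excludes the couple. No multiple-testing
#' correction is applied by default (set `adjust = "fdr"` or any
#' [stats::p.adjust()] method to correct within each subject).
#'
#' @param per_subject List of per-subject data frames from
#'   [couple_correlations()], all covering the same couples.
#' @param alpha Significance level (default 0.05).
#' @param adjust Optional p-value adjustment method (default `"none"`).
#' @return Data frame of the retained couples (`eeg_channel`,
#'   `noeeg_channel`), with attribute `n_subjects`.
#' @export
common_pattern <- function(per_subject, alpha = 0.05, adjust = "none") {
  stopifnot(is.list(per_subject), length(per_subject) >= 1)
  key <- function(d) paste(d$eeg_channel, d$noeeg_channel, sep = "|")
  keys <- key(per_subject[[1]])
  ok <- rep(TRUE, length(keys))
  for (d in per_subject) {
    if (!identical(sort(key(d)), sort(keys)))
      stop("subjects evaluated on different couple sets")
    d <- d[match(keys, key(d)), ]
    p <- stats::p.adjust(d$p, method = adjust)
    ok <- ok & (d$R > 0) & (p < alpha)
  }
  out <- per_subject[[1]][ok, c("eeg_channel", "noeeg_channel")]
  rownames(out) <- NULL
  attr(out, "n_subjects") <- length(per_subject)
  out
}

#' IAF-difference map over the common pattern
#'
#' For every couple in the common pattern and every subject, the
#' difference `d = IAF_EEG - IAF_noEEG` is computed, then averaged across
#' subjects. The mean is categorized as in the difference-map display:
#' `equal` (d = 0), `eeg_higher` (0 < d <= 0.25), `eeg_lower`
#' (-0.25 <= d < 0), `out_of_range` (|d| > 0.25). Zero-difference couples
#' are the candidates for proxy feature channels.
#'
#' @param pattern Data frame from [common_pattern()].
#' @param iaf_tab Data frame from [iaf_table()] covering every channel in
#'   the pattern for every subject.
#' @return Data frame: `eeg_channel`, `noeeg_channel`, `mean_d`,
#'   `category`, plus one `d_s<i>` column per subject.
#' @export
iaf_difference_map <- function(pattern, iaf_tab) {
  subjects <- sort(unique(iaf_tab$subject))
  lookup <- function(s, ch) {
    v <- iaf_tab$iaf[iaf_tab$subject == s & iaf_tab$channel == ch]
    if (length(v) != 1)
      stop(sprintf("missing IAF for subject %s channel %s", s, ch))
    v
  }
  if (nrow(pattern) == 0)
    return(data.frame(eeg_channel = character(),
                      noeeg_channel = character(),
                      mean_d = numeric(), category = character()))
  d_mat <- sapply(subjects, function(s)
    mapply(function(e, n) lookup(s, e) - lookup(s, n),
           pattern$eeg_channel, pattern$noeeg_channel))
  d_mat <- matrix(d_mat, nrow = nrow(pattern))
  mean_d <- rowMeans(d_mat)
  out <- data.frame(eeg_channel = pattern$eeg_channel,
                    noeeg_channel = pattern$noeeg_channel,
                    mean_d = mean_d,
                    category = vapply(mean_d, diff_category, character(1)))
  colnames(d_mat) <- paste0("d_s", subjects)
  cbind(out, as.data.frame(d_mat))
}

diff_category <- function(d, tol = 1e-9) {
  if (abs(d) <= tol) "equal"
  else if (d > tol && d <= 0.25 + tol) "eeg_higher"
  else if (d < -tol && d >= -0.25 - tol) "eeg_lower"
  else "out_of_range"
}
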