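#' Simulation configuration for synthetic EEG + noEEG cohorts
#'
#' Defines the statistical structure of a synthetic cohort: a per-subject
#' alpha oscillator (IAF drawn from `subject_iaf`, quantized to the 0.25 Hz
#' analysis grid) strongly present during eyes-closed (OC) blocks and
#' attenuated during eyes-open (OA) blocks on posterior scalp channels; a
#' theta oscillator with the opposite (OA >= OC) modulation; 1/f background
#' noise whose broadband level is higher during OA; and scalar
#' volume-conduction coupling of the posterior source activity onto a
#' subset of non-cerebral channels.
#'
#' The effect sizes (oscillator amplitudes, background OA/OC ratio,
#' coupling coefficients) are generator parameters chosen to give a
#' realistic, clearly discriminable OC/OA contrast; they are not empirical
#' measurements. See the methods vignette for the rationale behind each
#' default.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param sampling_rate Hz.
#' @param block_length Seconds per condition block.
#' @param n_repetitions Repetitions per condition (blocks total
#'   `2 * n_repetitions`).
#' @param subject_iaf Either a fixed IAF in Hz or a length-2 range to
#'   sample from uniformly; values are quantized to 0.25 Hz.
#' @param alpha_amp_oc,alpha_amp_oa Alpha oscillator amplitude (uV) at the
#'   strongest posterior channel, per condition.
#' @param theta_amp_oc,theta_amp_oa Theta oscillator amplitude (uV);
#'   the OA value should be >= the OC value.
#' @param background List: `exponent` (1/f spectral slope), `scale`
#'   (background SD in uV on EEG channels), `oa_ratio` (broadband OA/OC
#'   amplitude ratio), `noeeg_factor` (background scale multiplier for
#'   non-cerebral channels), `white_sd` (additive sensor noise SD, uV).
#' @param coupling Named numeric vector in `[0, 1]`: attenuation of the
#'   posterior source activity on each noEEG channel; channels absent from
#'   the vector are uncoupled.
#' @param artifact_rates List: `blinks_per_min`, `emg_per_min`, `ecg_bpm`
#'   event rates and `blink_amp`, `emg_amp`, `ecg_amp` amplitudes (uV).
#'   All-zero rates (the default) leave recordings artifact-free.
#' @param channels Character vector of channel labels (default: the full
#'   27 EEG + 16 noEEG montage). A reduced montage is useful for fast tests.
#' @param seed Master integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12,
                       sampling_rate = 250,
                       block_length = 120,
                       n_repetitions = 4,
                       subject_iaf = c(8, 12),
                       alpha_amp_oc = 8,
                       alpha_amp_oa = 1.5,
                       theta_amp_oc = 1.2,
                       theta_amp_oa = 2.5,
                       background = list(),
                       coupling = default_coupling(),
                       artifact_rates = list(),
                       channels = default_montage()$label,
                       seed = 1L) {
  bg <- utils::modifyList(list(exponent = 1, scale = 3, oa_ratio = 1.35,
                               noeeg_factor = 0.5, white_sd = 0.4),
                          background)
  ar <- utils::modifyList(list(blinks_per_min = 0, emg_per_min = 0,
                               ecg_bpm = 0, blink_amp = 150, emg_amp = 60,
                               ecg_amp = 80),
                          artifact_rates)
  cfg <- structure(list(n_subjects = as.integer(n_subjects),
                        sampling_rate = sampling_rate,
                        block_length = block_length,
                        n_repetitions = as.integer(n_repetitions),
                        subject_iaf = subject_iaf,
                        alpha_amp_oc = alpha_amp_oc,
                        alpha_amp_oa = alpha_amp_oa,
                        theta_amp_oc = theta_amp_oc,
                        theta_amp_oa = theta_amp_oa,
                        background = bg, coupling = coupling,
                        artifact_rates = ar,
                        channels = channels, seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default volume-conduction coupling map
#'
#' Nonzero attenuation coefficients on the eight non-cerebral channels used
#' as classification features (four neck, four wrist); the remaining noEEG
#' channels are uncoupled and carry only their own background noise.
#' @return Named numeric vector.
#' @export
default_coupling <- function() {
  c(Neck2 = 0.50, Neck4 = 0.60, Neck5 = 0.50, Neck6 = 0.45,
    WrL2 = 0.40, WrR1 = 0.35, WrR2 = 0.40, WrR4 = 0.35)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$sampling_rate <= 0 || cfg$block_length <= 0 ||
      cfg$n_repetitions < 1)
    stop("sampling_rate, block_length and n_repetitions must be positive",
         call. = FALSE)
  amps <- c(cfg$alpha_amp_oc, cfg$alpha_amp_oa, cfg$theta_amp_oc,
            cfg$theta_amp_oa, cfg$background$scale, cfg$background$white_sd)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(cfg$coupling < 0 | cfg$coupling > 1))
    stop("coupling coefficients must lie in [0, 1]", call. = FALSE)
  iaf_hi <- max(cfg$subject_iaf)
  if (cfg$sampling_rate <= 2 * (iaf_hi + 2))
    stop("sampling_rate must exceed twice the highest simulated frequency",
         call. = FALSE)
  rates <- unlist(cfg$artifact_rates[c("blinks_per_min", "emg_per_min",
                                       "ecg_bpm")])
  if (any(rates < 0)) stop("artifact rates must be >= 0", call. = FALSE)
  if (!(length(cfg$subject_iaf) %in% 1:2))
    stop("subject_iaf must be a value or a range", call. = FALSE)
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields map directly onto [sim_config()] arguments; `background`,
#' `coupling` and `artifact_rates` may be given as nested maps. `seed` is
#' required.
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config file must set a master seed")
  if (!is.null(y$coupling)) y$coupling <- unlist(y$coupling)
  do.call(sim_config, y)
}

# Alpha topography: relative source gain per EEG channel (posterior gradient).
alpha_topography <- function(labels) {
  w <- rep(0.1, length(labels))
  names(w) <- labels
  set_if <- function(w, pat, val) { w[grepl(pat, names(w))] <- val; w }
  w <- set_if(w, "^O[12z]$", 1.00)
  w <- set_if(w, "^PO", 0.85)
  w <- set_if(w, "^P[0-9z]", 0.70)
  w <- set_if(w, "^CP", 0.55)
  w <- set_if(w, "^C[0-9z]", 0.40)
  w <- set_if(w, "^F[0-9z]", 0.25)
  w <- set_if(w, "^AF", 0.15)
  w <- set_if(w, "^Fp", 0.10)
  w[channel_role(labels) != "EEG"] <- 0
  w
}

# Theta topography: fronto-central dominant, present across the scalp.
theta_topography <- function(labels) {
  w <- rep(0.5, length(labels))
  names(w) <- labels
  w[grepl("^(F[0-9z]|C[0-9z]|CP)", labels)] <- 1.0
  w[grepl("^(P|PO|O)", labels)] <- 0.7
  w[channel_role(labels) != "EEG"] <- 0
  w
}

# Slow positive amplitude envelope: Gaussian noise on a 2 s grid, spline
# interpolated, unit mean. Gives the oscillator a realistic nonzero
# spectral width (~0.1 Hz, under half a 0.25 Hz analysis bin) while
# keeping the PSD maximum on the carrier bin.
slow_envelope <- function(n, fs, depth = 0.35) {
  grid_dt <- 2
  m <- max(4, ceiling(n / fs / grid_dt) + 2)
  z <- stats::rnorm(m)
  z <- stats::filter(z, rep(1 / 3, 3), circular = TRUE)  # mild smoothing
  z <- as.numeric(z) / stats::sd(z)
  tt <- seq(0, by = grid_dt, length.out = m)
  env <- stats::spline(tt, 1 + depth * z, xout = (0:(n - 1)) / fs)$y
  pmax(env, 0.05)
}

# Narrowband oscillator: amplitude-modulated sinusoid at frequency f.
oscillator <- function(n, fs, f, amp, phase) {
  amp * slow_envelope(n, fs) * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# 1/f background noise of length n with SD `scale` via spectral shaping.
pink_noise <- function(n, fs, exponent, scale) {
  if (scale == 0) return(numeric(n))
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  mag <- pmin(f, Inf)^(-exponent / 2)
  mag[f < 0.5] <- 0.5^(-exponent / 2)  # flatten below 0.5 Hz
  re <- stats::rnorm(nf) * mag
  im <- stats::rnorm(nf) * mag
  spec <- complex(real = re, imaginary = im)
  full <- c(complex(real = 0), spec,
            if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * (scale / stats::sd(x))
}

derive_subject_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

draw_iaf <- function(subject_iaf) {
  if (length(subject_iaf) == 1) return(round(subject_iaf * 4) / 4)
  round(stats::runif(1, subject_iaf[1], subject_iaf[2]) * 4) / 4
}

#' Generate one synthetic subject recording
#'
#' Produces a continuous recording with `2 * n_repetitions` annotated
#' condition blocks (equal numbers of OC and OA in randomized order), an
#' alpha oscillator at the subject's IAF that is strong during OC and
#' attenuated during OA on posterior EEG channels and (scaled by the
#' coupling coefficients) on the coupled noEEG channels, a theta
#' oscillator with the opposite modulation, and 1/f background noise whose
#' broadband level is `background$oa_ratio` times larger during OA.
#'
#' Determinism: the subject's RNG stream is derived from
#' `config$seed` and `subject_index`, so identical calls are bit-identical.
#'
#' @param config A [sim_config()].
#' @param subject_index 1-based subject index (`<= n_subjects`).
#' @return A [recording()] with attributes `true_iaf` (Hz) and
#'   `subject_index`.
#' @export
generate_subject <- function(config, subject_index = 1L) {
  validate_sim_config(config)
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop("subject_index must be in 1..n_subjects")
  seed <- derive_subject_seeds(config$seed, config$n_subjects)[subject_index]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  fs <- config$sampling_rate
  iaf <- draw_iaf(config$subject_iaf)
  theta_f <- iaf - 4  # centre of the IAF-anchored theta band

  labels <- config$channels
  roles <- channel_role(labels)
  n_ch <- length(labels)
  nb <- round(config$block_length * fs)
  n_rep <- config$n_repetitions

  conds <- sample(rep(c("OC", "OA"), each = n_rep))
  reps <- stats::ave(seq_along(conds), conds, FUN = seq_along)
  blocks <- data.frame(condition = conds, repetition = as.integer(reps),
                       onset = (seq_along(conds) - 1) * config$block_length,
                       duration = config$block_length)

  aw <- alpha_topography(labels)
  tw <- theta_topography(labels)
  cpl <- numeric(n_ch)
  names(cpl) <- labels
  hit <- intersect(labels, names(config$coupling))
  cpl[hit] <- config$coupling[hit]

  bg <- config$background
  bg_scale <- ifelse(roles == "EEG", bg$scale, bg$scale * bg$noeeg_factor)

  X <- matrix(0, n_ch, nb * nrow(blocks), dimnames = list(labels, NULL))
  for (b in seq_len(nrow(blocks))) {
    oc <- blocks$condition[b] == "OC"
    a_amp <- if (oc) config$alpha_amp_oc else config$alpha_amp_oa
    t_amp <- if (oc) config$theta_amp_oc else config$theta_amp_oa
    cond_fac <- if (oc) 1 else bg$oa_ratio
    s_alpha <- oscillator(nb, fs, iaf, a_amp, stats::runif(1, 0, 2 * pi))
    s_theta <- oscillator(nb, fs, theta_f, t_amp, stats::runif(1, 0, 2 * pi))
    src <- outer(aw, s_alpha) + outer(tw, s_theta) +
      outer(cpl, s_alpha + s_theta)
    noise <- t(vapply(seq_len(n_ch), function(i)
      pink_noise(nb, fs, bg$exponent, bg_scale[i] * cond_fac),
      numeric(nb)))
    if (bg$white_sd > 0)
      noise <- noise + matrix(stats::rnorm(n_ch * nb, 0, bg$white_sd),
                              n_ch, nb)
    X[, (b - 1) * nb + seq_len(nb)] <- src + noise
  }

  rec <- recording(X, fs,
                   channels = data.frame(label = labels, role = roles,
                                         stringsAsFactors = FALSE),
                   blocks = blocks)
  attr(rec, "true_iaf") <- iaf
  attr(rec, "subject_index") <- as.integer(subject_index)
  rec
}

#' Generate a synthetic cohort
#'
#' One recording per subject, with per-subject RNG streams derived
#' deterministically from the master seed. Ground-truth IAF values are
#' attached both per recording (`attr(rec, "true_iaf")`) and as a summary
#' attribute on the returned list.
#'
#' @param config A [sim_config()].
#' @return List of [recording()] objects of length `n_subjects`, with
#'   attribute `true_iaf` (numeric vector).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  recs <- lapply(seq_len(config$n_subjects),
                 function(i) generate_subject(config, i))
  attr(recs, "true_iaf") <- vapply(recs, attr, numeric(1), "true_iaf")
  recs
}

#' Inject transient artifacts into a recording
#'
#' Adds blink-like low-frequency deflections on frontal channels, broadband
#' EMG-like bursts on a random channel, and periodic ECG-like spikes on the
#' neck channels, at the rates in `config$artifact_rates`. Ground-truth
#' event times are returned in the `artifact_events` attribute so that
#' downstream artifact-rejection flags can be audited. With all rates zero
#' the recording is returned unchanged.
#'
#' @param recording A [recording()].
#' @param config A [sim_config()] (rates and amplitudes are read from
#'   `artifact_rates`).
#' @return The recording with artifacts added and attribute
#'   `artifact_events`: data frame `type`, `onset`, `duration`, `channel`.
#' @export
inject_artifacts <- function(recording, config) {
  validate_sim_config(config)
  ar <- config$artifact_rates
  fs <- recording$sampling_rate
  n <- ncol(recording$samples)
  dur_min <- n / fs / 60
  events <- data.frame(type = character(), onset = numeric(),
                       duration = numeric(), channel = character())
  if (ar$blinks_per_min == 0 && ar$emg_per_min == 0 && ar$ecg_bpm == 0) {
    attr(recording, "artifact_events") <- events
    return(recording)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed + 777L)

  labels <- recording$channels$label
  add_burst <- function(X, ch_idx, onset, dur, wave) {
    i0 <- round(onset * fs) + 1
    idx <- i0:min(n, i0 + length(wave) - 1)
    X[ch_idx, idx] <- X[ch_idx, idx] +
      rep(wave[seq_along(idx)], each = length(ch_idx))
    X
  }
  X <- recording$samples

  if (ar$blinks_per_min > 0) {
    k <- stats::rpois(1, ar$blinks_per_min * dur_min)
    front <- which(grepl("^(Fp|AF)", labels))
    if (k > 0 && length(front) > 0) {
      onsets <- sort(stats::runif(k, 0, n / fs - 0.5))
      dur <- 0.2   # typical eyeblink; short enough to survive the 1 Hz HP
      wave <- ar$blink_amp * sin(pi * seq(0, 1, length.out = round(dur * fs)))^2
      for (o in onsets) X <- add_burst(X, front, o, dur, wave)
      events <- rbind(events, data.frame(type = "blink", onset = onsets,
                                         duration = dur,
                                         channel = "frontal"))
    }
  }
  if (ar$emg_per_min > 0) {
    k <- stats::rpois(1, ar$emg_per_min * dur_min)
    if (k > 0) {
      onsets <- sort(stats::runif(k, 0, n / fs - 0.6))
      dur <- 0.5
      for (o in onsets) {
        ch <- sample(length(labels), 1)
        wave <- ar$emg_amp * stats::rnorm(round(dur * fs))
        X <- add_burst(X, ch, o, dur, wave)
        events <- rbind(events, data.frame(type = "emg", onset = o,
                                           duration = dur,
                                           channel = labels[ch]))
      }
    }
  }
  if (ar$ecg_bpm > 0) {
    neck <- which(recording$channels$role == "neck")
    if (length(neck) > 0) {
      period <- 60 / ar$ecg_bpm
      onsets <- seq(stats::runif(1, 0, period), n / fs - 0.1, by = period)
      dur <- 0.08
      wave <- ar$ecg_amp * sin(pi * seq(0, 1, length.out = round(dur * fs)))
      for (o in onsets) X <- add_burst(X, neck, o, dur, wave)
      events <- rbind(events, data.frame(type = "ecg", onset = onsets,
                                         duration = dur, channel = "neck"))
    }
  }
  recording$samples <- X
  attr(recording, "artifact_events") <- events
  recording
}
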