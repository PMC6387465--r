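#' Default recording montage
#'
#' The 27 scalp EEG channels plus the 16 non-cerebral ("noEEG") channels
#' (eight around the neck, four on each wrist) used throughout the pipeline.
#'
#' @return A data frame with columns `label` and `role`
#'   (`"EEG"`, `"neck"` or `"wrist"`).
#' @export
default_montage <- function() {
  eeg <- c("Fp1", "Fp2", "AF3", "AFz", "AF4", "F7", "F3", "Fz", "F4", "F8",
           "C3", "Cz", "C4", "CP3", "CPz", "CP4", "P7", "P3", "Pz", "P4",
           "P8", "PO3", "POz", "PO4", "O1", "Oz", "O2")
  noeeg <- c(paste0("Neck", 1:8), paste0("WrL", 1:4), paste0("WrR", 1:4))
  data.frame(label = c(eeg, noeeg),
             role = channel_role(c(eeg, noeeg)),
             stringsAsFactors = FALSE)
}

#' Infer channel roles from labels
#'
#' Roles are derived from label prefixes: `Neck*` is a neck channel,
#' `WrL*`/`LWrist*` and `WrR*`/`RWrist*` are wrist channels, everything
#' else is scalp EEG. An explicit `override` map wins over the prefix rule
#' (the montage is described with both the `LWrist1` and `WrL1` spellings
#' in the field, so both are recognised).
#'
#' @param labels Character vector of channel labels.
#' @param override Optional named character vector `label -> role`.
#' @return Character vector of roles (`"EEG"`, `"neck"`, `"wrist"`).
#' @export
channel_role <- function(labels, override = NULL) {
  role <- ifelse(grepl("^Neck", labels), "neck",
          ifelse(grepl("^(WrL|WrR|LWrist|RWrist)", labels), "wrist", "EEG"))
  if (!is.null(override)) {
    hit <- labels %in% names(override)
    role[hit] <- unname(override[labels[hit]])
  }
  if (!all(role %in% c("EEG", "neck", "wrist")))
    stop("channel roles must be one of EEG/neck/wrist")
  role
}

#' Construct a continuous multichannel recording
#'
#' A `recording` holds a channels-by-time sample matrix in microvolts at a
#' fixed sampling rate, together with channel metadata and condition-block
#' annotations. Time is in seconds from recording start, sample indices are
#' 0-based, and block intervals are half-open `[onset, onset + duration)`.
#'
#' @param samples Numeric matrix, channels x samples, in microvolts; row
#'   names are taken as channel labels when `channels` is missing.
#' @param sampling_rate Sampling frequency in Hz.
#' @param channels Data frame with columns `label` and `role`, one row per
#'   matrix row. Defaults to roles inferred from row names.
#' @param blocks Data frame with columns `condition` ("OC"/"OA"),
#'   `repetition`, `onset`, `duration` (seconds). May have zero rows.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, sampling_rate, channels = NULL, blocks = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix (channels x time)")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar (Hz)")
  if (is.null(channels)) {
    labs <- rownames(samples)
    if (is.null(labs)) stop("channel labels required (rownames or channels=)")
    channels <- data.frame(label = labs, role = channel_role(labs),
                           stringsAsFactors = FALSE)
  }
  if (nrow(channels) != nrow(samples))
    stop("channels table must have one row per sample-matrix row")
  if (anyDuplicated(channels$label))
    stop("channel labels must be unique")
  rownames(samples) <- channels$label
  if (is.null(blocks))
    blocks <- data.frame(condition = character(), repetition = integer(),
                         onset = numeric(), duration = numeric())
  blocks <- validate_blocks(blocks, ncol(samples) / sampling_rate)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channels = channels, blocks = blocks),
            class = "recording")
}

validate_blocks <- function(blocks, total_dur) {
  need <- c("condition", "repetition", "onset", "duration")
  if (!all(need %in% names(blocks)))
    stop("blocks need columns condition, repetition, onset, duration")
  if (nrow(blocks) == 0) return(blocks)
  if (!all(blocks$condition %in% c("OC", "OA")))
    stop("block conditions must be OC or OA")
  if (any(blocks$onset < 0) ||
      any(blocks$onset + blocks$duration > total_dur + 1e-9))
    stop("blocks must lie within the recorded duration")
  o <- order(blocks$onset)
  b <- blocks[o, , drop = FALSE]
  if (nrow(b) > 1 &&
      any(b$onset[-1] < (b$onset + b$duration)[-nrow(b)] - 1e-9))
    stop("blocks must not overlap")
  rownames(b) <- NULL
  b
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  tab <- table(x$channels$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (nrow(x$blocks))
    cat(sprintf("  blocks: %d (%s)\n", nrow(x$blocks),
                paste(paste0(x$blocks$condition, "_", x$blocks$repetition),
                      collapse = " ")))
  else cat("  blocks: none\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `recording`.
#' @return Scalar seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate
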