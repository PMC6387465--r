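#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, physical range chosen per channel to cover the signal (never
#' silently clipped). Block annotations, and any ground-truth attributes
#' (`true_iaf`, `artifact_events`), are written to a JSON sidecar at
#' `<path>.json`; EDF+ annotation channels are not used.
#'
#' @param rec A [recording()]; its duration must be a whole number of
#'   seconds.
#' @param path Output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$samples)
  if (n == 0) stop("cannot write an empty recording (0 samples)")
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- n / fs
  if (abs(n_rec - round(n_rec)) > 1e-9)
    stop("recording duration must be a whole number of seconds")
  n_rec <- as.integer(round(n_rec))
  ns <- nrow(rec$samples)

  fix <- function(x, w) {  # fixed-width ASCII field
    s <- sprintf("%-*s", w, as.character(x))
    if (nchar(s) > w) stop("EDF header field too long: ", x)
    s
  }
  num8 <- function(x, width = 8) {
    for (d in 7:3) {
      s <- formatC(x, width = 1, digits = d, format = "g")
      if (nchar(s) <= width) return(s)
    }
    stop("numeric field does not fit in ", width, " chars: ", x)
  }

  # physical range: symmetric, written to the header first and the parsed
  # value reused for quantization so the round trip is self-consistent;
  # the max is kept to 7 chars so its negation also fits in 8
  pmax_raw <- pmax(apply(abs(rec$samples), 1, max), 1) * 1.0001
  pmax_str <- vapply(pmax_raw, num8, character(1), width = 7)
  pmax_use <- as.numeric(pmax_str)
  if (any(pmax_use < pmax_raw / 1.0001))
    stop("signal exceeds representable physical range")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(fix(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                       # patient id
  wr("Startdate 01-JAN-2000 X X X", 80)   # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)                              # record duration (s)
  wr(as.character(ns), 4)
  for (lab in rec$channels$label) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)       # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(paste0("-", pmax_str[i]), 8)
  for (i in seq_len(ns)) wr(pmax_str[i], 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)       # prefiltering
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)

  # affine map consistent with the reader: [-pm, pm] -> [-32768, 32767]
  dig <- round(sweep(sweep(rec$samples, 1, pmax_use, "+"),
                     1, 65535 / (2 * pmax_use), "*")) - 32768
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }

  sidecar <- list(blocks = rec$blocks)
  if (!is.null(attr(rec, "true_iaf")))
    sidecar$true_iaf <- attr(rec, "true_iaf")
  if (!is.null(attr(rec, "artifact_events")))
    sidecar$artifact_events <- attr(rec, "artifact_events")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  hdr_num <- function(w, field) {
    s <- rd(w)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop(sprintf("malformed EDF header field '%s': '%s'",
                               field, s))
    v
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_num(8, "header_bytes")
  rd(44)
  n_rec <- hdr_num(8, "n_records")
  rec_dur <- hdr_num(8, "record_duration")
  ns <- as.integer(hdr_num(4, "n_signals"))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- vapply(seq_len(ns), function(i) hdr_num(8, "phys_min"), numeric(1))
  pmaxv <- vapply(seq_len(ns), function(i) hdr_num(8, "phys_max"), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) hdr_num(8, "dig_min"), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) hdr_num(8, "dig_max"), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) hdr_num(8, "samples_per_record"),
                numeric(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  n <- as.integer(n_rec * spr[1])
  X <- matrix(NA_real_, ns, n, dimnames = list(labels, NULL))
  scale <- (pmaxv - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    blk <- matrix(raw, nrow = spr[1])     # column = signal
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    phys <- sweep(sweep(blk, 2, dmin, "-"), 2, scale, "*")
    X[, idx] <- t(sweep(phys, 2, pmin, "+"))
  }
  # unit conversion to microvolts
  to_uv <- ifelse(grepl("^mV$", units), 1e3,
           ifelse(grepl("^V$", units), 1e6, 1))
  X <- X * to_uv
  list(samples = X, sampling_rate = fs, labels = labels)
}

read_sidecar_blocks <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path)) return(NULL)
  jsonlite::read_json(sc_path, simplifyVector = TRUE)
}

#' Read a recording from EDF or BrainVision Core format
#'
#' EDF: the signals are read with units converted to microvolts; block
#' annotations are taken from the `<path>.json` sidecar written by
#' [write_recording()] (a missing sidecar gives an empty block table with
#' a warning). BrainVision: the `.vhdr`/`.vmrk`/`.eeg` triplet is read
#' (INT_16 or IEEE_FLOAT_32, multiplexed), with condition blocks parsed
#' from markers whose description matches `"OC_1"`, `"OA_3"`, ... and
#' whose length field gives the block duration in samples; unknown marker
#' labels are skipped with a warning.
#'
#' @param path File path (`.edf` or `.vhdr`).
#' @param format "EDF" or "BrainVision"; inferred from the extension by
#'   default.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "EDF", "BrainVision")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vhdr$", path, ignore.case = TRUE))
      "BrainVision" else "EDF"
  raw <- if (format == "EDF") read_edf(path) else read_brainvision(path)
  blocks <- if (format == "EDF") {
    sc <- read_sidecar_blocks(path)
    if (is.null(sc)) {
      warning("no annotation sidecar found; recording has no blocks")
      NULL
    } else {
      b <- as.data.frame(sc$blocks)
      if (nrow(b) == 0) NULL else b
    }
  } else raw$blocks
  rec <- recording(raw$samples, raw$sampling_rate, blocks = blocks)
  if (format == "EDF") {
    sc <- read_sidecar_blocks(path)
    if (!is.null(sc$true_iaf)) attr(rec, "true_iaf") <- sc$true_iaf
  }
  rec
}
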