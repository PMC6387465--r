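# BrainVision Core (.vhdr/.vmrk/.eeg) reader. Read-only: binary data in
# INT_16 or IEEE_FLOAT_32, multiplexed orientation.

parse_vhdr_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln) && !is.null(sec)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

read_brainvision <- function(path) {
  if (!file.exists(path)) stop("header file not found: ", path)
  hdr <- parse_vhdr_ini(readLines(path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("malformed BrainVision header: no [Common Infos]")
  need <- function(field, where = ci) {
    v <- where[[field]]
    if (is.null(v)) stop("malformed BrainVision header: missing ", field)
    v
  }
  n_ch <- as.integer(need("NumberOfChannels"))
  fs <- 1e6 / as.numeric(need("SamplingInterval"))  # microseconds
  orientation <- toupper(need("DataOrientation"))
  if (orientation != "MULTIPLEXED")
    stop("only MULTIPLEXED orientation is supported")
  bi <- hdr[["Binary Infos"]]
  fmt <- toupper(if (is.null(bi$BinaryFormat)) "INT_16" else bi$BinaryFormat)

  chs <- hdr[["Channel Infos"]]
  labels <- character(n_ch); resol <- rep(1, n_ch); units <- rep("uV", n_ch)
  for (i in seq_len(n_ch)) {
    entry <- chs[[paste0("Ch", i)]]
    if (is.null(entry)) stop("missing channel info for Ch", i)
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- trimws(parts[1])
    if (length(parts) >= 3 && nzchar(trimws(parts[3])))
      resol[i] <- as.numeric(parts[3])
    if (length(parts) >= 4 && nzchar(trimws(parts[4])))
      units[i] <- trimws(parts[4])
  }

  dir <- dirname(path)
  data_path <- file.path(dir, need("DataFile"))
  if (!file.exists(data_path))
    stop("BrainVision data file not found: ", data_path)
  sz <- file.size(data_path)
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (fmt == "INT_16") {
    raw <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
    X <- matrix(as.numeric(raw), nrow = n_ch) * resol
  } else if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
    X <- matrix(raw, nrow = n_ch) * resol
  } else stop("unsupported BinaryFormat: ", fmt)
  to_uv <- ifelse(units %in% c("mV"), 1e3, ifelse(units %in% c("V"), 1e6, 1))
  X <- X * to_uv
  rownames(X) <- labels

  blocks <- NULL
  mk_file <- ci$MarkerFile
  if (!is.null(mk_file) && file.exists(file.path(dir, mk_file))) {
    mk <- parse_vhdr_ini(readLines(file.path(dir, mk_file), warn = FALSE))
    mi <- mk[["Marker Infos"]]
    for (nm in names(mi)) {
      parts <- strsplit(mi[[nm]], ",", fixed = TRUE)[[1]]
      desc <- trimws(parts[2])
      if (grepl("^(OC|OA)_[0-9]+$", desc)) {
        cond_rep <- strsplit(desc, "_", fixed = TRUE)[[1]]
        pos <- as.numeric(parts[3]); len <- as.numeric(parts[4])
        blocks <- rbind(blocks, data.frame(
          condition = cond_rep[1],
          repetition = as.integer(cond_rep[2]),
          onset = (pos - 1) / fs, duration = len / fs))
      } else if (!desc %in% c("", "New Segment")) {
        warning("skipping unknown marker label: ", desc)
      }
    }
  }
  list(samples = X, sampling_rate = fs, labels = labels, blocks = blocks)
}
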