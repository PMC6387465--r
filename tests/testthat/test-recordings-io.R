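# Helper: write a BrainVision triplet (IEEE_FLOAT_32, multiplexed) in code.
write_brainvision_fixture <- function(dir, samples, fs, markers,
                                      base = "rec") {
  vhdr <- file.path(dir, paste0(base, ".vhdr"))
  n_ch <- nrow(samples)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / fs)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(n_ch), rownames(samples))), vhdr)
  writeLines(c(
    "[Common Infos]",
    "[Marker Infos]",
    sprintf("Mk%d=Stimulus,%s,%d,%d,0", seq_along(markers$desc),
            markers$desc, markers$pos, markers$len)),
    file.path(dir, paste0(base, ".vmrk")))
  con <- file(file.path(dir, paste0(base, ".eeg")), "wb")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  close(con)
  vhdr
}

test_that("EDF round trip is exact up to 16-bit quantization, with annotations", {
  cfg <- tiny_cfg(seed = 55)
  rec <- generate_subject(cfg, 1)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$channels$label, rec$channels$label)
  expect_equal(back$channels$role, rec$channels$role)
  # quantization bound: half an LSB of the declared physical range
  lsb <- (apply(abs(rec$samples), 1, max) * 1.0001) / 32767
  err <- apply(abs(back$samples - rec$samples), 1, max)
  expect_true(all(err <= lsb * 0.51 + 1e-9))
  expect_equal(back$blocks$condition, rec$blocks$condition)
  expect_equal(back$blocks$onset, rec$blocks$onset)
  expect_equal(attr(back, "true_iaf"), attr(rec, "true_iaf"))
})

test_that("EDF writer refuses empty input and encodes one signal per channel", {
  expect_error(write_recording(
    recording(matrix(numeric(0), 2, 0,
                     dimnames = list(c("Oz", "Pz"), NULL)), 250), "x.edf"),
    "empty")
  # full 43-channel montage yields 43 signals in the header
  mont <- default_montage()
  x <- matrix(stats::rnorm(nrow(mont) * 250), nrow(mont),
              dimnames = list(mont$label, NULL))
  rec <- recording(x, 250)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  con <- file(path, "rb")
  hdr <- readChar(con, 256, useBytes = TRUE)
  close(con)
  expect_equal(as.integer(trimws(substr(hdr, 253, 256))), 43)
  expect_equal(nrow(read_recording(path)$samples), 43)
})

test_that("a missing annotation sidecar degrades to an empty block table", {
  rec <- block_recording(2, samples = matrix(stats::rnorm(500), 1))
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  file.remove(paste0(path, ".json"))
  expect_warning(back <- read_recording(path), "sidecar")
  expect_equal(nrow(back$blocks), 0)
})

test_that("the written EDF is readable by an independent implementation", {
  cfg <- sim_config(n_subjects = 1, block_length = 4, n_repetitions = 1,
                    subject_iaf = 10, channels = c("Oz", "Neck4"), seed = 8)
  rec <- generate_subject(cfg, 1)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "probe.edf")
  write_recording(rec, path)
  script <- file.path(dir, "check.py")
  out_json <- file.path(dir, "out.json")
  writeLines(c(
    "import json, sys, warnings",
    "warnings.filterwarnings('ignore')",
    "import mne",
    "raw = mne.io.read_raw_edf(sys.argv[1], preload=True, verbose='ERROR')",
    "d = raw.get_data() * 1e6  # mne loads volts",
    "json.dump({'ch': raw.ch_names, 'sfreq': raw.info['sfreq'],",
    "           'n': int(d.shape[1]),",
    "           'x0': [float(v) for v in d[0, :10]]},",
    "          open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, path, out_json),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  ref <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_equal(ref$ch, c("Oz", "Neck4"))
  expect_equal(ref$sfreq, 250)
  expect_equal(ref$n, ncol(rec$samples))
  expect_equal(ref$x0, unname(rec$samples[1, 1:10]), tolerance = 1e-3)
})

test_that("BrainVision triplets are read with markers parsed into blocks", {
  fs <- 250
  set.seed(6)
  x <- matrix(stats::rnorm(2 * fs * 4), 2,
              dimnames = list(c("Oz", "Neck4"), NULL))
  dir <- withr::local_tempdir()
  vhdr <- write_brainvision_fixture(
    dir, x, fs, markers = list(desc = c("OC_1", "OA_1", "Bogus"),
                               pos = c(1, 501, 800), len = c(500, 500, 1)))
  expect_warning(rec <- read_recording(vhdr), "Bogus")
  expect_equal(rec$sampling_rate, fs)
  expect_equal(rec$channels$label, c("Oz", "Neck4"))
  expect_equal(rec$samples[1, ], x[1, ], tolerance = 1e-6)
  expect_equal(rec$blocks$condition, c("OC", "OA"))
  expect_equal(rec$blocks$onset, c(0, 2))
  expect_equal(rec$blocks$duration, c(2, 2))
  # missing binary file is a parse error
  file.remove(file.path(dir, "rec.eeg"))
  expect_error(read_recording(vhdr), "data file not found")
})

test_that("channel roles are inferred from both label spellings with overrides", {
  expect_equal(channel_role(c("Oz", "Neck3", "WrL1", "LWrist2", "RWrist4",
                              "WrR2", "Fp1")),
               c("EEG", "neck", "wrist", "wrist", "wrist", "wrist", "EEG"))
  expect_equal(channel_role("Nk1", override = c(Nk1 = "neck")), "neck")
  expect_error(channel_role("X", override = c(X = "leg")), "EEG/neck/wrist")
})

test_that("recording invariants are enforced", {
  x <- matrix(0, 2, 100, dimnames = list(c("Oz", "Oz"), NULL))
  expect_error(recording(x, 250), "unique")
  x2 <- matrix(c(0, Inf), 1, 2, dimnames = list("Oz", NULL))
  expect_error(recording(x2, 250), "finite")
  x3 <- matrix(0, 1, 250, dimnames = list("Oz", NULL))
  expect_error(recording(x3, 250, blocks = data.frame(
    condition = "OC", repetition = 1, onset = 0, duration = 10)),
    "within the recorded duration")
  expect_error(recording(x3, 250, blocks = data.frame(
    condition = c("OC", "OA"), repetition = c(1, 1),
    onset = c(0, 0.5), duration = c(0.8, 0.5))), "overlap")
})
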