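#!/usr/bin/env Rscript
# Correlate every EEG channel with every noEEG channel across the alpha
# bins (7.5-12.5 Hz) of the mean-OC spectra, per subject; keep the couples
# positive and significant (R > 0, p < 0.05) in ALL subjects (the common
# pattern); and tabulate the cross-subject mean IAF difference per couple
# with its category (equal / eeg_higher / eeg_lower / out_of_range).
# Zero-difference couples are the proxy candidates: noEEG sites whose IAF
# estimate is interchangeable with the paired EEG site's.

source("analysis/00_config.R")

means <- readRDS(file.path(CACHE_DIR, "condition_means.rds"))
iafs <- read.csv(file.path(TAB_DIR, "iaf_by_channel.csv"))

per_subject <- lapply(means$oc, couple_correlations, range = PIPE$range)
corr_tab <- do.call(rbind, lapply(seq_along(per_subject), function(s)
  cbind(subject = s, per_subject[[s]])))
write.csv(corr_tab, file.path(TAB_DIR, "correlations.csv"),
          row.names = FALSE)

pattern <- common_pattern(per_subject, PIPE$correlation_alpha)
write.csv(pattern, file.path(TAB_DIR, "common_pattern.csv"),
          row.names = FALSE)

map <- iaf_difference_map(pattern, iafs)
write.csv(map, file.path(TAB_DIR, "iaf_difference_map.csv"),
          row.names = FALSE)

message(sprintf(
  "%d of %d couples in the common pattern; %d with identical IAF (%s)",
  nrow(pattern), nrow(per_subject[[1]]),
  sum(map$category == "equal"),
  paste(unique(map$noeeg_channel[map$category == "equal"]),
        collapse = " ")))
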