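# Shared settings for the analysis scripts. The cohort is a six-subject
# synthetic study (12 in the emulated protocol; six keeps each script in
# the minutes range on one core) with the generator's default eyes-closed
# vs eyes-open contrast. All scripts are deterministic under MASTER_SEED.

library(neuroproxy)

MASTER_SEED <- 42L
N_SUBJECTS <- 6L

SIM <- sim_config(n_subjects = N_SUBJECTS, seed = MASTER_SEED)
PIPE <- pipeline_config(sim = SIM)

RESULTS <- "results"
REC_DIR <- file.path(RESULTS, "recordings")
TAB_DIR <- file.path(RESULTS, "tables")
CACHE_DIR <- file.path(RESULTS, "cache")
for (d in c(RESULTS, REC_DIR, TAB_DIR, CACHE_DIR))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)

subject_edf <- function(i) file.path(REC_DIR, sprintf("sub%02d.edf", i))
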