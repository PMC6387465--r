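#!/usr/bin/env Rscript
# Simulate the synthetic cohort and persist it as EDF files (one per
# subject, with a JSON sidecar carrying the OC/OA block annotations and
# the ground-truth IAF). The per-subject IAF draws are the reference
# against which the estimation scripts are judged.

source("analysis/00_config.R")

cohort <- generate_cohort(SIM)
truth <- data.frame(subject = seq_along(cohort),
                    true_iaf = attr(cohort, "true_iaf"))

for (i in seq_along(cohort)) {
  write_recording(cohort[[i]], subject_edf(i))
  message(sprintf("subject %d: true IAF %.2f Hz, blocks %s", i,
                  truth$true_iaf[i],
                  paste0(cohort[[i]]$blocks$condition, collapse = " ")))
}

write.csv(truth, file.path(TAB_DIR, "true_iaf.csv"), row.names = FALSE)
message(sprintf("wrote %d EDF recordings to %s; IAF range %.2f-%.2f Hz",
                length(cohort), REC_DIR, min(truth$true_iaf),
                max(truth$true_iaf)))
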