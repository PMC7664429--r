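#!/usr/bin/env Rscript
# Simulate the study-shaped cohort: 41 participants, EDA at 4 Hz over three
# marked exercises (60/10/10 s), paired 12-item JAWS responses, and latent
# two-class ground truth. Writes an E4-style directory tree that the rest
# of the workflow (and any external tool) can ingest.

library(edaffect)

cfg <- synth_config(seed = 1L)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cls <- table(as.integer(cohort$truth))
cat(sprintf("cohort: %d participants (%d low-arousal, %d high-arousal)\n",
            cfg$n_participants, cls["0"], cls["1"]))
cat(sprintf("each session: %.0f samples at %g Hz, markers at %s\n",
            length(cohort$sessions[[1]]$samples), cfg$fs,
            paste(round(cohort$sessions[[1]]$markers -
                        cohort$sessions[[1]]$start_time), collapse = ", ")))
cat("written to results/cohort/\n")
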