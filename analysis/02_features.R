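#!/usr/bin/env Rscript
# Segment every session at its begin/end markers, wavelet-denoise each
# segment (sym4, capped decomposition level), split tonic/phasic, detect
# GSR events on the phasic derivative, and assemble one participants x 26
# feature matrix per exercise.

library(edaffect)

cohort <- read_cohort("results/cohort")
feats <- session_features(cohort$sessions, default_config(seed = 1L))

for (ex in names(feats)) {
  write_feature_matrix(feats[[ex]], sprintf("results/features_%s.csv", ex))
  m <- feats[[ex]]
  cat(sprintf("%s: %d x %d matrix; mean GSR count %.2f, mean rpm %.2f\n",
              ex, nrow(m), ncol(m), mean(m[, "n_gsr"]), mean(m[, "rpm"])))
}
cat("feature matrices written to results/features_exercise_*.csv\n")
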