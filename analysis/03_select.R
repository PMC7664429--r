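#!/usr/bin/env Rscript
# Reduce each exercise's feature battery: drop features whose coefficient
# of variation is below 50%, then keep the 13 features with the smallest
# univariate two-cluster WCSS (the most class-separable ones).

library(edaffect)

cfg <- default_config(seed = 1L)
for (ex in c("exercise_1", "exercise_2", "exercise_3")) {
  m <- read_feature_matrix(sprintf("results/features_%s.csv", ex))
  sel <- select_features(m, cfg)
  jsonlite::write_json(sel[c("cv_report", "wcss_report")],
                       sprintf("results/selection_%s.json", ex),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  dropped_cv <- sum(!sel$cv_report$kept)
  cat(sprintf("%s: CV filter dropped %d of %d features; WCSS kept %d: %s\n",
              ex, dropped_cv, nrow(sel$cv_report), ncol(sel$matrix),
              paste(colnames(sel$matrix), collapse = ", ")))
}
cat("selection reports written to results/selection_exercise_*.json\n")
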