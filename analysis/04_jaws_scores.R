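#!/usr/bin/env Rscript
# Score the questionnaire: positive/negative subscale sums, reverse-coded
# totals, the 1-D two-means reference split of each scale, and the
# positivity (Losada) ratio of the cohort.

library(edaffect)

cohort <- read_cohort("results/cohort")
scores <- score_jaws_table(cohort$responses)
write.csv(scores, "results/jaws_scores.csv", row.names = FALSE, quote = FALSE)

for (scale in c("total", "pos", "neg")) {
  sc <- setNames(scores[[scale]], scores$participant_id)
  ref <- reference_labels(sc)
  write_labels_csv(ref$labels, sprintf("results/jaws_labels_%s.csv", scale))
  cat(sprintf("%-5s scale: mean %.2f (sd %.2f), two-means threshold %.1f, split %d/%d\n",
              scale, mean(sc), sd(sc), ref$threshold,
              sum(ref$labels == 1), sum(ref$labels == 0)))
}
cat(sprintf("positivity ratio (mean pos / mean neg): %.2f\n",
            positivity_ratio(mean(scores$pos), mean(scores$neg))))
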