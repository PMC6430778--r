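#!/usr/bin/env Rscript
# Test-retest reliability of the staging: percent agreement with one-stage
# offset counts, Cohen's kappa on the pooled stage ratings, and the Pearson
# correlation of the maturity scores across the two readings.
library(dentalage)

test <- read_cohort("results/retest_subsample.csv")
retest <- read_cohort("results/retest_rescored.csv")

rel <- reliability_report(test, retest, load_score_table())
cat(sprintf("items compared: %d stage ratings on %d radiographs\n",
            rel$n_items, nrow(test)))
cat(sprintf("percent agreement: %.2f%% (%d one stage ahead, %d behind)\n",
            rel$percent_agreement, rel$n_ahead, rel$n_behind))
cat(sprintf("Cohen's kappa: %.3f (p = %.2g)\n", rel$kappa, rel$kappa_p))
cat(sprintf("test-retest Pearson r on maturity scores: %.3f (p = %.2g)\n",
            rel$pearson_r, rel$pearson_p))

write.csv(rel$per_tooth, "results/reliability_per_tooth.csv", row.names = FALSE)
summary_row <- data.frame(n_items = rel$n_items,
                          percent_agreement = rel$percent_agreement,
                          n_ahead = rel$n_ahead, n_behind = rel$n_behind,
                          kappa = rel$kappa, kappa_p = rel$kappa_p,
                          pearson_r = rel$pearson_r, pearson_p = rel$pearson_p)
write.csv(summary_row, "results/reliability_summary.csv", row.names = FALSE)
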