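#!/usr/bin/env Rscript
# Score the seven left mandibular teeth (contralateral substitution where a
# left tooth is missing), sum the sex-specific stage scores into the dental
# maturity score, convert to estimated dental age, and apply the < 2.5-year
# exclusion used by the study.
library(dentalage)

cohort <- read_cohort("results/cohort.csv")
cohort$ca <- compute_chronological_age(cohort$dob, cohort$dor)

scored <- score_cohort(cohort, load_score_table())
cat(sprintf("scored %d of %d records (%d unscorable)\n",
            nrow(scored$cohort), nrow(cohort), nrow(scored$log)))

est <- estimate_cohort(scored$cohort, load_conversion_table(), policy = "clamp")
filt <- exclude_below_min_age(est, min_eda = 2.5)
cat(sprintf("excluded %d record(s) with estimated dental age < 2.5 years\n",
            nrow(filt$excluded)))

out <- filt$retained[c("child_id", "sex", "ca", "dms", "eda")]
write.csv(out, "results/estimates.csv", row.names = FALSE)
exclusions <- rbind(scored$log, filt$log)
write.csv(exclusions, "results/exclusions.csv", row.names = FALSE)
cat(sprintf("retained %d records -> results/estimates.csv\n", nrow(out)))
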