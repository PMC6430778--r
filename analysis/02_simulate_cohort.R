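#!/usr/bin/env Rscript
# Generate the default synthetic cohort: 160 children (74 male, 86 female)
# in yearly age groups 3 to <11 with the published group sizes and
# estimation-bias pattern, plus a perturbed retest scoring of a 20%
# subsample for the reliability analysis.
library(dentalage)
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = 20260922L)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort.csv")

counts <- table(group = as.character(assign_age_group(cohort$ca)), sex = cohort$sex)
cat("cohort written to results/cohort.csv\n")
print(counts)
cat(sprintf("totals: %d male, %d female, %d overall\n",
            sum(cohort$sex == "M"), sum(cohort$sex == "F"), nrow(cohort)))

retest_src <- select_retest_subsample(cohort, 0.20, seed = cfg$seed + 1L)
retest <- perturb_cohort_ratings(retest_src, cfg$rater_flip_rate,
                                 seed = cfg$seed + 2L)
write_cohort(retest_src, "results/retest_subsample.csv")
write_cohort(retest, "results/retest_rescored.csv")
cat(sprintf("retest subsample: %d radiographs re-scored\n", nrow(retest)))
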