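#!/usr/bin/env Rscript
# Study design: how many radiographs does the survey need?
# A finite source population of 420 archived radiographs, a 50% hypothesised
# proportion (the conservative maximum-variance choice), 5% absolute
# precision at 95% confidence, no clustering (DEFF 1).
library(dentalage)
dir.create("results", showWarnings = FALSE)

n_required <- required_sample_size(N = 420, p = 0.5, d = 0.05, Z = 1.96, deff = 1)
cat(sprintf("required sample size from N = 420: %d radiographs\n", n_required))
cat("(169 satisfied the selection criteria; 160 remained after exclusions)\n")

sensitivity <- do.call(rbind, lapply(c(0.03, 0.05, 0.10), function(d) {
  data.frame(d = d, n = required_sample_size(N = 420, p = 0.5, d = d))
}))
write.csv(sensitivity, "results/sample_size.csv", row.names = FALSE)
print(sensitivity)
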