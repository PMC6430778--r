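#!/usr/bin/env Rscript
# How well does the standard conversion estimate chronological age?
# Stratified comparison (mean difference EDA - CA with an independent
# samples t-test per age group and sex) and the bias-versus-age regression.
library(dentalage)

est <- read.csv("results/estimates.csv")

tab <- accuracy_table(est)
write.csv(tab, "results/accuracy_table.csv", row.names = FALSE)
cat("stratified accuracy (one row per age group and sex):\n")
print(tab[c("group", "sex", "n", "mean_diff", "p_value", "category")],
      digits = 3, row.names = FALSE)

for (sx in c("M", "F")) {
  sub <- est[est$sex == sx, ]
  fit <- bias_regression(sub$ca, sub$eda - sub$ca)
  cat(sprintf(
    "%s: overall bias %.4f (SD %.4f) years; drift %.4f years per year of age\n",
    c(M = "males", F = "females")[sx],
    fit$overall_mean_diff, fit$overall_sd, fit$slope))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(est, aes(ca, eda - ca)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    facet_wrap(~sex, labeller = labeller(sex = c(M = "males", F = "females"))) +
    labs(x = "chronological age (years)", y = "EDA - CA (years)",
         title = "Estimation bias against chronological age")
  ggsave("results/bias_vs_age.png", p, width = 8, height = 4, dpi = 150)
  cat("scatter written to results/bias_vs_age.png\n")
}
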