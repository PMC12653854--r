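#!/usr/bin/env Rscript
# Extrapolation of the stiripentol add-on regimen to infants and
# toddlers (6 months to 2 years): steady-state average concentrations
# per age group against the therapeutic reference windows.

suppressMessages(library(dravetpbpk))
dir.create("results", showWarnings = FALSE)

message("simulating five age groups (10 trials x 10 subjects each) ...")
pe <- suppressWarnings(pediatric_extrapolation(seed = 20250916))
write.csv(pe$by_age, "results/infant_cavg_by_age.csv", row.names = FALSE)
print(pe$by_age, digits = 3)

win <- therapeutic_windows()
cat("\nTherapeutic reference windows (mg/L):\n")
print(win)
cat("\nFindings:\n",
    "* Stiripentol C_avg decreases with age (higher per-kg capacity in\n",
    "  older children) and stays within the 4-25 mg/L effective window\n",
    "  in every group under the 50 mg/kg/day regimen with the 14 L/h\n",
    "  clearance anchor.\n",
    "* CLB and N-CLB averages sit above the lower therapeutic bounds\n",
    "  and far below the toxicity thresholds (3 and 12 mg/L).\n",
    "* N-CLB exposure is nearly flat across 6 mo-2 y in this\n",
    "  open-physiology implementation: under ~40-fold CYP2C19\n",
    "  inhibition, maturation of formation and of elimination cancel\n",
    "  (see the methods vignette for the sensitivity discussion).\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(pe$by_age, aes(factor(age_group), cavg_mean)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = cavg_mean - cavg_sd,
                      ymax = cavg_mean + cavg_sd), width = 0.2) +
    facet_wrap(~compound, scales = "free_y") +
    labs(x = "age group (years)",
         y = "steady-state C_avg (mg/L), mean +/- SD") +
    theme_bw()
  ggsave("results/infant_cavg_by_age.pdf", p, width = 8, height = 3.2)
}
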