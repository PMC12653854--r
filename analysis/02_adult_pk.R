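#!/usr/bin/env Rscript
# Adult pharmacokinetics: single- and multiple-dose clobazam with its
# metabolite, and the stiripentol dose ladder with regimen-dependent
# clearance, summarised by noncompartmental analysis.

suppressMessages(library(dravetpbpk))
dir.create("results", showWarnings = FALSE)

ref <- reference_adult()
clb <- builtin_clobazam()
nclb <- builtin_ndesmethylclobazam()
stp <- builtin_stiripentol()

## CLB 20 mg single dose (fasted) and 10 mg QD for 6 weeks
m <- assemble_model(list(clb, nclb), ref)
single <- simulate_pbpk(m, dose_regimen("CLB", dose_mg = 20,
                                        interval_h = 24,
                                        duration_days = 1),
                        t_end = 96, output_step = 0.25)
met_clb <- summary_metrics(single, "CLB", c(0, 96))
met_nclb <- summary_metrics(single, "NCLB", c(0, 96))
cat("CLB 20 mg single dose:",
    sprintf("Cmax %.3f mg/L at %.1f h, AUC0-96 %.2f mg*h/L, t1/2 %.1f h\n",
            met_clb$cmax, met_clb$tmax, met_clb$auc, met_clb$t_half))

multi <- simulate_pbpk(m, dose_regimen("CLB", dose_mg = 10,
                                       interval_h = 24,
                                       duration_days = 42),
                       t_end = 42 * 24, output_step = 1)
ss_clb <- summary_metrics(multi, "CLB", c(41, 42) * 24)
ss_nclb <- summary_metrics(multi, "NCLB", c(41, 42) * 24)
cat("CLB 10 mg QD steady state:",
    sprintf("CLB Cavg %.3f, N-CLB Cavg %.3f mg/L (ratio %.1f)\n",
            ss_clb$cavg, ss_nclb$cavg, ss_nclb$cavg / ss_clb$cavg))
cat("  (clinical steady-state metabolite:parent ratios run higher,\n",
    "   3-5; without a time-dependent reduction in N-CLB clearance\n",
    "   on chronic dosing the model under-predicts multiple-dose\n",
    "   N-CLB exposure - a known limitation of this parameterisation)\n")

## stiripentol single-dose ladder: fitted clearance anchors reproduce
## the more-than-proportional exposure increase
ladder <- lapply(c(300, 500, 1000, 2000), function(dose) {
  cl <- stp_clpo_for_regimen(dose_mg = dose, schedule = "single",
                             population = "adult")
  ms <- assemble_model(list(stp), ref, cl_override = list(STP = cl),
                       prandial = "fed")
  rs <- simulate_pbpk(ms, dose_regimen("STP", dose_mg = dose,
                                       interval_h = 24,
                                       duration_days = 1,
                                       prandial = "fed"),
                      t_end = 96, output_step = 0.25,
                      lag_by_compound = list(STP = 0.75))
  mt <- summary_metrics(rs, "STP", c(0, 96))
  data.frame(dose_mg = dose, cl_po_anchor = cl, cmax = mt$cmax,
             auc = mt$auc, auc_per_dose = mt$auc / dose)
})
ladder <- do.call(rbind, ladder)
write.csv(ladder, "results/stp_dose_ladder.csv", row.names = FALSE)
cat("\nSTP single-dose ladder (fed):\n")
print(ladder, digits = 3)
cat("\nDose-normalized AUC rises",
    sprintf("%.1f-fold from 300 to 2000 mg",
            ladder$auc_per_dose[4] / ladder$auc_per_dose[1]),
    "- the fitted-clearance representation of the non-linearity.\n")

tidy <- as_tidy_conc(single)
tidy$regimen <- "CLB 20 mg single"
write.csv(tidy, "results/adult_clb_single_profile.csv",
          row.names = FALSE)
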