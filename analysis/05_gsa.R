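#!/usr/bin/env Rscript
# Global sensitivity analysis of the CLB and STP models: Morris
# elementary-effects screening followed by Sobol variance-based
# indices on single-dose AUC(0-24 h) and Cmax in the reference adult.

suppressMessages(library(dravetpbpk))
dir.create("results", showWarnings = FALSE)

wc <- gsa_wrapper_clb()
ws <- gsa_wrapper_stp()
wc$spec$seed <- 41
ws$spec$seed <- 42

message("Morris screening (r = 20 trajectories, p = 4 levels) ...")
mo <- rbind(cbind(model = "CLB", morris_screen(wc$f, wc$spec)),
            cbind(model = "STP", morris_screen(ws$f, ws$spec)))
write.csv(mo, "results/gsa_morris.csv", row.names = FALSE)
print(mo[order(mo$model, mo$output, -mo$mu_star), ], digits = 3)

message("Sobol indices (Saltelli sampling, N = 1024) ...")
so <- rbind(cbind(model = "CLB", sobol_indices(wc$f, wc$spec)),
            cbind(model = "STP", sobol_indices(ws$f, ws$spec)))
write.csv(so, "results/gsa_sobol.csv", row.names = FALSE)
print(so[order(so$model, so$output, -so$st),
         c("model", "parameter", "output", "s1", "st")], digits = 2)

cat("\nInterpretation (0.1 total-effect threshold):\n",
    "* CLB AUC is driven by logP and fa (distribution-limited early\n",
    "  exposure and absorbed fraction), with fu,p and pKa moderate;\n",
    "  Cmax is less sensitive overall.\n",
    "* STP exposure is dominated by fa for both AUC and Cmax; ka and\n",
    "  the Kp scalar matter moderately for Cmax only and fall below\n",
    "  the threshold for AUC. fu,gut is inert (no gut-wall\n",
    "  metabolism in the model).\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p1 <- ggplot(mo, aes(reorder(parameter, mu_star), mu_star)) +
    geom_col(fill = "grey40") + coord_flip() +
    facet_grid(model ~ output, scales = "free") +
    labs(x = NULL, y = "Morris mu* (unit-cube scale)") + theme_bw()
  ggsave("results/gsa_morris.pdf", p1, width = 7, height = 5)
  so_long <- rbind(
    transform(so, index = "S1", value = s1, lo = s1_lo, hi = s1_hi),
    transform(so, index = "ST", value = st, lo = st_lo, hi = st_hi))
  p2 <- ggplot(so_long, aes(parameter, value, fill = index)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 0.1, linetype = 2) +
    facet_grid(model ~ output, scales = "free_x") +
    labs(x = NULL, y = "Sobol index") + theme_bw()
  ggsave("results/gsa_sobol.pdf", p2, width = 7, height = 5)
}
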