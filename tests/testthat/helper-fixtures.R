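# shared fixtures: cheap cached objects reused across test files
ref_adult <- reference_adult()
clb <- builtin_clobazam()
nclb <- builtin_ndesmethylclobazam()
stp <- builtin_stiripentol()

# small STICLO-style design for engine-level tests (2 subjects)
tiny_sticlo <- function(seed = 42, phenotype = "EM", n = 2) {
  ddi_preset("sticlo", phenotype = phenotype, seed = seed,
             n_trials = 1, n_subjects = n)
}

# trapezoid AUC on a simulation result column
sim_auc <- function(res, compound, from = 0, to = Inf) {
  sel <- res$time >= from & res$time <= to
  auc_trapezoid(res$time[sel], res$conc[sel, compound], method = "linear")
}
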