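# one-compartment limit fixture: all Kp forced to 1, B/P = 1, fu,p = 1,
# single systemic clearance -> the whole body behaves as one mixing
# volume V = sum of all compartment volumes
onecmp_compound <- function(cl = 2, ka = 1) {
  compound_model("OC", mw = 100, logp = 0, type = "neutral", bp = 1,
                 fup = 1, fa = 1, ka = ka, cl_renal = cl)
}

onecmp_model <- function(cl = 2, ka = 1) {
  cp <- onecmp_compound(cl, ka)
  kp1 <- structure(list(kp = setNames(rep(1, 12), PBPK_TISSUES),
                        scalar = 1, bp = 1, compound = "OC"),
                   class = "KpSet")
  # lump the flows (x10) so that whole-body mixing is fast relative to
  # elimination and the one-compartment closed form applies
  lumped <- ref_adult
  lumped$flows <- lumped$flows * 10
  lumped$cardiac_output <- lumped$cardiac_output * 10
  assemble_model(list(cp), lumped, kp_sets = list(OC = kp1))
}

onecmp_volume <- function() {
  sum(ref_adult$volumes)
}

test_that("no doses gives an all-zero trajectory", {
  m <- onecmp_model()
  res <- simulate_pbpk(m, list(), t_end = 24, output_step = 1)
  expect_true(all(res$conc == 0))
})

test_that("the one-compartment limit matches the closed-form oral
          solution", {
  cl <- 2; ka <- 1; dose <- 100
  m <- onecmp_model(cl, ka)
  res <- simulate_pbpk(m, dose_regimen("OC", dose_mg = dose,
                                       interval_h = 24,
                                       duration_days = 1),
                       t_end = 120, output_step = 0.5)
  V <- onecmp_volume()
  ke <- cl / V
  analytic <- dose * ka / (V * (ka - ke)) *
    (exp(-ke * res$time) - exp(-ka * res$time))
  # after early distribution transients the profile tracks the
  # closed form within 2%
  late <- res$time >= 6
  expect_lt(max(abs(res$conc[late, "OC"] - analytic[late]) /
                  analytic[late]), 0.02)
  # AUC to 120 h within 2% of the analytic value
  a_num <- sim_auc(res, "OC")
  a_ana <- dose / cl * (1 - exp(-ke * 120))
  expect_equal(a_num, a_ana, tolerance = 0.02)
})

test_that("steady-state average concentration matches F Dose / (CL tau)
          within 3%", {
  cl <- 2
  m <- onecmp_model(cl)
  res <- simulate_pbpk(m, dose_regimen("OC", dose_mg = 50,
                                       interval_h = 24,
                                       duration_days = 60),
                       t_end = 60 * 24, output_step = 0.5)
  met <- summary_metrics(res, "OC", c(59, 60) * 24)
  expect_equal(met$cavg, 50 / (cl * 24), tolerance = 0.03)
})

test_that("a parent with a full metabolite link conserves moles", {
  parent <- compound_model("P", mw = 300, logp = 1, type = "neutral",
                           bp = 1, fup = 0.5, fa = 1, ka = 1,
                           cl_hepatic_plasma = 2,
                           pathways = c(CYP3A4 = 1),
                           metabolite = "M", metabolite_fraction = 1)
  met <- compound_model("M", mw = 150, logp = 1, type = "neutral",
                        bp = 1, fup = 0.5, fa = 1, ka = 1,
                        cl_renal = 1)
  m <- assemble_model(list(parent, met), ref_adult)
  res <- simulate_pbpk(m, dose_regimen("P", dose_mg = 100,
                                       interval_h = 24,
                                       duration_days = 1),
                       t_end = 96, output_step = 1, keep_states = TRUE)
  st <- res$states
  # parent has no other losses, so parent moles eliminated equal
  # metabolite moles formed at every output time
  expect_equal(st[, "M_formed"] / 150, st[, "P_elim"] / 300,
               tolerance = 1e-6)
  mb <- mass_balance(res)
  expect_true(all(mb < 1e-4))
})

test_that("clobazam exposure is dose-proportional within 1%", {
  run <- function(dose) {
    m <- assemble_model(list(clb, nclb), ref_adult)
    simulate_pbpk(m, dose_regimen("CLB", dose_mg = dose,
                                  interval_h = 24, duration_days = 1),
                  t_end = 96, output_step = 0.5)
  }
  r10 <- run(10); r20 <- run(20)
  expect_equal(sim_auc(r20, "CLB") / sim_auc(r10, "CLB"), 2,
               tolerance = 0.01)
  expect_equal(sim_auc(r20, "NCLB") / sim_auc(r10, "NCLB"), 2,
               tolerance = 0.01)
})

test_that("mass balance closes and states stay non-negative on a
          multi-dose DDI run", {
  ped <- scale_to_age(ref_adult, 8, "male")
  m <- assemble_model(list(clb, nclb, stp), ped,
                      cl_override = list(STP = 8),
                      prandial = c(CLB = "fasted", NCLB = "fasted",
                                   STP = "fed"))
  regs <- list(
    dose_regimen("CLB", dose_mg_per_kg = 0.5, interval_h = 24,
                 duration_days = 14),
    dose_regimen("STP", dose_mg_per_kg = 25, interval_h = 12,
                 start_h = 7 * 24, duration_days = 7, prandial = "fed"))
  res <- suppressWarnings(
    simulate_pbpk(m, regs, t_end = 14 * 24, output_step = 1,
                  lag_by_compound = list(STP = 0.75),
                  keep_states = TRUE))
  mb <- mass_balance(res)
  expect_true(all(mb < 1e-4))
  expect_true(all(res$states[, -1] > -1e-6))
  expect_true(all(diff(res$time) > 0))
})

test_that("removing the perpetrator regimen reproduces the baseline
          victim trajectories", {
  ped <- scale_to_age(ref_adult, 8, "male")
  mk <- function(cps) {
    assemble_model(cps, ped, cl_override = list(STP = 8),
                   prandial = c(CLB = "fasted", NCLB = "fasted",
                                STP = "fed"))
  }
  reg <- dose_regimen("CLB", dose_mg_per_kg = 0.5, interval_h = 24,
                      duration_days = 7)
  r3 <- simulate_pbpk(mk(list(clb, nclb, stp)), list(reg),
                      t_end = 7 * 24, output_step = 1)
  r2 <- simulate_pbpk(mk(list(clb, nclb)), list(reg),
                      t_end = 7 * 24, output_step = 1)
  expect_equal(r3$conc[, "CLB"], r2$conc[, "CLB"], tolerance = 1e-6)
  expect_equal(r3$conc[, "NCLB"], r2$conc[, "NCLB"], tolerance = 1e-6)
  expect_true(all(r3$conc[, "STP"] == 0))
})

test_that("N-desmethylclobazam accumulates to steady state over weeks", {
  m <- assemble_model(list(clb, nclb), ref_adult)
  troughs <- c(21, 42, 60) * 24 - 0.5
  res <- simulate_pbpk(m, dose_regimen("CLB", dose_mg = 10,
                                       interval_h = 24,
                                       duration_days = 60),
                       t_end = 60 * 24, output_step = 6,
                       extra_times = troughs)
  at <- function(t) res$conc[which.min(abs(res$time - t)), "NCLB"]
  # by day 21 the trough is at >= 90% of the day-42 trough, and the
  # day-42 trough is within 10% of the plateau
  expect_gte(at(troughs[1]), 0.9 * at(troughs[2]))
  expect_gte(at(troughs[2]), 0.9 * at(troughs[3]))
})
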