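test_that("a 1x1 trial set reproduces that subject's metrics and fixed
          seeds reproduce exactly", {
  des <- ddi_preset("sticlo", phenotype = "EM", seed = 5,
                    n_trials = 1, n_subjects = 1)
  des$duration_days <- 14
  des$regimens <- list(dose_regimen("CLB", dose_mg_per_kg = 0.5,
                                    interval_h = 24, duration_days = 14))
  ts1 <- run_trial_set(des)
  ts2 <- run_trial_set(des)
  expect_identical(ts1$subjects, ts2$subjects)
  clb_row <- ts1$subjects[ts1$subjects$compound == "CLB", ]
  expect_equal(nrow(clb_row), 1)
  expect_equal(ts1$summary$cavg_mean[ts1$summary$compound == "CLB"],
               clb_row$cavg)
  expect_true(is.na(ts1$summary$cavg_sd[1]) ||
                ts1$summary$cavg_sd[1] == 0)
})

test_that("a non-inhibiting perpetrator leaves troughs unchanged", {
  des <- tiny_sticlo(seed = 21, n = 2)
  des$duration_days <- 28
  des$baseline_days <- 14
  des$regimens[[1]]$duration_days <- 28
  des$regimens[[2]]$start_h <- 14 * 24
  des$regimens[[2]]$duration_days <- 14
  # push every ki far above any attainable liver exposure
  idx <- which(vapply(des$compounds, `[[`, character(1), "name") == "STP")
  des$compounds[[idx]]$inhibition[] <- 1e9
  dd <- suppressWarnings(run_ddi_study(des))
  expect_true(all(abs(dd$subjects$cmin_ratio - 1) < 0.02))
})

test_that("phenotype drives the N-desmethylclobazam asymmetry", {
  em <- suppressWarnings(run_ddi_study(local({
    d <- tiny_sticlo(seed = 33, phenotype = "EM", n = 8)
    d$duration_days <- 56; d$baseline_days <- 28
    d$regimens[[2]]$duration_days <- 28
    d
  })))
  pm <- suppressWarnings(run_ddi_study(local({
    d <- tiny_sticlo(seed = 33, phenotype = "PM", n = 2)
    d$duration_days <- 56; d$baseline_days <- 28
    d$regimens[[2]]$duration_days <- 28
    d
  })))
  em_n <- em$subjects[em$subjects$compound == "NCLB", ]
  pm_n <- pm$subjects[pm$subjects$compound == "NCLB", ]
  # poor metabolizers run far higher baseline N-CLB troughs
  expect_gt(mean(pm_n$cmin_control), 3 * mean(em_n$cmin_control))
  # inhibition raises N-CLB in EMs and does not raise it in PMs
  expect_gt(mean(em_n$cmin_ratio), 2)
  expect_lt(mean(pm_n$cmin_ratio), 1.05)
  # within-subject pairing: the paired ratio varies less (on the log
  # scale) than ratios formed across mismatched subjects
  lp <- log(em_n$cmin_ratio)
  shifted <- c(em_n$cmin_control[-1], em_n$cmin_control[1])
  lx <- log(em_n$cmin_inh / shifted)
  expect_lt(var(lp), var(lx))
})

test_that("pediatric extrapolation returns windows and group summaries", {
  pe <- suppressWarnings(
    pediatric_extrapolation(ages = c(0.5, 2), seed = 2, n_trials = 1,
                            n_subjects = 2, duration_days = 42))
  expect_setequal(unique(pe$by_age$compound), c("CLB", "NCLB", "STP"))
  stp_rows <- pe$by_age[pe$by_age$compound == "STP", ]
  expect_true(all(stp_rows$cavg_mean > 0))
  expect_true(all(c("within_window", "above_toxic") %in%
                    names(pe$by_age)))
  expect_error(pediatric_extrapolation(ages = 0.1, seed = 1),
               "unsupported age")
})

test_that("the nearest stiripentol clearance anchor follows the study
          mean age", {
  des <- ddi_preset("sticlo", phenotype = "EM", seed = 1)
  expect_equal(des$cl_override$STP, 8)
  pe_anchor <- stp_clpo_for_regimen(population = "pediatric", age = 2)
  expect_equal(pe_anchor, 14)
})
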