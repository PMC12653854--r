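test_that("zero-CV synthetic data equals the model prediction and noisy
          replicates are mean-unbiased", {
  sched <- c(0.5, 1, 2, 4, 8, 12, 24, 48)
  spec0 <- synthetic_spec("CLB", dose_mg = 20, duration_days = 1,
                          schedule = sched, cv = 0, seed = 4)
  d0 <- synth_profile(spec0)
  expect_equal(d0$conc_mg_per_L, d0$conc_true)
  # law of large numbers: the mean of 500 noisy replicates tracks the
  # truth within 2% at every time point
  specN <- synthetic_spec("CLB", dose_mg = 20, duration_days = 1,
                          schedule = sched, cv = 0.15,
                          n_replicates = 500, seed = 4)
  dN <- synth_profile(specN)
  m <- tapply(dN$conc_mg_per_L, dN$time_h, mean)
  expect_equal(as.numeric(m[as.character(sched)]),
               d0$conc_true, tolerance = 0.02)
  # reproducible from (spec, seed)
  expect_identical(synth_profile(specN), dN)
})

test_that("the stiripentol dose ladder shows a more-than-proportional
          exposure increase", {
  sched <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 24, 36, 48)
  auc_dn <- vapply(c(300, 1000, 2000), function(dose) {
    cl <- stp_clpo_for_regimen(dose_mg = dose, schedule = "single",
                               population = "adult")
    d <- synth_profile(synthetic_spec("STP", dose_mg = dose,
                                      duration_days = 1,
                                      schedule = sched, cv = 0,
                                      prandial = "fed", cl_po = cl,
                                      seed = 1))
    auc_trapezoid(d$time_h, d$conc_true) / dose
  }, numeric(1))
  expect_true(all(diff(auc_dn) > 0))
})

test_that("synthetic trough studies carry phenotype labels and ground
          truth", {
  des <- tiny_sticlo(seed = 12, phenotype = "PM", n = 2)
  des$duration_days <- 42
  des$baseline_days <- 28
  des$regimens[[1]]$duration_days <- 42
  des$regimens[[2]]$duration_days <- 14
  tr <- suppressWarnings(synth_trough_study(des, assay_cv = 0, seed = 9))
  expect_setequal(unique(tr$phase), c("baseline", "coadministration"))
  expect_true(all(tr$phenotype == "PM"))
  expect_equal(tr$trough_mg_per_L, tr$trough_true)
})

test_that("the fixture pack is manifest-complete and byte-identical on
          regeneration", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- suppressWarnings(fixture_suite(d1, seed = 123,
                                       n_trough_subjects = 2))
  m2 <- suppressWarnings(fixture_suite(d2, seed = 123,
                                       n_trough_subjects = 2))
  expect_true(all(file.exists(file.path(d1, m1$file))))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_identical(m1$md5, m2$md5)
  # checksums in the manifest match the files on disk
  expect_identical(unname(tools::md5sum(file.path(d1, m1$file))), m1$md5)
})
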