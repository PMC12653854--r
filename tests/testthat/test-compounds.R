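test_that("clobazam parameter set matches its published table", {
  expect_equal(clb$fa, 0.93)
  expect_equal(clb$mw, 300.74)
  expect_equal(unname(clb$ka["fasted"]), 2.11)
  expect_equal(unname(clb$ka["fed"]), 1.25)
  # enzymatic + additional + renal clearance partition
  expect_equal(clb$cl_hepatic_plasma, 1.4)
  expect_equal(clb$cl_additional, 0.6)
  expect_equal(clb$cl_renal, 0.05)
  expect_equal(sum(clb$pathways), 1.0)
  expect_equal(unname(clb$pathways[c("CYP3A4", "CYP2C19", "CYP2B6")]),
               c(0.70, 0.19, 0.11))
  expect_identical(clb$metabolite, "NCLB")
  expect_equal(clb$metabolite_fraction, 1.0)
})

test_that("N-desmethylclobazam is a pure CYP2C19 substrate", {
  expect_equal(names(nclb$pathways), "CYP2C19")
  expect_equal(unname(nclb$pathways), 1)
  expect_equal(nclb$kp_scalar, 0.8)
  expect_equal(nclb$cl_renal, 0.08)
  expect_equal(nclb$cl_hepatic_plasma, 1.09)
})

test_that("stiripentol fm and ki tables match the published set", {
  expect_equal(stp$inhibition[["CYP2C19"]], 0.0139)
  expect_equal(sum(stp$pathways), 0.755, tolerance = 1e-9)
  # residual non-enzyme-specific fraction
  expect_equal(1 - sum(stp$pathways), 0.245, tolerance = 1e-9)
  expect_equal(stp$fugut, stp$fup)
  expect_equal(stp$fup, 0.01)
  expect_equal(stp$fa, 0.82)
  expect_equal(stp$kp_scalar, 4.2)
  # transporters are inert metadata, not inhibition pathways
  expect_false(any(c("Pgp", "BCRP") %in% names(stp$inhibition)))
})

test_that("regimen-dependent stiripentol clearance follows the anchors", {
  expect_equal(stp_clpo_for_regimen(600, "single", population = "adult"), 60)
  expect_equal(stp_clpo_for_regimen(300, "single", population = "adult"), 70)
  expect_equal(stp_clpo_for_regimen(1000, "single", population = "adult"), 35)
  expect_equal(stp_clpo_for_regimen(2000, "single", population = "adult"), 25)
  expect_equal(stp_clpo_for_regimen(schedule = "multiple",
                                    daily_dose_mg = 1500,
                                    population = "adult"), 17)
  expect_equal(stp_clpo_for_regimen(schedule = "multiple",
                                    daily_dose_mg = 3000,
                                    population = "adult"), 8)
  expect_equal(stp_clpo_for_regimen(population = "pediatric", age = 4), 14)
  expect_equal(stp_clpo_for_regimen(population = "pediatric", age = 13), 8)
  expect_error(stp_clpo_for_regimen(-5, "single", population = "adult"),
               "dose")
  # monotone non-increasing over the single-dose anchor set
  doses <- c(300, 500, 600, 1000, 1200, 2000)
  cls <- vapply(doses, stp_clpo_for_regimen, numeric(1),
                schedule = "single", population = "adult")
  expect_true(all(diff(cls) <= 0))
})

test_that("compound config round-trips losslessly and validation rejects
          bad inputs", {
  for (cp in list(clb, nclb, stp)) {
    path <- withr::local_tempfile(fileext = ".yaml")
    compound_to_config(cp, path)
    back <- compound_from_config(path)
    expect_equal(back, cp, tolerance = 1e-12)
  }
  expect_error(compound_model("X", mw = 100, logp = 1, type = "neutral",
                              bp = 1, fup = 0.5, fa = 1.2, ka = 1),
               "fa")
  expect_error(compound_model("X", mw = 100, logp = 1, type = "neutral",
                              bp = 1, fup = 0.5, fa = 0.5, ka = 1,
                              pathways = c(CYP3A4 = 0.8, CYP2C19 = 0.5)),
               "sum")
  expect_error(compound_model("X", mw = 100, logp = 1, type = "neutral",
                              bp = 1, fup = 0.5, fa = 0.5, ka = 1,
                              inhibition = c(CYP3A4 = -2)),
               "ki")
})
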