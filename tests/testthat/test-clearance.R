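test_that("blood unbound fraction conversion is exact arithmetic", {
  expect_equal(fu_blood(0.1, 0.69), 0.1 / 0.69)
  expect_equal(fu_blood(1, 1), 1)
  expect_equal(fu_blood(0.01, 0.58), 0.0172414, tolerance = 1e-5)
})

test_that("well-stirred model respects its asymptotes and round-trips", {
  qh <- hepatic_blood_flow(ref_adult)
  # flow limit: huge intrinsic clearance -> blood clearance -> Qh
  expect_equal(well_stirred_forward(1e9, 0.1, 0.69, qh) / 0.69, qh,
               tolerance = 1e-3)
  # restrictive limit: small CLint -> CL ~ fu_B x CLint
  small <- well_stirred_forward(0.01, 0.1, 0.69, qh)
  expect_equal(small, fu_blood(0.1, 0.69) * 0.01 * 0.69,
               tolerance = 1e-3)
  expect_equal(well_stirred_back_calc(0, 0.1, 0.69, qh), 0)
  # near the flow limit the back-calculated CLint explodes
  cl99 <- 0.99 * qh * 0.69
  expect_gt(well_stirred_back_calc(cl99, 0.1, 0.69, qh),
            50 * qh / fu_blood(0.1, 0.69))
  expect_error(well_stirred_back_calc(qh * 0.69 * 1.01, 0.1, 0.69, qh),
               "exceeds hepatic blood flow")
  # property: back_calc o forward = identity over random inputs
  set.seed(1)
  for (i in 1:50) {
    clint <- runif(1, 0.01, 5000)
    fup <- runif(1, 0.01, 1)
    bp <- runif(1, 0.5, 2)
    cl <- well_stirred_forward(clint, fup, bp, qh)
    expect_equal(well_stirred_back_calc(cl, fup, bp, qh), clint,
                 tolerance = 1e-8)
  }
})

test_that("published plasma clearances round-trip through the liver
          model", {
  qh <- hepatic_blood_flow(ref_adult)
  for (case in list(list(cl = 2, fup = 0.1, bp = 0.69),
                    list(cl = 1.4, fup = 0.1, bp = 0.69),
                    list(cl = 1.09, fup = 0.11, bp = 0.69))) {
    clint <- well_stirred_back_calc(case$cl, case$fup, case$bp, qh)
    expect_gt(clint, 0)
    expect_equal(well_stirred_forward(clint, case$fup, case$bp, qh),
                 case$cl, tolerance = 1e-6)
  }
})

test_that("fm splitting conserves clearance and flags the residual", {
  sp <- split_clint_by_fm(10, clb$pathways)
  expect_equal(unname(sp$clint), 10 * c(0.70, 0.19, 0.11))
  expect_equal(sp$residual, 0)
  single <- split_clint_by_fm(5, c(CYP2C19 = 1))
  expect_equal(unname(single$clint), 5)
  stp_split <- split_clint_by_fm(100, stp$pathways)
  expect_equal(stp_split$residual, 24.5, tolerance = 1e-9)
  expect_error(split_clint_by_fm(1, c(CYP3A4 = 0.8, CYP2C19 = 0.5)),
               "sum")
})

test_that("per-pmol conversion round-trips and scales with abundance", {
  per <- clint_per_pmol(10, "CYP3A4", ref_adult)
  total <- total_hepatic_cyp(ref_adult, "CYP3A4")
  expect_equal(per * total * 60 / 1e6, 10, tolerance = 1e-12)
  half <- ref_adult
  half$cyp_abundance[["CYP3A4"]] <- half$cyp_abundance[["CYP3A4"]] * 2
  expect_equal(clint_per_pmol(10, "CYP3A4", half), per / 2)
  # the printed CYP2C19 per-pmol value is order-of-magnitude only
  rc <- reference_clint(clb, ref_adult)
  per19 <- clint_per_pmol(rc$clint[["CYP2C19"]], "CYP2C19", ref_adult)
  expect_gt(per19, 0.173 / 10)
  expect_lt(per19, 0.173 * 10)
  null <- ref_adult
  null$cyp_multiplier[["CYP2C19"]] <- 0
  expect_error(clint_per_pmol(1, "CYP2C19", null), "phenotype-null")
  expect_true(is.na(clint_per_pmol(1, "CYP2C19", null,
                                   allow_null = TRUE)))
})

test_that("effective clearance combines ontogeny, phenotype and
          inhibition multiplicatively", {
  rc <- reference_clint(nclb, ref_adult)
  base <- effective_clint(clearance_context(ref_adult, nclb), rc,
                          ref_adult)
  expect_equal(unname(base$clint[["CYP2C19"]]),
               unname(rc$clint[["CYP2C19"]]))
  # I_u = ki halves the inhibited pathway
  ctx <- clearance_context(ref_adult, nclb,
                           inhibitor_conc_um = c(CYP2C19 = 0.0139),
                           ki_um = stp$inhibition)
  inh <- effective_clint(ctx, rc, ref_adult)
  expect_equal(unname(inh$clint[["CYP2C19"]] / base$clint[["CYP2C19"]]),
               0.5, tolerance = 1e-9)
  # inhibition factor monotone decreasing in I_u
  ius <- c(0, 0.01, 0.1, 1)
  facs <- vapply(ius, function(iu) {
    inhibition_factors("CYP2C19", c(CYP2C19 = iu), stp$inhibition)
  }, numeric(1))
  expect_true(all(diff(facs) < 0))
  # PM phenotype nulls the CYP2C19 pathway
  pm <- ref_adult
  pm$phenotype <- "PM"
  pm$cyp_multiplier[["CYP2C19"]] <- 0
  eff_pm <- effective_clint(clearance_context(pm, nclb), rc, ref_adult)
  expect_equal(unname(eff_pm$clint[["CYP2C19"]]), 0)
  expect_error(clearance_context(ref_adult, nclb,
                                 inhibitor_conc_um = c(CYP2C19 = -1)),
               ">= 0")
})

test_that("at clinical stiripentol exposure CYP2C19 is inhibited far
          more than CYP3A4", {
  iu <- c(CYP2C19 = 0.5, CYP3A4 = 0.5)  # uM unbound liver exposure
  facs <- inhibition_factors(c("CYP2C19", "CYP3A4"), iu, stp$inhibition)
  expect_lt(facs[["CYP2C19"]], 0.05)
  expect_gt(facs[["CYP3A4"]], 0.7)
})
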