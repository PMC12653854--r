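test_that("reference adult is deterministic with literature-scale values", {
  expect_identical(ref_adult, reference_adult())
  qh <- hepatic_blood_flow(ref_adult)
  expect_gt(qh, 80)
  expect_lt(qh, 100)
  expect_gt(ref_adult$liver_mass_g, 1400)
  expect_lt(ref_adult$liver_mass_g, 1800)
  # total hepatic CYP3A4 amount is the closed arithmetic product
  expect_equal(total_hepatic_cyp(ref_adult, "CYP3A4"),
               ref_adult$cyp_abundance[["CYP3A4"]] * ref_adult$mppgl *
                 ref_adult$liver_mass_g)
  # flows close through the lung: venous return equals cardiac output
  expect_equal(sum(ref_adult$flows), ref_adult$cardiac_output)
})

test_that("ontogeny fractions are sane across isoforms", {
  expect_equal(ontogeny_fraction("CYP2C19", 0), 0.3, tolerance = 1e-6)
  for (iso in c("CYP1A2", "CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6",
                "CYP3A4")) {
    expect_equal(ontogeny_fraction(iso, 25), 1, tolerance = 0.01)
    expect_lte(ontogeny_fraction(iso, 0), ontogeny_fraction(iso, 25))
    fr <- ontogeny_fraction(iso, seq(0, 25, by = 0.5))
    expect_true(all(fr > 0 & fr <= 2))
  }
  # CYP2C19 maturation is monotone over the first two years
  grid <- ontogeny_fraction("CYP2C19", seq(0, 2, by = 0.05))
  expect_true(all(diff(grid) >= -1e-12))
  expect_error(ontogeny_fraction("CYP9Z9", 1), "supported")
  expect_error(ontogeny_fraction("CYP3A4", -1), "age")
})

test_that("age scaling is the identity at adulthood and isoform-specific
          below it", {
  at25 <- scale_to_age(ref_adult, 25, "male")
  expect_equal(at25$body_weight_kg, ref_adult$body_weight_kg,
               tolerance = 0.01)
  expect_equal(at25$volumes, ref_adult$volumes, tolerance = 0.01)
  expect_equal(at25$flows, ref_adult$flows, tolerance = 0.01)
  expect_equal(at25$cyp_abundance, ref_adult$cyp_abundance,
               tolerance = 0.01)

  at1 <- scale_to_age(ref_adult, 1, "male")
  expect_equal(at1$body_weight_kg, weight_for_age(1, "male"))
  # isoform-specific maturation is not pure size scaling: the CYP2C19
  # abundance fraction at 6 months is below the body-size fraction of
  # a size-scaled quantity like blood volume
  at05 <- scale_to_age(ref_adult, 0.5, "male")
  size_frac <- at05$volumes[["venous_blood"]] /
    ref_adult$volumes[["venous_blood"]]
  cyp_frac <- at05$cyp_abundance[["CYP2C19"]] /
    ref_adult$cyp_abundance[["CYP2C19"]]
  expect_lt(cyp_frac * 0 + ontogeny_fraction("CYP2C19", 0.5), 1)
  expect_false(isTRUE(all.equal(cyp_frac, size_frac, tolerance = 0.05)))
  expect_error(scale_to_age(ref_adult, 0.2), "range")
  expect_error(scale_to_age(ref_adult, 30), "range")
})

test_that("population sampling is reproducible and respects phenotype
          frequencies", {
  spec <- population_spec(n_trials = 2, n_subjects = 3,
                          age_range = c(3, 16), pm_frequency = 0,
                          seed = 9)
  p1 <- sample_population(spec)
  p2 <- sample_population(spec)
  expect_identical(p1, p2)
  expect_length(p1, 6)
  expect_true(all(vapply(p1, `[[`, character(1), "phenotype") == "EM"))
  expect_equal(vapply(p1, `[[`, integer(1), "trial"),
               rep(1:2, each = 3))

  # binomial check on the PM frequency
  big <- population_spec(n_trials = 1, n_subjects = 2000,
                         age_range = c(5, 15), pm_frequency = 0.19,
                         seed = 4)
  pb <- sample_population(big)
  pm_frac <- mean(vapply(pb, `[[`, character(1), "phenotype") == "PM")
  expect_lt(abs(pm_frac - 0.19), 0.02)
  # PM subjects carry a null CYP2C19 multiplier by default
  pm_mult <- vapply(pb, function(s) s$cyp_multiplier[["CYP2C19"]],
                    numeric(1))
  expect_true(all(pm_mult[vapply(pb, `[[`, character(1),
                                 "phenotype") == "PM"] == 0))
  expect_error(population_spec(n_trials = 1, n_subjects = 1),
               "seed")
})
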