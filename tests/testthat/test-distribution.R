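test_that("predicted distribution volumes sit near the published
          anchors", {
  v_stp <- compute_vss(predict_kp(stp), ref_adult)
  expect_equal(v_stp, 0.45, tolerance = 0.30)
  v_stp_scaled <- compute_vss(apply_kp_scalar(predict_kp(stp), 4.2),
                              ref_adult)
  expect_equal(v_stp_scaled, 1.74, tolerance = 0.30)
  v_clb <- compute_vss(predict_kp(clb), ref_adult)
  expect_equal(v_clb, 0.56, tolerance = 0.30)
})

test_that("Kp scaling is exact, invertible and affine in the scalar", {
  k <- predict_kp(stp)
  expect_equal(apply_kp_scalar(k, 1)$kp, k$kp)
  expect_equal(apply_kp_scalar(apply_kp_scalar(k, 2), 0.5)$kp, k$kp)
  expect_error(apply_kp_scalar(k, -1), "scalar")
  # Vss(scalar) is affine with intercept = plasma + erythrocyte term
  v1 <- compute_vss(apply_kp_scalar(k, 1), ref_adult)
  v2 <- compute_vss(apply_kp_scalar(k, 2), ref_adult)
  v3 <- compute_vss(apply_kp_scalar(k, 3), ref_adult)
  expect_equal(v3 - v2, v2 - v1, tolerance = 1e-12)
  hct <- ref_adult$hematocrit
  v_blood <- ref_adult$volumes[["venous_blood"]] +
    ref_adult$volumes[["arterial_blood"]]
  intercept <- (v_blood * (1 - hct) +
                  (k$bp - (1 - hct)) / hct * v_blood * hct) /
    ref_adult$body_weight_kg
  expect_equal(2 * v1 - v2, intercept, tolerance = 1e-12)
})

test_that("limiting behaviour of the partition equations is correct", {
  # logP -> -inf, fu,p = 1: no lipid or protein partitioning, Kp
  # approaches the tissue water fraction
  watery <- compound_model("W", mw = 100, logp = -12, type = "neutral",
                           bp = 1, fup = 1, fa = 1, ka = 1)
  kw <- predict_kp(watery)
  comp <- tissue_composition()
  # exact limit: tissue water plus the water-equivalent 0.7 share of
  # neutral phospholipid, minus the plasma-side correction
  lim <- comp$tissues$f_ew + comp$tissues$f_iw +
    0.7 * comp$tissues$f_np - 0.7 * comp$plasma$f_np * comp$tissues$ra
  expect_equal(unname(kw$kp[comp$tissues$tissue]), lim,
               tolerance = 1e-4)
  # Vss monotone increasing in logP for a lipophilic neutral
  v <- vapply(c(1, 2, 3), function(lp) {
    cpd <- compound_model("L", mw = 200, logp = lp, type = "neutral",
                          bp = 1, fup = 0.5, fa = 1, ka = 1)
    compute_vss(predict_kp(cpd), ref_adult)
  }, numeric(1))
  expect_true(all(diff(v) > 0))
  # unsupported ionization class errors
  acid <- compound_model("A", mw = 100, logp = 1, type = "neutral",
                         bp = 1, fup = 0.5, fa = 1, ka = 1)
  acid$type <- "monoprotic acid"
  expect_error(predict_kp(acid), "ionization")
})

test_that("doubling all Kp values doubles the tissue part of Vss", {
  k <- predict_kp(clb)
  v1 <- compute_vss(k, ref_adult)
  v2 <- compute_vss(apply_kp_scalar(k, 2), ref_adult)
  hct <- ref_adult$hematocrit
  v_blood <- ref_adult$volumes[["venous_blood"]] +
    ref_adult$volumes[["arterial_blood"]]
  intercept <- (v_blood * (1 - hct) +
                  (k$bp - (1 - hct)) / hct * v_blood * hct) /
    ref_adult$body_weight_kg
  expect_equal(v2 - intercept, 2 * (v1 - intercept), tolerance = 1e-12)
})
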