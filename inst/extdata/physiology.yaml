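# Reference human physiology for whole-body PBPK simulation.
# version 1 -- all values from open literature:
#   * organ volumes/flows: ICRP Publication 89 reference adult male,
#     lightly adjusted to an 81-kg virtual healthy volunteer
#   * tissue composition: Rodgers & Rowland (2006) unified tissue
#     composition tables (fractional water/lipid content, acidic
#     phospholipid content, tissue:plasma albumin ratios)
#   * hepatic scalars: MPPGL 40 mg/g (Barter et al. meta-analysis adult
#     value), liver density 1.05 g/mL
#   * CYP abundances: pmol per mg microsomal protein, adult liver
#     meta-analysis means (Achour et al. / Rodrigues-type compilations)
#   * ontogeny: tabulated fraction-of-adult abundance curves digitised
#     from published maturation profiles (Salem et al. CYP3A4; Upreti &
#     Wahlstrom CYP2C19/2C9/2B6/2D6/1A2 compilations), linear
#     interpolation between knots
#   * growth: WHO/CDC median weight-for-age, sex-specific
#   * GFR: absolute glomerular filtration rate by age (Rhodin et al.
#     maturation scaled to a 120 mL/min adult)
version: 1
adult:
  age_y: 25
  sex: male
  body_weight_kg: 81
  hematocrit: 0.45
  liver_density_g_per_ml: 1.05
  mppgl_mg_per_g: 40
  gfr_l_per_h: 7.2
  # organ volumes, L
  volumes:
    adipose: 18.2
    bone: 5.5
    brain: 1.45
    gut: 1.65
    heart: 0.33
    kidney: 0.31
    liver: 1.69
    lung: 0.53
    muscle: 29.0
    skin: 3.3
    spleen: 0.19
    pancreas: 0.10
    venous_blood: 3.9
    arterial_blood: 1.7
  # blood flows, L/h; liver entry is the hepatic artery; the portal vein
  # carries the summed gut + spleen + pancreas outflow into the liver
  flows:
    adipose: 20
    bone: 11
    brain: 46
    gut: 50
    heart: 14
    kidney: 74
    liver: 24
    muscle: 68
    skin: 22
    spleen: 8
    pancreas: 5
  # pmol per mg microsomal protein
  cyp_abundance:
    CYP1A2: 52
    CYP2B6: 17
    CYP2C8: 24
    CYP2C9: 73
    CYP2C19: 14
    CYP2D6: 8
    CYP3A4: 137
    CYP3A5: 24
tissue_composition:
  # f_ew/f_iw: extra/intracellular water (v/v); f_nl/f_np: neutral
  # lipid / neutral phospholipid (v/v); ap: acidic phospholipid (mg/g);
  # ra: tissue:plasma albumin ratio
  adipose:  {f_ew: 0.135, f_iw: 0.017, f_nl: 0.790,  f_np: 0.0020, ap: 0.40, ra: 0.049}
  bone:     {f_ew: 0.100, f_iw: 0.346, f_nl: 0.0740, f_np: 0.0011, ap: 0.67, ra: 0.100}
  brain:    {f_ew: 0.162, f_iw: 0.620, f_nl: 0.0510, f_np: 0.0565, ap: 0.40, ra: 0.048}
  gut:      {f_ew: 0.282, f_iw: 0.475, f_nl: 0.0487, f_np: 0.0163, ap: 2.41, ra: 0.158}
  heart:    {f_ew: 0.320, f_iw: 0.456, f_nl: 0.0115, f_np: 0.0166, ap: 2.25, ra: 0.157}
  kidney:   {f_ew: 0.273, f_iw: 0.483, f_nl: 0.0207, f_np: 0.0162, ap: 5.03, ra: 0.130}
  liver:    {f_ew: 0.165, f_iw: 0.586, f_nl: 0.0348, f_np: 0.0252, ap: 4.56, ra: 0.086}
  lung:     {f_ew: 0.336, f_iw: 0.446, f_nl: 0.0030, f_np: 0.0090, ap: 3.91, ra: 0.212}
  muscle:   {f_ew: 0.091, f_iw: 0.666, f_nl: 0.0238, f_np: 0.0072, ap: 1.53, ra: 0.064}
  skin:     {f_ew: 0.382, f_iw: 0.291, f_nl: 0.0284, f_np: 0.0111, ap: 1.32, ra: 0.277}
  spleen:   {f_ew: 0.207, f_iw: 0.579, f_nl: 0.0201, f_np: 0.0198, ap: 3.18, ra: 0.097}
  pancreas: {f_ew: 0.120, f_iw: 0.664, f_nl: 0.0403, f_np: 0.0090, ap: 2.67, ra: 0.060}
  plasma:   {f_water: 0.945, f_nl: 0.0023, f_np: 0.0013, ph: 7.4}
  blood_cells: {f_iw: 0.603, f_nl: 0.0017, f_np: 0.0029, ap: 0.50, ph: 7.22}
  ph_intracellular: 7.0
ontogeny:
  # fraction of adult abundance per mg microsomal protein; linear
  # interpolation between (age_y, fraction) knots; constant beyond 25 y
  CYP1A2:  {age: [0, 0.25, 0.5, 1, 2, 5, 10, 15, 25], frac: [0.05, 0.12, 0.25, 0.45, 0.65, 0.85, 1.0, 1.0, 1.0]}
  CYP2B6:  {age: [0, 0.25, 0.5, 1, 2, 25],            frac: [0.35, 0.55, 0.70, 0.90, 1.0, 1.0]}
  CYP2C8:  {age: [0, 0.25, 0.5, 1, 2, 25],            frac: [0.30, 0.50, 0.65, 0.85, 1.0, 1.0]}
  CYP2C9:  {age: [0, 0.25, 0.5, 1, 2, 25],            frac: [0.30, 0.55, 0.70, 0.90, 1.0, 1.0]}
  CYP2C19: {age: [0, 0.25, 0.5, 1, 2, 25],            frac: [0.30, 0.42, 0.55, 0.75, 1.0, 1.0]}
  CYP2D6:  {age: [0, 0.25, 0.5, 1, 2, 5, 25],         frac: [0.25, 0.45, 0.60, 0.80, 0.95, 1.0, 1.0]}
  CYP3A4:  {age: [0, 0.25, 0.5, 1, 2, 5, 10, 25],     frac: [0.11, 0.30, 0.42, 0.60, 0.80, 0.95, 1.0, 1.0]}
  CYP3A5:  {age: [0, 0.25, 0.5, 1, 2, 5, 10, 25],     frac: [0.11, 0.30, 0.42, 0.60, 0.80, 0.95, 1.0, 1.0]}
age_tables:
  # organ-specific growth that deviates from simple body-weight scaling
  mppgl:        {age: [0, 0.5, 1, 2, 5, 10, 15, 25], value: [26, 27, 28, 30, 32, 35, 38, 40]}
  liver_volume: {age: [0, 0.5, 1, 1.5, 2, 5, 10, 15, 25], value: [0.125, 0.22, 0.31, 0.35, 0.39, 0.54, 0.79, 1.24, 1.69]}
  brain_volume: {age: [0, 0.5, 1, 2, 5, 10, 25], value: [0.35, 0.60, 0.85, 1.05, 1.25, 1.35, 1.45]}
  gfr:          {age: [0, 0.25, 0.5, 1, 2, 5, 10, 15, 25], value: [0.20, 0.80, 1.20, 1.80, 2.40, 3.60, 4.80, 6.30, 7.20]}
growth:
  # median body weight for age (kg); WHO (0-5 y) / CDC (5-20 y) medians
  male:
    age: [0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 14, 16, 18, 20, 25]
    weight: [3.3, 6.4, 7.9, 8.9, 9.6, 10.9, 12.2, 14.3, 16.3, 18.3, 20.5, 25.4, 31.9, 39.9, 50.8, 60.8, 67.0, 72.0, 81.0]
  female:
    age: [0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 14, 16, 18, 20, 25]
    weight: [3.2, 5.8, 7.3, 8.2, 8.9, 10.2, 11.5, 13.9, 16.1, 18.2, 20.2, 25.0, 31.9, 41.5, 49.4, 53.9, 57.0, 59.0, 61.0]
cardiac_output:
  # adult CO equals the summed organ flows (342 L/h); pediatric scaling
  # follows allometric BW^0.75
  allometric_exponent: 0.75
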