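#' Tissue:plasma partition coefficients by the Rodgers-Rowland method
#'
#' Implements the unified tissue-composition equations for neutral
#' compounds and monoprotic bases. Partitioning terms: extracellular and
#' intracellular water (with Henderson-Hasselbalch ionisation at plasma
#' pH 7.4 and intracellular pH 7.0), neutral lipid and neutral
#' phospholipid (log P-derived; the adipose neutral-lipid term uses the
#' vegetable-oil:water relationship log D_vo = 1.115 log P - 1.35), and
#' either albumin-type protein binding scaled from the plasma unbound
#' fraction (neutrals and weak bases, pKa < 7) or acidic-phospholipid
#' association (strong bases, pKa >= 7, through the blood-cell
#' association constant).
#'
#' @param compound A `CompoundModel` (type "neutral" or
#'   "monoprotic base").
#' @param composition A `TissueComposition` (default: packaged tables).
#' @param apply_scalar If `TRUE`, multiply tissue Kp values by the
#'   compound's Kp scalar.
#' @param family "auto" picks the equation family from the pKa
#'   criterion (bases with pKa >= 7 use the acidic-phospholipid
#'   association); "moderate" or "strong" force a family — useful in
#'   sensitivity analyses that sweep pKa across the boundary, where
#'   the family switch would introduce a structural discontinuity.
#' @return Object of class `KpSet`: named per-tissue Kp (plasma-
#'   referenced), the scalar applied and the blood:plasma ratio used.
#' @export
predict_kp <- function(compound, composition = tissue_composition(),
                       apply_scalar = FALSE,
                       family = c("auto", "moderate", "strong")) {
  validate_compound(compound)
  family <- match.arg(family)
  if (!compound$type %in% c("neutral", "monoprotic base")) {
    stop("unsupported ionization class '", compound$type,
         "'; supported: neutral, monoprotic base", call. = FALSE)
  }
  tis <- composition$tissues
  pl <- composition$plasma
  ph_p <- pl$ph
  ph_iw <- composition$ph_iw
  P <- 10^compound$logp
  # vegetable-oil:water partitioning for adipose neutral lipid
  P_vo <- 10^(1.115 * compound$logp - 1.35)
  fup <- compound$fup

  is_base <- compound$type == "monoprotic base"
  strong_base <- switch(family,
                        auto = is_base && compound$pka >= 7,
                        moderate = FALSE,
                        strong = is_base)
  X <- if (is_base) 1 + 10^(compound$pka - ph_iw) else 1  # intracellular
  Y <- if (is_base) 1 + 10^(compound$pka - ph_p) else 1   # plasma

  # plasma neutral-lipid/phospholipid partitioning (appears in the
  # albumin-binding correction)
  pr_plasma <- P * pl$f_nl + (0.3 * P + 0.7) * pl$f_np

  kpu <- numeric(nrow(tis))
  for (i in seq_len(nrow(tis))) {
    r <- tis[i, ]
    Pt <- if (r$tissue == "adipose") P_vo else P
    lipid <- (Pt * r$f_nl + (0.3 * Pt + 0.7) * r$f_np) / Y
    water <- r$f_ew + X * r$f_iw / Y
    if (strong_base) {
      # association to tissue acidic phospholipids, scaled from the
      # blood-cell association constant
      bc <- composition$blood_cells
      X_bc <- 1 + 10^(compound$pka - bc$ph)
      kpu_bc <- .kpu_blood_cells(compound)
      ka_ap <- (kpu_bc - X_bc * bc$f_iw / Y -
                  (P * bc$f_nl + (0.3 * P + 0.7) * bc$f_np) / Y) *
        Y / (bc$ap * (X_bc - 1))
      prot <- ka_ap * r$ap * (X - 1) / Y
    } else {
      prot <- (1 / fup - 1 - pr_plasma) * r$ra
    }
    kpu[i] <- water + lipid + prot
  }
  kp <- kpu * fup
  if (any(!is.finite(kp)) || any(kp <= 0)) {
    stop("Rodgers-Rowland prediction produced non-positive Kp; check ",
         "fu,p / logP inputs", call. = FALSE)
  }
  names(kp) <- tis$tissue
  out <- structure(list(kp = kp, scalar = 1, bp = compound$bp,
                        compound = compound$name), class = "KpSet")
  if (apply_scalar) out <- apply_kp_scalar(out, compound$kp_scalar)
  out
}

# unbound blood-cell:plasma-water partition from B/P and hematocrit
.kpu_blood_cells <- function(compound, hct = 0.45) {
  ep <- (compound$bp - (1 - hct)) / hct  # erythrocyte:plasma ratio
  if (ep <= 0) {
    stop("B/P ", compound$bp, " implies no erythrocyte partitioning; ",
         "strong-base Kp prediction needs B/P > 1 - hematocrit",
         call. = FALSE)
  }
  ep / compound$fup
}

#' Apply a Kp scalar
#'
#' Multiplies every tissue Kp by a global scalar; plasma and blood are
#' unchanged.
#' @param kps A `KpSet`.
#' @param scalar Positive multiplier.
#' @return The scaled `KpSet`.
#' @export
apply_kp_scalar <- function(kps, scalar) {
  stopifnot(inherits(kps, "KpSet"))
  if (!is.numeric(scalar) || scalar <= 0) {
    stop("Kp scalar must be > 0", call. = FALSE)
  }
  kps$kp <- kps$kp * scalar
  kps$scalar <- kps$scalar * scalar
  kps
}

#' Steady-state volume of distribution from a Kp set
#'
#' `Vss = (V_plasma + sum_t Kp_t V_t + E:P * V_erythrocyte) / BW`, with
#' the erythrocyte:plasma ratio derived from B/P and hematocrit.
#'
#' @param kps A `KpSet`.
#' @param phys A `SystemPhysiology`.
#' @return Vss in L/kg.
#' @export
compute_vss <- function(kps, phys = reference_adult()) {
  stopifnot(inherits(kps, "KpSet"))
  validate_physiology(phys)
  missing <- setdiff(names(kps$kp), names(phys$volumes))
  if (length(missing)) {
    stop("no tissue volume for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vols <- phys$volumes[names(kps$kp)]
  hct <- phys$hematocrit
  v_blood <- phys$volumes[["venous_blood"]] + phys$volumes[["arterial_blood"]]
  v_plasma <- v_blood * (1 - hct)
  v_ery <- v_blood * hct
  ep <- (kps$bp - (1 - hct)) / hct
  ep <- max(ep, 0)  # no negative erythrocyte contribution
  unname((v_plasma + sum(kps$kp * vols) + ep * v_ery) /
           phys$body_weight_kg)
}

#' Export a Kp set as a data frame
#' @param kps A `KpSet`.
#' @export
kp_table <- function(kps) {
  data.frame(tissue = names(kps$kp), kp = unname(kps$kp),
             scalar = kps$scalar, bp = kps$bp)
}
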