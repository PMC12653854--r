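#' Unbound fraction in blood
#'
#' `fu_B = fu_p / (B/P)` -- the standard conversion feeding the
#' well-stirred liver model.
#' @param fu_p Unbound fraction in plasma, (0, 1].
#' @param bp Blood:plasma concentration ratio, > 0.
#' @export
fu_blood <- function(fu_p, bp) {
  stopifnot(fu_p > 0, fu_p <= 1, bp > 0)
  fu_p / bp
}

#' Well-stirred liver model, forward direction
#'
#' `CL_h,b = Qh fu_B CLint_u / (Qh + fu_B CLint_u)`, returned as a
#' plasma clearance via B/P.
#'
#' @param clint_u Unbound intrinsic clearance, L/h.
#' @param fu_p,bp Plasma unbound fraction and blood:plasma ratio.
#' @param qh Hepatic blood flow, L/h.
#' @return Hepatic plasma clearance, L/h.
#' @export
well_stirred_forward <- function(clint_u, fu_p, bp, qh) {
  stopifnot(clint_u >= 0, qh > 0)
  fub <- fu_blood(fu_p, bp)
  cl_b <- qh * fub * clint_u / (qh + fub * clint_u)
  cl_b * bp
}

#' Well-stirred liver model, inverse direction
#'
#' Back-calculates the unbound intrinsic clearance from an observed
#' hepatic plasma clearance:
#' `CLint_u = Qh CL_b / (fu_B (Qh - CL_b))`.
#'
#' @param cl_h_plasma Hepatic plasma clearance, L/h.
#' @param fu_p,bp Plasma unbound fraction and blood:plasma ratio.
#' @param qh Hepatic blood flow, L/h.
#' @return Unbound intrinsic clearance, L/h.
#' @export
well_stirred_back_calc <- function(cl_h_plasma, fu_p, bp, qh) {
  stopifnot(cl_h_plasma >= 0, qh > 0)
  cl_b <- cl_h_plasma / bp
  if (cl_b >= qh) {
    stop("hepatic blood clearance ", signif(cl_b, 4),
         " L/h exceeds hepatic blood flow ", signif(qh, 4), " L/h",
         call. = FALSE)
  }
  fub <- fu_blood(fu_p, bp)
  qh * cl_b / (fub * (qh - cl_b))
}

#' Split an intrinsic clearance over enzyme pathways
#'
#' `CLint_i = fm_i CLint_u`; the residual `(1 - sum fm)` is assigned to
#' a non-inhibitable bucket.
#'
#' @param clint_u Total unbound intrinsic clearance, L/h.
#' @param pathways Named fm vector (sum <= 1).
#' @return List with per-isoform `clint` (named vector, L/h) and the
#'   non-inhibitable `residual` (L/h).
#' @export
split_clint_by_fm <- function(clint_u, pathways) {
  stopifnot(clint_u >= 0)
  if (length(pathways) == 0) {
    return(list(clint = setNames(numeric(0), character(0)),
                residual = clint_u))
  }
  if (any(pathways < 0) || sum(pathways) > 1 + 1e-9) {
    stop("fm values must be >= 0 and sum to <= 1", call. = FALSE)
  }
  list(clint = clint_u * pathways,
       residual = clint_u * max(0, 1 - sum(pathways)))
}

#' Convert a whole-liver intrinsic clearance to a per-pmol value
#'
#' Divides by the total hepatic isoform amount
#' (abundance x MPPGL x liver mass) with L/h -> uL/min unit conversion.
#' Informational representation; model calibration anchors on
#' whole-liver clearances.
#'
#' @param clint_i Whole-liver unbound intrinsic clearance, L/h.
#' @param isoform CYP isoform name.
#' @param phys A `SystemPhysiology`.
#' @param allow_null Return `NA` instead of erroring when the phenotype
#'   abundance is zero.
#' @return uL/min/pmol P450.
#' @export
clint_per_pmol <- function(clint_i, isoform, phys = reference_adult(),
                           allow_null = FALSE) {
  stopifnot(isoform %in% CYP_ISOFORMS)
  total_pmol <- total_hepatic_cyp(phys, isoform)
  if (total_pmol <= 0) {
    if (allow_null) return(NA_real_)
    stop("zero hepatic ", isoform, " abundance (phenotype-null); ",
         "set allow_null = TRUE to return NA", call. = FALSE)
  }
  clint_i * 1e6 / 60 / total_pmol
}

#' Total hepatic CYP amount (pmol)
#' @param phys A `SystemPhysiology`.
#' @param isoform CYP isoform name.
#' @export
total_hepatic_cyp <- function(phys, isoform) {
  mult <- if (!is.null(phys$cyp_multiplier)) phys$cyp_multiplier[[isoform]] else 1
  phys$cyp_abundance[[isoform]] * mult * phys$mppgl * phys$liver_mass_g
}

#' Clearance context for one individual at one instant
#'
#' @param phys A `SystemPhysiology`.
#' @param compound A `CompoundModel`.
#' @param inhibitor_conc_um Named numeric vector: unbound inhibitor
#'   concentration (uM) per inhibited enzyme.
#' @param ki_um Named numeric vector: competitive ki (uM) of the
#'   inhibitor for the same enzymes (typically the perpetrator
#'   compound's `inhibition` slot).
#' @export
clearance_context <- function(phys, compound, inhibitor_conc_um = numeric(0),
                              ki_um = numeric(0)) {
  if (length(inhibitor_conc_um) && any(inhibitor_conc_um < 0)) {
    stop("unbound inhibitor concentrations must be >= 0", call. = FALSE)
  }
  structure(list(phys = phys, compound = compound,
                 inhibitor = inhibitor_conc_um, ki = ki_um),
            class = "ClearanceContext")
}

#' Competitive-inhibition factors per enzyme
#'
#' `1 / (1 + I_u / ki)` per isoform; isoforms without an inhibitor
#' entry (or without a ki) get factor 1.
#' @param isoforms Character vector of isoform names.
#' @param inhibitor_conc_um Named unbound inhibitor concentrations, uM.
#' @param ki_um Named ki values, uM.
#' @export
inhibition_factors <- function(isoforms, inhibitor_conc_um, ki_um) {
  vapply(isoforms, function(i) {
    if (!i %in% names(inhibitor_conc_um) || !i %in% names(ki_um)) return(1)
    iu <- inhibitor_conc_um[[i]]
    ki <- ki_um[[i]]
    if (!is.finite(ki)) return(1)
    1 / (1 + iu / ki)
  }, numeric(1))
}

#' Retrograde intrinsic clearance from an apparent oral clearance
#'
#' For a purely hepatically eliminated oral drug the well-stirred model
#' gives `CL_po = fu_B CLint_u / (fa B/P) x B/P`, i.e.
#' `CLint_u = fa CL_po / fu_p` -- the first-pass extraction cancels, so
#' the relation stays valid for oral clearances above the hepatic blood
#' flow (stiripentol's low-dose anchors reach 70 L/h against a ~90 L/h
#' hepatic flow, where the hepatic-clearance inverse is undefined).
#'
#' @param cl_po Apparent oral plasma clearance, L/h.
#' @param fa Fraction absorbed.
#' @param fu_p Unbound fraction in plasma.
#' @return Unbound intrinsic clearance, L/h.
#' @export
oral_retrograde_clint <- function(cl_po, fa, fu_p) {
  stopifnot(cl_po >= 0, fa > 0, fa <= 1, fu_p > 0, fu_p <= 1)
  fa * cl_po / fu_p
}

#' Reference-adult intrinsic clearance split of a compound
#'
#' Back-calculates the total unbound intrinsic clearance from the
#' compound's clearance anchor in the reference adult (well-stirred
#' inverse for hepatic plasma clearances, retrograde oral relation for
#' apparent oral clearances) and splits it over the fm pathways.
#'
#' @param compound A `CompoundModel`.
#' @param ref Reference adult `SystemPhysiology`.
#' @param cl_hepatic_plasma Override for the anchored hepatic plasma
#'   clearance (used for regimen-dependent stiripentol clearance).
#' @return List with `clint` (per-isoform, L/h), `residual` (L/h) and
#'   `clint_total`.
#' @export
reference_clint <- function(compound, ref = reference_adult(),
                            cl_hepatic_plasma = NULL) {
  cl <- if (!is.null(cl_hepatic_plasma)) cl_hepatic_plasma else
    compound$cl_hepatic_plasma
  if (is.null(cl) || !is.finite(cl)) {
    stop("compound ", compound$name, " has no anchored hepatic plasma ",
         "clearance; pass cl_hepatic_plasma", call. = FALSE)
  }
  anchor <- if (is.null(compound$cl_anchor_type)) "hepatic_plasma" else
    compound$cl_anchor_type
  clint_u <- if (anchor == "oral") {
    oral_retrograde_clint(cl, compound$fa, compound$fup)
  } else {
    well_stirred_back_calc(cl, compound$fup, compound$bp,
                           hepatic_blood_flow(ref))
  }
  c(split_clint_by_fm(clint_u, compound$pathways),
    list(clint_total = clint_u))
}

#' Effective per-isoform intrinsic clearance for an individual
#'
#' `CLint_i,eff = CLint_i,adult x ontogeny_i(age) x liver-size scaling
#' (liver mass x MPPGL relative to the adult) x abundance-variability
#' multiplier x phenotype multiplier x 1 / (1 + I_u / ki)`.
#' The non-inhibitable residual bucket skips ontogeny, the phenotype
#' multiplier and the inhibition factor but keeps the liver-size
#' scaling.
#'
#' @param context A `ClearanceContext`.
#' @param ref_clint Output of [reference_clint()] for the same compound.
#' @param ref Reference adult physiology (scaling denominator).
#' @param data Parsed physiology data (ontogeny curves).
#' @return List with `clint` (per-isoform effective, L/h), `residual`,
#'   and `inhibition_factor` per isoform.
#' @export
effective_clint <- function(context, ref_clint, ref = reference_adult(),
                            data = load_physiology_data()) {
  stopifnot(inherits(context, "ClearanceContext"))
  phys <- context$phys
  compound <- context$compound
  liver_scale <- (phys$liver_mass_g * phys$mppgl) /
    (ref$liver_mass_g * ref$mppgl)
  iso <- names(ref_clint$clint)
  ont <- vapply(iso, ontogeny_fraction, numeric(1), age = phys$age_y,
                data = data)
  mult <- if (!is.null(phys$cyp_multiplier)) {
    vapply(iso, function(i) phys$cyp_multiplier[[i]], numeric(1))
  } else rep(1, length(iso))
  inh <- inhibition_factors(iso, context$inhibitor, context$ki)
  list(clint = ref_clint$clint * ont * mult * inh * liver_scale,
       residual = ref_clint$residual * liver_scale,
       inhibition_factor = inh)
}
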