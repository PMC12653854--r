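#' Construct a compound model
#'
#' Typed container for all drug-specific parameters of one compound:
#' physicochemistry, absorption, distribution, elimination, enzyme
#' pathway fractions (fm), competitive-inhibition constants (ki) and
#' metabolite links. Validation enforces fm sums <= 1, positive ki and
#' fa in (0, 1].
#'
#' @param name Compound name.
#' @param mw Molecular weight, g/mol.
#' @param logp Octanol:water log partition coefficient.
#' @param type "neutral" or "monoprotic base".
#' @param pka Acid dissociation constant (bases only).
#' @param bp Blood:plasma concentration ratio.
#' @param fup Unbound fraction in plasma.
#' @param fugut Unbound fraction in gut (informational; no gut-wall
#'   metabolism is modelled).
#' @param fa Fraction absorbed, in (0, 1].
#' @param ka First-order absorption rate constant(s), 1/h; a named
#'   vector `c(fasted = ..., fed = ...)` or a single value.
#' @param lag_range Absorption lag-time range, h (length 2, sampled
#'   uniformly per subject), or `c(0, 0)`.
#' @param kp_scalar Global multiplier applied to all tissue Kp values.
#' @param cl_hepatic_plasma Enzymatic clearance anchor, L/h, that is
#'   split over the `pathways` fm values; interpreted per
#'   `cl_anchor_type`.
#' @param cl_anchor_type "hepatic_plasma" (well-stirred inverse applies)
#'   or "oral" (apparent oral plasma clearance; retrograde conversion
#'   `CLint_u = fa CL_po / fu_p`, valid above the hepatic flow limit).
#' @param cl_additional Additional first-order systemic plasma
#'   clearance, L/h (non-inhibitable, not forming metabolites).
#' @param cl_renal Renal plasma clearance, L/h (age-scaled with GFR).
#' @param pathways Named numeric vector of fm fractions per CYP isoform
#'   (sum <= 1; the residual is a non-inhibitable hepatic bucket).
#' @param inhibition Named numeric vector of competitive ki values, uM
#'   (total; f_inc = 1).
#' @param transporter_ki Named numeric vector, uM; inert metadata.
#' @param metabolite Name of the metabolite compound formed by the
#'   enzymatic pathways, or `NULL`.
#' @param metabolite_fraction Fraction of enzymatic parent metabolism
#'   that forms the metabolite.
#' @param vss_target Informational literature Vss, L/kg.
#' @return Object of class `CompoundModel`.
#' @export
compound_model <- function(name, mw, logp, type = c("neutral", "monoprotic base"),
                           pka = NA_real_, bp, fup, fugut = fup, fa, ka,
                           lag_range = c(0, 0), kp_scalar = 1,
                           cl_hepatic_plasma = 0,
                           cl_anchor_type = c("hepatic_plasma", "oral"),
                           cl_additional = 0,
                           cl_renal = 0, pathways = numeric(0),
                           inhibition = numeric(0),
                           transporter_ki = numeric(0),
                           metabolite = NULL, metabolite_fraction = 1,
                           vss_target = NA_real_) {
  type <- match.arg(type)
  cl_anchor_type <- match.arg(cl_anchor_type)
  obj <- structure(list(
    name = name, mw = mw, logp = logp, type = type, pka = pka, bp = bp,
    fup = fup, fugut = fugut, fa = fa, ka = ka,
    lag_range = lag_range, kp_scalar = kp_scalar,
    cl_hepatic_plasma = cl_hepatic_plasma,
    cl_anchor_type = cl_anchor_type, cl_additional = cl_additional,
    cl_renal = cl_renal, pathways = pathways, inhibition = inhibition,
    transporter_ki = transporter_ki, metabolite = metabolite,
    metabolite_fraction = metabolite_fraction, vss_target = vss_target
  ), class = "CompoundModel")
  validate_compound(obj)
}

#' Validate a compound model
#' @param x A `CompoundModel`.
#' @return The validated object (invisibly usable in pipelines).
#' @export
validate_compound <- function(x) {
  stopifnot(inherits(x, "CompoundModel"))
  if (!is.numeric(x$mw) || x$mw <= 0) stop("MW must be > 0", call. = FALSE)
  if (x$fa <= 0 || x$fa > 1) stop("fa must be in (0, 1]", call. = FALSE)
  if (x$fup <= 0 || x$fup > 1) stop("fu,p must be in (0, 1]", call. = FALSE)
  if (x$bp <= 0) stop("B/P must be > 0", call. = FALSE)
  cls <- c(x$cl_hepatic_plasma, x$cl_additional, x$cl_renal)
  if (any(cls[!is.na(cls)] < 0)) {
    stop("clearances must be >= 0", call. = FALSE)
  }
  if (length(x$pathways)) {
    if (is.null(names(x$pathways)) ||
        !all(names(x$pathways) %in% CYP_ISOFORMS)) {
      stop("pathway names must be CYP isoforms", call. = FALSE)
    }
    if (any(x$pathways < 0) || sum(x$pathways) > 1 + 1e-9) {
      stop("fm values must be >= 0 and sum to <= 1", call. = FALSE)
    }
  }
  if (length(x$inhibition) && any(x$inhibition <= 0)) {
    stop("ki values must be > 0", call. = FALSE)
  }
  if (x$kp_scalar <= 0) stop("Kp scalar must be > 0", call. = FALSE)
  if (x$type == "monoprotic base" && !is.finite(x$pka)) {
    stop("a monoprotic base needs a pKa", call. = FALSE)
  }
  x
}

#' Built-in clobazam (CLB) model
#'
#' 1,5-benzodiazepine parent drug. Hepatic enzymatic plasma clearance of
#' 1.4 L/h forms N-desmethylclobazam via CYP3A4/2C19/2B6 (70/19/11%);
#' an additional 0.6 L/h systemic clearance covers the minor
#' 4-hydroxyclobazam pathway; renal clearance 0.05 L/h.
#' @return A `CompoundModel`.
#' @export
builtin_clobazam <- function() {
  compound_model(
    name = "CLB", mw = 300.74, logp = 2.14, type = "monoprotic base",
    pka = 6.65, bp = 0.69, fup = 0.1, fugut = 0.1, fa = 0.93,
    ka = c(fasted = 2.11, fed = 1.25), kp_scalar = 1,
    cl_hepatic_plasma = 1.4, cl_additional = 0.6, cl_renal = 0.05,
    pathways = c(CYP3A4 = 0.70, CYP2C19 = 0.19, CYP2B6 = 0.11),
    metabolite = "NCLB", metabolite_fraction = 1.0, vss_target = 0.56
  )
}

#' Built-in N-desmethylclobazam (N-CLB) model
#'
#' Active metabolite of clobazam, eliminated exclusively by CYP2C19
#' (oral plasma clearance 1.09 L/h) plus 0.08 L/h renally; Kp scalar
#' 0.8 to match the observed distribution volume.
#' @return A `CompoundModel`.
#' @export
builtin_ndesmethylclobazam <- function() {
  compound_model(
    name = "NCLB", mw = 286.71, logp = 2.45, type = "monoprotic base",
    pka = 3.93, bp = 0.69, fup = 0.11, fugut = 0.11, fa = 0.93,
    ka = c(fasted = 2.11, fed = 1.25), kp_scalar = 0.8,
    cl_hepatic_plasma = 1.09, cl_anchor_type = "oral",
    cl_additional = 0, cl_renal = 0.08,
    pathways = c(CYP2C19 = 1.0), vss_target = 1.04
  )
}

#' Built-in stiripentol (STP) model
#'
#' Aromatic allylic alcohol co-medication and broad competitive CYP
#' inhibitor. Oral clearance is regimen-dependent (see
#' [stp_clpo_for_regimen()]); fm values cover 75.5% of clearance and
#' the residual 24.5% is a non-inhibitable hepatic bucket. The CYP2C19
#' ki of 0.0139 uM is the 10-fold-reduced optimised value (in vitro
#' 0.139 uM). P-gp and BCRP ki values are stored as inert metadata.
#' @return A `CompoundModel`.
#' @export
builtin_stiripentol <- function() {
  compound_model(
    name = "STP", mw = 234.29, logp = 2.94, type = "neutral",
    bp = 0.58, fup = 0.01, fugut = 0.01, fa = 0.82, ka = c(fed = 1.4),
    lag_range = c(0.5, 1.0), kp_scalar = 4.2,
    cl_hepatic_plasma = NA_real_,  # regimen-dependent, see stp_clpo_for_regimen
    cl_anchor_type = "oral", cl_renal = 0,
    pathways = c(CYP1A2 = 0.20, CYP2C19 = 0.15, CYP2C9 = 0.08,
                 CYP2D6 = 0.075, CYP3A4 = 0.14, CYP3A5 = 0.11),
    inhibition = c(CYP1A2 = 3.3, CYP2B6 = 7, CYP2C19 = 0.0139,
                   CYP2C8 = 3.4, CYP2C9 = 65, CYP2D6 = 9.3, CYP3A4 = 2.5),
    transporter_ki = c(Pgp = 46, BCRP = 1.17), vss_target = 1.74
  )
}

# regimen-dependent oral-clearance anchors for stiripentol (L/h)
.stp_anchors <- list(
  adult_single = data.frame(dose = c(300, 500, 600, 1000, 1200, 2000),
                            cl = c(70, 60, 60, 35, 35, 25)),
  adult_multiple = data.frame(daily = c(1200, 1800, 3000),
                              cl = c(17, 17, 8)),
  pediatric = data.frame(age = c(3, 12), cl = c(14, 8))
)

#' Regimen-dependent stiripentol oral clearance
#'
#' Stiripentol clearance falls with dose and with chronic dosing; the
#' non-linearity is represented by fitted clearance anchors per regimen
#' rather than Michaelis-Menten parameters. Nearest-anchor policy, no
#' interpolation. Adult single doses: 300 mg -> 70, 500/600 -> 60,
#' 1000/1200 -> 35, 2000 -> 25 L/h. Adult multiple dosing:
#' 1200-1800 mg/day -> 17, 3000 mg/day -> 8 L/h. Pediatric: < 6 y ->
#' 14 L/h, >= 12 y -> 8 L/h (nearest anchor for intermediate ages).
#'
#' @param dose_mg Single-dose amount (mg), for single-dose regimens.
#' @param schedule "single" or "multiple".
#' @param daily_dose_mg Total daily dose (mg/day) for multiple dosing.
#' @param population "adult" or "pediatric".
#' @param age Age in years (pediatric anchor selection).
#' @return Oral clearance anchor, L/h.
#' @export
stp_clpo_for_regimen <- function(dose_mg = NULL,
                                 schedule = c("single", "multiple"),
                                 daily_dose_mg = NULL,
                                 population = c("adult", "pediatric"),
                                 age = NULL) {
  schedule <- match.arg(schedule)
  population <- match.arg(population)
  if (!is.null(dose_mg) && any(dose_mg <= 0)) {
    stop("dose must be > 0", call. = FALSE)
  }
  if (population == "pediatric") {
    if (is.null(age)) stop("pediatric regimen needs an age", call. = FALSE)
    tab <- .stp_anchors$pediatric
    return(tab$cl[which.min(abs(tab$age - age))])
  }
  if (schedule == "single") {
    if (is.null(dose_mg)) stop("single-dose regimen needs dose_mg", call. = FALSE)
    tab <- .stp_anchors$adult_single
    i <- which.min(abs(tab$dose - dose_mg))
    if (min(abs(tab$dose - dose_mg)) > 0 && !dose_mg %in% tab$dose) {
      # nearest-anchor fallback for unanchored doses
      if (dose_mg < min(tab$dose) || dose_mg > max(tab$dose)) {
        warning("dose ", dose_mg, " mg outside the anchored range; ",
                "using nearest anchor ", tab$dose[i], " mg", call. = FALSE)
      }
    }
    return(tab$cl[i])
  }
  if (is.null(daily_dose_mg)) {
    stop("multiple-dose regimen needs daily_dose_mg", call. = FALSE)
  }
  tab <- .stp_anchors$adult_multiple
  tab$cl[which.min(abs(tab$daily - daily_dose_mg))]
}

#' Pick the absorption rate constant for a prandial state
#' @param compound A `CompoundModel`.
#' @param prandial "fasted" or "fed".
#' @export
ka_for_state <- function(compound, prandial = c("fasted", "fed")) {
  prandial <- match.arg(prandial)
  ka <- compound$ka
  if (is.null(names(ka)) || length(ka) == 1) return(unname(ka[1]))
  if (prandial %in% names(ka)) return(unname(ka[[prandial]]))
  unname(ka[1])
}

#' Serialise a compound model to a config list / file
#' @param compound A `CompoundModel`.
#' @param path Optional YAML path to write.
#' @return The plain-list representation (invisibly when writing).
#' @export
compound_to_config <- function(compound, path = NULL) {
  validate_compound(compound)
  lst <- unclass(compound)
  lst <- lapply(lst, function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  if (!is.null(path)) {
    yaml::write_yaml(lst, path)
    return(invisible(lst))
  }
  lst
}

#' Load a compound model from a config list / file
#' @param x A list as produced by [compound_to_config()] or a YAML path.
#' @return A `CompoundModel`.
#' @export
compound_from_config <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  for (f in c("pathways", "inhibition", "transporter_ki", "ka")) {
    if (!is.null(x[[f]]) && is.list(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  for (f in c("lag_range")) {
    if (!is.null(x[[f]])) x[[f]] <- as.numeric(unlist(x[[f]]))
  }
  if (is.null(x$pathways)) x$pathways <- numeric(0)
  if (is.null(x$inhibition)) x$inhibition <- numeric(0)
  if (is.null(x$transporter_ki)) x$transporter_ki <- numeric(0)
  obj <- structure(x[c("name", "mw", "logp", "type", "pka", "bp", "fup",
                       "fugut", "fa", "ka", "lag_range", "kp_scalar",
                       "cl_hepatic_plasma", "cl_anchor_type",
                       "cl_additional", "cl_renal",
                       "pathways", "inhibition", "transporter_ki",
                       "metabolite", "metabolite_fraction", "vss_target")],
                   class = "CompoundModel")
  if (is.null(obj$pka)) obj$pka <- NA_real_
  if (is.null(obj$cl_additional)) obj$cl_additional <- 0
  if (is.null(obj$cl_anchor_type)) obj$cl_anchor_type <- "hepatic_plasma"
  if (is.null(obj$metabolite_fraction)) obj$metabolite_fraction <- 1
  if (is.null(obj$vss_target)) obj$vss_target <- NA_real_
  validate_compound(obj)
}
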