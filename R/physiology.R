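#' @useDynLib dravetpbpk
#' @importFrom stats approx optim rbinom rlnorm runif setNames rnorm sd quantile var coef lm
#' @importFrom utils read.csv write.csv modifyList
NULL

PBPK_TISSUES <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
                  "liver", "lung", "muscle", "skin", "spleen", "pancreas")
CYP_ISOFORMS <- c("CYP1A2", "CYP2B6", "CYP2C8", "CYP2C9", "CYP2C19",
                  "CYP2D6", "CYP3A4", "CYP3A5")

.pkg_env <- new.env(parent = emptyenv())

#' Load the packaged physiology data file
#'
#' Reads the versioned YAML file holding the reference adult physiology,
#' Rodgers-Rowland tissue composition tables, CYP ontogeny curves,
#' growth tables and age tables. The result is cached per path.
#'
#' @param path Optional override path to a physiology YAML file.
#' @return A list mirroring the YAML structure (invisibly cached).
#' @export
load_physiology_data <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physiology.yaml", package = "dravetpbpk")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("physiology data file not found: ", path, call. = FALSE)
  }
  key <- normalizePath(path)
  if (!is.null(.pkg_env$phys_cache[[key]])) {
    return(.pkg_env$phys_cache[[key]])
  }
  dat <- yaml::read_yaml(path)
  # coerce YAML sequences to numeric vectors in the tabulated sections
  dat$ontogeny <- lapply(dat$ontogeny, lapply, unlist)
  dat$age_tables <- lapply(dat$age_tables, lapply, unlist)
  dat$growth <- lapply(dat$growth, lapply, unlist)
  req <- c("adult", "tissue_composition", "ontogeny", "age_tables", "growth")
  missing <- setdiff(req, names(dat))
  if (length(missing)) {
    stop("physiology data file is missing sections: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(.pkg_env$phys_cache)) .pkg_env$phys_cache <- list()
  .pkg_env$phys_cache[[key]] <- dat
  dat
}

#' Tissue composition table for partition-coefficient prediction
#'
#' @param data Parsed physiology data (default: packaged file).
#' @return Object of class `TissueComposition`: a list with a per-tissue
#'   data frame (`tissues`), plasma and blood-cell composition, and pH
#'   values.
#' @export
tissue_composition <- function(data = load_physiology_data()) {
  tc <- data$tissue_composition
  tis <- do.call(rbind, lapply(PBPK_TISSUES, function(t) {
    row <- tc[[t]]
    if (is.null(row)) stop("no tissue composition for ", t, call. = FALSE)
    data.frame(tissue = t, f_ew = row$f_ew, f_iw = row$f_iw,
               f_nl = row$f_nl, f_np = row$f_np, ap = row$ap, ra = row$ra)
  }))
  stopifnot(all(tis$f_ew + tis$f_iw + tis$f_nl + tis$f_np < 1),
            all(tis[, c("f_ew", "f_iw", "f_nl", "f_np")] >= 0),
            all(tis[, c("f_ew", "f_iw", "f_nl", "f_np")] <= 1))
  structure(list(
    tissues = tis,
    plasma = tc$plasma,
    blood_cells = tc$blood_cells,
    ph_iw = tc$ph_intracellular
  ), class = "TissueComposition")
}

#' Reference healthy adult physiology
#'
#' Deterministic literature-based reference individual (81 kg adult
#' male): organ volumes and blood flows, hepatic scalars (liver mass,
#' MPPGL), per-isoform hepatic CYP abundances, GFR. Stands in for a
#' proprietary simulator population library; every value is cited in the
#' packaged data file.
#'
#' @param data Parsed physiology data (default: packaged file).
#' @return Object of class `SystemPhysiology`.
#' @export
reference_adult <- function(data = load_physiology_data()) {
  a <- data$adult
  vols <- unlist(a$volumes)[c(PBPK_TISSUES, "venous_blood", "arterial_blood")]
  flows <- unlist(a$flows)[setdiff(PBPK_TISSUES, "lung")]
  if (anyNA(vols) || anyNA(flows)) {
    stop("physiology data file has missing volumes or flows", call. = FALSE)
  }
  co <- sum(flows)  # venous return closes through the lung
  liver_mass <- vols[["liver"]] * 1000 * a$liver_density_g_per_ml
  phys <- structure(list(
    age_y = a$age_y,
    sex = a$sex,
    body_weight_kg = a$body_weight_kg,
    hematocrit = a$hematocrit,
    volumes = vols,
    flows = flows,
    cardiac_output = co,
    liver_mass_g = liver_mass,
    mppgl = a$mppgl_mg_per_g,
    cyp_abundance = unlist(a$cyp_abundance)[CYP_ISOFORMS],
    gfr_l_per_h = a$gfr_l_per_h,
    phenotype = "EM",
    cyp_multiplier = setNames(rep(1, length(CYP_ISOFORMS)), CYP_ISOFORMS)
  ), class = "SystemPhysiology")
  validate_physiology(phys)
  phys
}

validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "SystemPhysiology"))
  num <- c(phys$body_weight_kg, phys$volumes, phys$flows,
           phys$liver_mass_g, phys$mppgl, phys$gfr_l_per_h,
           phys$cardiac_output)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("SystemPhysiology has non-positive or missing quantities",
         call. = FALSE)
  }
  if (sum(phys$flows) > phys$cardiac_output + 1e-9) {
    stop("sum of tissue blood flows exceeds cardiac output", call. = FALSE)
  }
  if (!phys$phenotype %in% c("EM", "PM")) {
    stop("phenotype must be 'EM' or 'PM'", call. = FALSE)
  }
  invisible(phys)
}

#' Hepatic blood flow of an individual (L/h)
#'
#' Hepatic artery plus portal vein (gut + spleen + pancreas outflow).
#' @param phys A `SystemPhysiology`.
#' @export
hepatic_blood_flow <- function(phys) {
  unname(phys$flows[["liver"]] + phys$flows[["gut"]] +
         phys$flows[["spleen"]] + phys$flows[["pancreas"]])
}

#' Fraction-of-adult CYP abundance at a given age
#'
#' Tabulated published maturation profiles with linear interpolation;
#' CYP2C19 starts near 30% of the adult level at birth and reaches the
#' adult level by about two years.
#'
#' @param isoform One of the supported CYP isoforms.
#' @param age Age in years (>= 0); vectorised.
#' @param data Parsed physiology data.
#' @return Fraction of adult abundance in (0, 2].
#' @export
ontogeny_fraction <- function(isoform, age, data = load_physiology_data()) {
  if (!isoform %in% names(data$ontogeny)) {
    stop("unknown isoform '", isoform, "'; supported: ",
         paste(names(data$ontogeny), collapse = ", "), call. = FALSE)
  }
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  tab <- data$ontogeny[[isoform]]
  approx(tab$age, tab$frac, xout = pmin(age, max(tab$age)), rule = 2)$y
}

.age_table <- function(data, name, age) {
  tab <- data$age_tables[[name]]
  approx(tab$age, tab$value, xout = pmin(age, max(tab$age)), rule = 2)$y
}

#' Median body weight for age and sex
#'
#' @param age Age in years.
#' @param sex "male" or "female".
#' @param data Parsed physiology data.
#' @export
weight_for_age <- function(age, sex = "male", data = load_physiology_data()) {
  sex <- match.arg(sex, c("male", "female"))
  tab <- data$growth[[sex]]
  approx(tab$age, tab$weight, xout = pmin(age, max(tab$age)), rule = 2)$y
}

#' Scale the reference adult physiology to a pediatric age
#'
#' Body weight follows the sex-specific growth table; liver and brain
#' volumes follow organ-specific tables; remaining organ, plasma and
#' blood volumes scale proportionally with body weight; blood flows
#' scale with allometric cardiac output (BW^0.75); MPPGL and GFR follow
#' their own age tables; CYP abundances are multiplied by the
#' isoform-specific ontogeny fraction.
#'
#' @param reference A `SystemPhysiology` (the reference adult).
#' @param age Target age in years, in `[0.5, 25]`.
#' @param sex "male" or "female".
#' @param data Parsed physiology data.
#' @return A `SystemPhysiology` at the target age.
#' @export
scale_to_age <- function(reference, age, sex = "male",
                         data = load_physiology_data()) {
  validate_physiology(reference)
  if (age < 0.5 || age > 25) {
    stop("age ", age, " outside the supported range [0.5, 25] years",
         call. = FALSE)
  }
  sex <- match.arg(sex, c("male", "female"))
  bw <- weight_for_age(age, sex, data)
  wr <- bw / reference$body_weight_kg
  phys <- reference
  phys$age_y <- age
  phys$sex <- sex
  phys$body_weight_kg <- bw
  vols <- reference$volumes * wr
  vols[["liver"]] <- .age_table(data, "liver_volume", age)
  vols[["brain"]] <- .age_table(data, "brain_volume", age)
  phys$volumes <- vols
  exp_co <- if (!is.null(data$cardiac_output$allometric_exponent)) {
    data$cardiac_output$allometric_exponent
  } else 0.75
  phys$flows <- reference$flows * wr^exp_co
  phys$cardiac_output <- sum(phys$flows)
  phys$liver_mass_g <- vols[["liver"]] * 1000 *
    data$adult$liver_density_g_per_ml
  phys$mppgl <- .age_table(data, "mppgl", age)
  phys$gfr_l_per_h <- .age_table(data, "gfr", age)
  ont <- vapply(CYP_ISOFORMS, ontogeny_fraction, numeric(1),
                age = age, data = data)
  phys$cyp_abundance <- reference$cyp_abundance * ont
  validate_physiology(phys)
  phys
}

#' Population specification for virtual trials
#'
#' @param n_trials,n_subjects Number of virtual trials and subjects per
#'   trial (both >= 1).
#' @param age_range Length-2 numeric, years; subjects are drawn
#'   uniformly over the range (a single value fixes the age).
#' @param prop_female Proportion of female subjects.
#' @param pm_frequency CYP2C19 poor-metabolizer frequency in `[0, 1]`.
#' @param cv_abundance,cv_ka,cv_fup Log-normal inter-individual
#'   coefficients of variation for CYP abundances, absorption rate
#'   constant and unbound plasma fraction.
#' @param pm_multiplier CYP2C19 abundance multiplier applied to poor
#'   metabolizers (default 0: no functional enzyme).
#' @param seed Mandatory integer random seed.
#' @return Object of class `PopulationSpec`.
#' @export
population_spec <- function(n_trials = 10, n_subjects = 10,
                            age_range = c(25, 25), prop_female = 0.5,
                            pm_frequency = 0, cv_abundance = 0.30,
                            cv_ka = 0.30, cv_fup = 0.15,
                            pm_multiplier = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (length(age_range) == 1) age_range <- rep(age_range, 2)
  stopifnot(n_trials >= 1, n_subjects >= 1,
            pm_frequency >= 0, pm_frequency <= 1,
            prop_female >= 0, prop_female <= 1,
            cv_abundance >= 0, cv_ka >= 0, cv_fup >= 0,
            age_range[1] <= age_range[2])
  structure(list(
    n_trials = as.integer(n_trials), n_subjects = as.integer(n_subjects),
    age_range = age_range, prop_female = prop_female,
    pm_frequency = pm_frequency, cv_abundance = cv_abundance,
    cv_ka = cv_ka, cv_fup = cv_fup, pm_multiplier = pm_multiplier,
    seed = as.integer(seed)
  ), class = "PopulationSpec")
}

.lnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a virtual population
#'
#' Draws `n_trials * n_subjects` individuals: age uniform over the range,
#' sex by the female proportion, body size from the growth tables,
#' log-normal inter-individual variability on CYP abundances (one
#' multiplier per isoform per subject, shared across compounds), and
#' CYP2C19 phenotype from the PM frequency. Fully reproducible from the
#' spec seed.
#'
#' @param spec A `PopulationSpec`.
#' @param data Parsed physiology data.
#' @return List of `SystemPhysiology` objects with attributes `trial`
#'   and per-subject variability multipliers (`cyp_multiplier`,
#'   `ka_multiplier`, `fup_multiplier`).
#' @export
sample_population <- function(spec, data = load_physiology_data()) {
  stopifnot(inherits(spec, "PopulationSpec"))
  ref <- reference_adult(data)
  n <- spec$n_trials * spec$n_subjects
  set.seed(spec$seed)
  ages <- runif(n, spec$age_range[1], spec$age_range[2])
  sexes <- ifelse(runif(n) < spec$prop_female, "female", "male")
  pm <- runif(n) < spec$pm_frequency
  out <- vector("list", n)
  for (i in seq_len(n)) {
    phys <- scale_to_age(ref, ages[i], sexes[i], data)
    mult <- .lnorm_mult(length(CYP_ISOFORMS), spec$cv_abundance)
    names(mult) <- CYP_ISOFORMS
    if (pm[i]) {
      phys$phenotype <- "PM"
      mult[["CYP2C19"]] <- mult[["CYP2C19"]] * spec$pm_multiplier
    }
    phys$cyp_multiplier <- mult
    phys$ka_multiplier <- .lnorm_mult(1, spec$cv_ka)
    phys$fup_multiplier <- .lnorm_mult(1, spec$cv_fup)
    phys$subject_id <- i
    phys$trial <- ((i - 1L) %/% spec$n_subjects) + 1L
    out[[i]] <- phys
  }
  out
}
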