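#' Synthetic-dataset specification
#'
#' Describes a digitised-style mean-profile dataset to generate: the
#' regimen, sampling schedule, residual-error model and replication
#' level, with known ground truth stored alongside.
#'
#' @param compound Compound name ("CLB", "NCLB", "STP") or a
#'   `CompoundModel`.
#' @param dose_mg Dose per administration, mg.
#' @param interval_h Dosing interval, h.
#' @param duration_days Days of dosing.
#' @param schedule Sampling times, h (within the simulated window).
#' @param cv Proportional residual error CV (default 0.15).
#' @param floor_mg_per_l Additive error floor: observations are not
#'   generated below this assay floor.
#' @param n_replicates Number of replicate "studies".
#' @param prandial Prandial state.
#' @param cl_po Hepatic plasma clearance anchor override (regimen-
#'   dependent stiripentol clearance, or a true-parameter override for
#'   recovery tests).
#' @param seed Mandatory seed.
#' @return Object of class `SyntheticDatasetSpec`.
#' @export
synthetic_spec <- function(compound, dose_mg, interval_h = 24,
                           duration_days = 1, schedule, cv = 0.15,
                           floor_mg_per_l = 0, n_replicates = 1,
                           prandial = "fasted", cl_po = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(cv >= 0, n_replicates >= 1, all(schedule >= 0))
  if (any(schedule > duration_days * 24 + 96)) {
    stop("sampling schedule extends beyond the simulation window",
         call. = FALSE)
  }
  structure(list(compound = compound, dose_mg = dose_mg,
                 interval_h = interval_h, duration_days = duration_days,
                 schedule = sort(unique(schedule)), cv = cv,
                 floor_mg_per_l = floor_mg_per_l,
                 n_replicates = n_replicates, prandial = prandial,
                 cl_po = cl_po, seed = as.integer(seed)),
            class = "SyntheticDatasetSpec")
}

.builtin_by_name <- function(name) {
  switch(name,
         CLB = builtin_clobazam(),
         NCLB = builtin_ndesmethylclobazam(),
         STP = builtin_stiripentol(),
         stop("unknown builtin compound '", name, "'", call. = FALSE))
}

#' Generate a synthetic digitised-style mean profile
#'
#' Simulates the model truth in the reference adult and overlays
#' mean-unbiased multiplicative log-normal noise at the stated CV.
#' The noiseless truth is returned in a `conc_true` column so recovery
#' tests can compare against it.
#'
#' @param spec A `SyntheticDatasetSpec`.
#' @return Data frame: replicate, compound, time_h, conc_mg_per_L,
#'   conc_true, dose_mg, regimen_id.
#' @export
synth_profile <- function(spec) {
  stopifnot(inherits(spec, "SyntheticDatasetSpec"))
  cp <- if (inherits(spec$compound, "CompoundModel")) spec$compound else
    .builtin_by_name(spec$compound)
  ref <- reference_adult()
  cl_override <- list()
  if (!is.null(spec$cl_po)) cl_override[[cp$name]] <- spec$cl_po
  lag <- if (any(cp$lag_range > 0)) mean(cp$lag_range) else 0
  m <- assemble_model(list(cp), ref, cl_override = cl_override,
                      prandial = spec$prandial)
  res <- simulate_pbpk(
    m, dose_regimen(cp$name, dose_mg = spec$dose_mg,
                    interval_h = spec$interval_h,
                    duration_days = spec$duration_days,
                    prandial = spec$prandial),
    t_end = max(spec$schedule) + 1, output_step = 1,
    extra_times = spec$schedule,
    lag_by_compound = setNames(list(lag), cp$name))
  truth <- res$conc[match(spec$schedule, res$time), cp$name]
  set.seed(spec$seed)
  out <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    obs <- truth * .lnorm_mult(length(truth), spec$cv)
    obs <- pmax(obs, spec$floor_mg_per_l)
    data.frame(replicate = r, compound = cp$name, time_h = spec$schedule,
               conc_mg_per_L = obs, conc_true = truth,
               dose_mg = spec$dose_mg,
               regimen_id = paste0(cp$name, "_", spec$dose_mg, "mg_q",
                                   spec$interval_h, "h"))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic steady-state trough study
#'
#' Emulates a retrospective pediatric trough collection: a two-phase
#' stiripentol add-on design simulated with between-subject
#' variability, with multiplicative assay noise on the sampled troughs
#' and phenotype labels attached. Ground truth (noise-free troughs) is
#' kept alongside.
#'
#' @param design A `TrialDesign` with `baseline_days` set (e.g., from
#'   [ddi_preset()]).
#' @param assay_cv Proportional assay error CV on troughs.
#' @param seed Noise seed (population seed lives in the design).
#' @return Data frame: subject, phase (baseline / coadministration),
#'   phenotype, dose_mg_per_kg_day, compound, trough_mg_per_L,
#'   trough_true.
#' @export
synth_trough_study <- function(design, assay_cv = 0.15, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  dd <- run_ddi_study(design)
  d <- dd$subjects
  set.seed(seed)
  long <- rbind(
    data.frame(subject_id = d$subject_id, phase = "baseline",
               phenotype = d$phenotype, compound = d$compound,
               trough_true = d$cmin_control),
    data.frame(subject_id = d$subject_id, phase = "coadministration",
               phenotype = d$phenotype, compound = d$compound,
               trough_true = d$cmin_inh))
  long$trough_mg_per_L <- long$trough_true *
    .lnorm_mult(nrow(long), assay_cv)
  long
}

#' Write the standard synthetic fixture pack
#'
#' Adult CLB single/multiple dose profiles, the STP single-dose ladder
#' (300-2000 mg), a STICLO-style pediatric DDI trough set and the GSA
#' test-function tables, all with fixed seeds, plus a manifest with
#' MD5 checksums. Regeneration with the same seeds is byte-identical.
#'
#' @param output_dir Directory to write into (created if missing).
#' @param seed Base seed.
#' @param n_trough_subjects Subjects in the trough study (kept small:
#'   fixtures are illustrative, not study-sized).
#' @return Invisibly, the manifest data frame.
#' @export
fixture_suite <- function(output_dir, seed = 20250901,
                          n_trough_subjects = 4) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output dir ", output_dir, call. = FALSE)
  }
  files <- character(0)
  wr <- function(d, name) {
    path <- file.path(output_dir, name)
    write.csv(d, path, row.names = FALSE)
    files <<- c(files, path)
  }
  sched_single <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 36, 48)
  # calibration-style 20 mg single-dose CLB study, fasted
  wr(synth_profile(synthetic_spec("CLB", 20, duration_days = 1,
                                  schedule = sched_single, seed = seed)),
     "clb_20mg_single_fasted.csv")
  wr(synth_profile(synthetic_spec("CLB", 10, interval_h = 24,
                                  duration_days = 14,
                                  schedule = 13 * 24 + sched_single,
                                  seed = seed + 1)),
     "clb_10mg_qd_multiple.csv")
  for (dose in c(300, 500, 600, 1000, 1200, 2000)) {
    cl <- stp_clpo_for_regimen(dose_mg = dose, schedule = "single",
                               population = "adult")
    wr(synth_profile(synthetic_spec("STP", dose, duration_days = 1,
                                    schedule = sched_single,
                                    prandial = "fed", cl_po = cl,
                                    seed = seed + dose)),
       sprintf("stp_%dmg_single_fed.csv", dose))
  }
  des <- ddi_preset("sticlo", phenotype = "mixed", seed = seed + 7,
                    n_trials = 1, n_subjects = n_trough_subjects)
  wr(synth_trough_study(des, seed = seed + 8),
     "sticlo_pediatric_troughs.csv")
  # additive GSA test function table: y = 2 x1 + 1 x2 + 0.5 x3
  set.seed(seed + 9)
  X <- matrix(runif(300), 100, 3)
  wr(data.frame(x1 = X[, 1], x2 = X[, 2], x3 = X[, 3],
                y = X %*% c(2, 1, 0.5)),
     "gsa_additive_testfunction.csv")
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    seed = seed)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
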