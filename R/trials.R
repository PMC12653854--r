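#' Virtual-trial design
#'
#' @param population A `PopulationSpec`.
#' @param regimens List of `DoseRegimen` (weight-based doses are
#'   resolved per subject).
#' @param compounds List of `CompoundModel` to co-simulate.
#' @param cl_override Named list of hepatic plasma clearance anchors
#'   (regimen-dependent stiripentol clearance).
#' @param prandial Named prandial states per compound.
#' @param duration_days Total simulated duration.
#' @param baseline_days Duration of the baseline (pre-perpetrator)
#'   phase for DDI designs.
#' @return Object of class `TrialDesign`.
#' @export
trial_design <- function(population, regimens, compounds,
                         cl_override = list(), prandial = "fasted",
                         duration_days, baseline_days = NULL) {
  stopifnot(inherits(population, "PopulationSpec"), duration_days > 0)
  structure(list(population = population, regimens = regimens,
                 compounds = compounds, cl_override = cl_override,
                 prandial = prandial, duration_days = duration_days,
                 baseline_days = baseline_days), class = "TrialDesign")
}

# deterministic per-subject absorption lag times derived from the
# population seed
.subject_lags <- function(design, n) {
  lag_cp <- Filter(function(cp) any(cp$lag_range > 0), design$compounds)
  if (!length(lag_cp)) return(replicate(n, list(), simplify = FALSE))
  set.seed(design$population$seed * 2L + 1L)
  lapply(seq_len(n), function(i) {
    out <- lapply(lag_cp, function(cp) runif(1, cp$lag_range[1],
                                             cp$lag_range[2]))
    setNames(out, vapply(lag_cp, `[[`, character(1), "name"))
  })
}

.resolve_regimens <- function(regimens, keep = NULL) {
  if (is.null(keep)) return(regimens)
  Filter(function(r) r$compound %in% keep, regimens)
}

.subject_sim <- function(design, phys, lags, compounds = NULL,
                         extra_times = NULL, output_step = 6,
                         keep_states = FALSE) {
  cps <- if (is.null(compounds)) design$compounds else compounds
  nm <- vapply(cps, `[[`, character(1), "name")
  kp_key <- paste(nm, collapse = "+")
  if (is.null(.pkg_env$kp_cache)) .pkg_env$kp_cache <- list()
  if (is.null(.pkg_env$kp_cache[[kp_key]])) {
    .pkg_env$kp_cache[[kp_key]] <- setNames(lapply(cps, function(cp) {
      apply_kp_scalar(predict_kp(cp), cp$kp_scalar)
    }), nm)
  }
  model <- assemble_model(cps, phys, cl_override = design$cl_override,
                          prandial = design$prandial,
                          kp_sets = .pkg_env$kp_cache[[kp_key]])
  regs <- .resolve_regimens(design$regimens, keep = nm)
  simulate_pbpk(model, regs, t_end = design$duration_days * 24,
                output_step = output_step, extra_times = extra_times,
                lag_by_compound = lags, keep_states = keep_states)
}

#' Run a set of virtual trials
#'
#' Simulates `n_trials x n_subjects` individuals under the design's
#' regimens and summarises exposure per subject over the requested
#' interval (default: the last 24 h).
#'
#' @param design A `TrialDesign`.
#' @param interval Observation interval (h, length 2); default last
#'   24 h of the study.
#' @param profile_times Optional time grid (h) at which pooled profile
#'   summaries (mean, 5th/95th percentile) are returned.
#' @return List with `subjects` (per-subject `NCAMetrics` rows plus
#'   trial/age/weight/phenotype columns), `summary` (per-compound
#'   pooled mean/SD) and optional `profiles`.
#' @export
run_trial_set <- function(design, interval = NULL, profile_times = NULL) {
  stopifnot(inherits(design, "TrialDesign"))
  pop <- sample_population(design$population)
  lags <- .subject_lags(design, length(pop))
  t_end <- design$duration_days * 24
  if (is.null(interval)) interval <- c(t_end - 24, t_end)
  fine <- seq(interval[1], interval[2], by = 0.25)
  rows <- list()
  profs <- list()
  for (i in seq_along(pop)) {
    res <- .subject_sim(design, pop[[i]], lags[[i]],
                        extra_times = c(fine, profile_times))
    met <- do.call(rbind, lapply(colnames(res$conc), function(n) {
      summary_metrics(res, n, interval)
    }))
    met$subject_id <- pop[[i]]$subject_id
    met$trial <- pop[[i]]$trial
    met$age_y <- pop[[i]]$age_y
    met$weight_kg <- pop[[i]]$body_weight_kg
    met$phenotype <- pop[[i]]$phenotype
    rows[[i]] <- met
    if (!is.null(profile_times)) {
      idx <- match(profile_times, res$time)
      profs[[i]] <- res$conc[idx, , drop = FALSE]
    }
  }
  subjects <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(subjects, subjects$compound),
    function(d) data.frame(compound = d$compound[1],
                           n = nrow(d),
                           cavg_mean = mean(d$cavg), cavg_sd = sd(d$cavg),
                           cmax_mean = mean(d$cmax), cmin_mean = mean(d$cmin),
                           auc_mean = mean(d$auc))))
  out <- list(subjects = subjects, summary = summ, design = design)
  if (!is.null(profile_times)) {
    arr <- simplify2array(profs)  # time x compound x subject
    out$profiles <- list(
      time = profile_times,
      mean = apply(arr, c(1, 2), mean),
      p05 = apply(arr, c(1, 2), quantile, probs = 0.05),
      p95 = apply(arr, c(1, 2), quantile, probs = 0.95))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a two-phase drug-drug interaction study
#'
#' Within-subject two-arm design: every subject is simulated once with
#' the perpetrator regimen added after the baseline phase and once
#' without it (identical physiology, random effects and victim doses).
#' Troughs are sampled pre-dose at the end of the study in both arms,
#' so that approach to steady state cancels within subject; the
#' baseline-phase-end trough is also recorded. Trough concentrations
#' are dose-normalized to 1 mg/kg/day of the victim dose.
#'
#' @param design A `TrialDesign` whose regimens include the perpetrator
#'   (`perpetrator` compound name) starting at `baseline_days * 24` h.
#' @param perpetrator Compound name of the inhibitor (default "STP").
#' @param victims Compound names to report (default CLB and N-CLB).
#' @return Object of class `DDIResult`: per-subject data frame with
#'   control and inhibited dose-normalized troughs and their ratio, and
#'   a phenotype-stratified summary (mean, SD, 5th-95th percentiles).
#' @export
run_ddi_study <- function(design, perpetrator = "STP",
                          victims = c("CLB", "NCLB")) {
  stopifnot(inherits(design, "TrialDesign"))
  if (is.null(design$baseline_days)) {
    stop("DDI design needs baseline_days", call. = FALSE)
  }
  t_end <- design$duration_days * 24
  t_base <- design$baseline_days * 24
  if (t_base >= t_end) stop("baseline phase must end before the study",
                            call. = FALSE)
  # victim daily dose for normalization
  vict_reg <- Filter(function(r) r$compound == victims[1], design$regimens)
  if (!length(vict_reg)) stop("no victim regimen found", call. = FALSE)
  dose_per_day <- vict_reg[[1]]$dose_mg_per_kg * 24 / vict_reg[[1]]$interval_h
  pop <- sample_population(design$population)
  lags <- .subject_lags(design, length(pop))
  ctrl_compounds <- Filter(function(cp) cp$name != perpetrator,
                           design$compounds)
  troughs <- c(t_base, t_end) - 0.05
  rows <- list()
  for (i in seq_along(pop)) {
    res_inh <- .subject_sim(design, pop[[i]], lags[[i]],
                            extra_times = troughs)
    res_ctl <- .subject_sim(design, pop[[i]], lags[[i]],
                            compounds = ctrl_compounds,
                            extra_times = troughs)
    conc_at <- function(res, t, v) {
      res$conc[which.min(abs(res$time - t)), v]
    }
    for (v in victims) {
      cmin_ctl <- dose_normalize(conc_at(res_ctl, troughs[2], v), dose_per_day)
      cmin_inh <- dose_normalize(conc_at(res_inh, troughs[2], v), dose_per_day)
      cmin_base <- dose_normalize(conc_at(res_inh, troughs[1], v), dose_per_day)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = pop[[i]]$subject_id, trial = pop[[i]]$trial,
        age_y = pop[[i]]$age_y, weight_kg = pop[[i]]$body_weight_kg,
        phenotype = pop[[i]]$phenotype, compound = v,
        cmin_control = cmin_ctl, cmin_baseline_phase = cmin_base,
        cmin_inh = cmin_inh, cmin_ratio = cmin_inh / cmin_ctl)
    }
  }
  subjects <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(subjects, list(subjects$compound, subjects$phenotype),
          drop = TRUE),
    function(d) data.frame(
      compound = d$compound[1], phenotype = d$phenotype[1], n = nrow(d),
      cmin_control_mean = mean(d$cmin_control),
      cmin_inh_mean = mean(d$cmin_inh),
      cmin_inh_sd = sd(d$cmin_inh),
      cmin_ratio_mean = mean(d$cmin_ratio),
      cmin_ratio_sd = sd(d$cmin_ratio),
      cmin_ratio_p05 = unname(quantile(d$cmin_ratio, 0.05)),
      cmin_ratio_p95 = unname(quantile(d$cmin_ratio, 0.95)))))
  rownames(summ) <- NULL
  structure(list(subjects = subjects, summary = summ, design = design),
            class = "DDIResult")
}

#' Preset DDI replication designs
#'
#' Replicates the three published stiripentol add-on studies in
#' pediatric Dravet syndrome patients stabilised on clobazam:
#' \describe{
#'   \item{sticlo}{ages 3-16 y, CLB 0.5 mg/kg/day QD for 1 month, then
#'     STP 25 mg/kg BID added for 2 months.}
#'   \item{inoue}{Japanese trial, ages 1-24 y, CLB 1 mg/kg/day QD, STP
#'     25 mg/kg BID; 84-day phases so that poor metabolizers (N-CLB
#'     half-life 2-3 weeks) reach steady state.}
#'   \item{yamamoto}{retrospective Japanese cohort, ages 1-24 y, CLB
#'     1 mg/kg/day QD, STP 17.5 mg/kg BID; 84-day phases.}
#' }
#' The stiripentol clearance anchor is selected by the study's mean
#' age (about 9.5 y -> 8 L/h for all three).
#'
#' @param study One of "sticlo", "inoue", "yamamoto".
#' @param phenotype "EM", "PM" or "mixed" (3% PM).
#' @param seed Population seed.
#' @param n_trials,n_subjects Trial-set size (default 10 x 10).
#' @return A `TrialDesign`.
#' @export
ddi_preset <- function(study = c("sticlo", "inoue", "yamamoto"),
                       phenotype = c("EM", "PM", "mixed"), seed,
                       n_trials = 10, n_subjects = 10) {
  study <- match.arg(study)
  phenotype <- match.arg(phenotype)
  pm_freq <- switch(phenotype, EM = 0, PM = 1, mixed = 0.03)
  cfg <- switch(study,
    sticlo = list(ages = c(3, 16), clb = 0.5, stp_bid = 25,
                  baseline = 28, total = 84, mean_age = 9.5),
    inoue = list(ages = c(1, 24), clb = 1, stp_bid = 25,
                 baseline = 84, total = 168, mean_age = 9.6),
    yamamoto = list(ages = c(1, 24), clb = 1, stp_bid = 17.5,
                    baseline = 84, total = 168, mean_age = 9.6))
  pop <- population_spec(n_trials = n_trials, n_subjects = n_subjects,
                         age_range = cfg$ages, pm_frequency = pm_freq,
                         seed = seed)
  regs <- list(
    dose_regimen("CLB", dose_mg_per_kg = cfg$clb, interval_h = 24,
                 duration_days = cfg$total),
    dose_regimen("STP", dose_mg_per_kg = cfg$stp_bid, interval_h = 12,
                 start_h = cfg$baseline * 24,
                 duration_days = cfg$total - cfg$baseline,
                 prandial = "fed"))
  cl_stp <- stp_clpo_for_regimen(population = "pediatric",
                                 age = cfg$mean_age)
  trial_design(
    population = pop, regimens = regs,
    compounds = list(builtin_clobazam(), builtin_ndesmethylclobazam(),
                     builtin_stiripentol()),
    cl_override = list(STP = cl_stp),
    prandial = c(CLB = "fasted", NCLB = "fasted", STP = "fed"),
    duration_days = cfg$total, baseline_days = cfg$baseline)
}

#' Therapeutic reference windows (mg/L)
#'
#' CLB 0.03-0.3 (toxic > 3), N-CLB 0.3-3 (toxic > 12), STP effective
#' 4-25.
#' @export
therapeutic_windows <- function() {
  data.frame(compound = c("CLB", "NCLB", "STP"),
             lower = c(0.03, 0.3, 4), upper = c(0.3, 3, 25),
             toxic = c(3, 12, NA))
}

#' Extrapolate the dosing regimen to infants and toddlers
#'
#' Simulates the stiripentol add-on regimen (CLB 0.5 mg/kg/day QD plus
#' STP 50 mg/kg/day BID, stiripentol clearance anchor 14 L/h as in the
#' under-six reference group) in fixed-age groups below two years of
#' age, ten trials of ten subjects each with a 1:1 sex ratio, and
#' summarises steady-state average concentrations over the final dosing
#' interval.
#'
#' @param ages Age groups in years (default 0.5, 0.75, 1, 1.5, 2).
#' @param seed Seed shared by all age groups (common random numbers:
#'   the same subject-level random effects are reused at every age so
#'   that between-group comparisons isolate the age effect).
#' @param n_trials,n_subjects Trial-set size per age group.
#' @param duration_days Simulated duration (default 84 d).
#' @param clb_mg_per_kg_day,stp_mg_per_kg_day Daily doses.
#' @param stp_cl_anchor Stiripentol oral-clearance anchor, L/h.
#' @return List with `by_age` (mean/SD C_avg per compound per age, with
#'   therapeutic-window flags) and `subjects`.
#' @export
pediatric_extrapolation <- function(ages = c(0.5, 0.75, 1, 1.5, 2), seed,
                                    n_trials = 10, n_subjects = 10,
                                    duration_days = 84,
                                    clb_mg_per_kg_day = 0.5,
                                    stp_mg_per_kg_day = 50,
                                    stp_cl_anchor = 14) {
  if (any(ages < 0.5 | ages > 25)) {
    stop("unsupported age; supported range is 0.5-25 years", call. = FALSE)
  }
  all_subj <- list()
  for (a in ages) {
    pop <- population_spec(n_trials = n_trials, n_subjects = n_subjects,
                           age_range = c(a, a), prop_female = 0.5,
                           seed = seed)
    regs <- list(
      dose_regimen("CLB", dose_mg_per_kg = clb_mg_per_kg_day,
                   interval_h = 24, duration_days = duration_days),
      dose_regimen("STP", dose_mg_per_kg = stp_mg_per_kg_day / 2,
                   interval_h = 12, duration_days = duration_days,
                   prandial = "fed"))
    des <- trial_design(
      population = pop, regimens = regs,
      compounds = list(builtin_clobazam(), builtin_ndesmethylclobazam(),
                       builtin_stiripentol()),
      cl_override = list(STP = stp_cl_anchor),
      prandial = c(CLB = "fasted", NCLB = "fasted", STP = "fed"),
      duration_days = duration_days)
    ts <- run_trial_set(des)
    ts$subjects$age_group <- a
    all_subj[[as.character(a)]] <- ts$subjects
  }
  subjects <- do.call(rbind, all_subj)
  win <- therapeutic_windows()
  by_age <- do.call(rbind, lapply(
    split(subjects, list(subjects$age_group, subjects$compound),
          drop = TRUE),
    function(d) {
      w <- win[win$compound == d$compound[1], ]
      data.frame(age_group = d$age_group[1], compound = d$compound[1],
                 cavg_mean = mean(d$cavg), cavg_sd = sd(d$cavg),
                 within_window = mean(d$cavg) >= w$lower &
                   mean(d$cavg) <= w$upper,
                 above_toxic = !is.na(w$toxic) & mean(d$cavg) > w$toxic)
    }))
  rownames(by_age) <- NULL
  by_age <- by_age[order(by_age$compound, by_age$age_group), ]
  list(by_age = by_age, subjects = subjects)
}
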