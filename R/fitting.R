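#' Parameter-estimation specification
#'
#' Bounded least-squares fitting of model parameters to a
#' concentration-time dataset, with residuals on the log scale
#' (proportional-error assumption appropriate for concentrations
#' spanning orders of magnitude).
#'
#' @param par_names Names of the free parameters.
#' @param start Named start values.
#' @param lower,upper Named finite bounds.
#' @param predict_fn Function(named parameter vector, times) ->
#'   predicted concentrations at `times`.
#' @param data Data frame with columns `time_h` and `conc_mg_per_L`
#'   (positive for log residuals).
#' @param n_starts Number of multistart points (the given start plus
#'   `n_starts - 1` Latin-style random starts within the bounds).
#' @param seed Seed for the random restarts.
#' @return Object of class `FitSpec`.
#' @export
fit_spec <- function(par_names, start, lower, upper, predict_fn, data,
                     n_starts = 5, seed = 1) {
  stopifnot(length(start) == length(par_names),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper), nrow(data) >= 1,
            all(c("time_h", "conc_mg_per_L") %in% names(data)))
  if (any(data$conc_mg_per_L <= 0)) {
    stop("log-scale residuals need positive concentrations", call. = FALSE)
  }
  if (nrow(data) < 3 * length(par_names)) {
    stop("identifiability check failed: need >= 3 observations per free ",
         "parameter (", nrow(data), " obs, ", length(par_names),
         " parameters)", call. = FALSE)
  }
  structure(list(par_names = par_names, start = start, lower = lower,
                 upper = upper, predict_fn = predict_fn, data = data,
                 n_starts = n_starts, seed = as.integer(seed)),
            class = "FitSpec")
}

#' Fit model parameters to concentration data
#'
#' Bounded local optimisation (L-BFGS-B) of the sum of squared
#' log-concentration residuals, with multistart. Standard errors come
#' from the numeric Hessian of the objective at the optimum (residual
#' variance x inverse Hessian).
#'
#' @param spec A `FitSpec`.
#' @return List: `estimate` (named), `se` (named, may be NA), `sse`,
#'   `converged`, `starts` (per-start results), `predicted`.
#' @export
fit <- function(spec) {
  stopifnot(inherits(spec, "FitSpec"))
  obj <- function(p) {
    names(p) <- spec$par_names
    pred <- tryCatch(spec$predict_fn(p, spec$data$time_h),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred)) || any(pred <= 0)) {
      return(1e10)
    }
    sum((log(pred) - log(spec$data$conc_mg_per_L))^2)
  }
  set.seed(spec$seed)
  starts <- list(spec$start)
  for (i in seq_len(spec$n_starts - 1)) {
    starts[[i + 1]] <- spec$lower + runif(length(spec$lower)) *
      (spec$upper - spec$lower)
  }
  runs <- lapply(starts, function(s) {
    tryCatch(optim(s, obj, method = "L-BFGS-B", lower = spec$lower,
                   upper = spec$upper,
                   control = list(factr = 1e7, maxit = 200)),
             error = function(e) list(value = Inf, convergence = 99,
                                      par = s))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  est <- setNames(best$par, spec$par_names)
  # standard errors from the numeric Hessian of the SSE surface
  se <- rep(NA_real_, length(est))
  hess <- tryCatch(optimHess(est, obj), error = function(e) NULL)
  n <- nrow(spec$data)
  pdf <- n - length(est)
  if (!is.null(hess) && pdf > 0) {
    s2 <- best$value / pdf
    cov <- tryCatch(2 * s2 * solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se[d > 0] <- sqrt(d[d > 0])
    }
  }
  names(se) <- spec$par_names
  list(estimate = est, se = se, sse = best$value,
       converged = best$convergence == 0,
       starts = data.frame(
         start = seq_along(runs),
         sse = vapply(runs, `[[`, numeric(1), "value"),
         convergence = vapply(runs, `[[`, numeric(1), "convergence")),
       predicted = spec$predict_fn(est, spec$data$time_h))
}

#' @importFrom stats optimHess
NULL

#' Fit scenario: stiripentol oral clearance from a mean profile
#'
#' Frees CL_po; each evaluation back-calculates the enzyme-specific
#' intrinsic clearances in the reference adult and simulates the stated
#' regimen.
#'
#' @param data Concentration-time data frame (`time_h`,
#'   `conc_mg_per_L`).
#' @param dose_mg Dose per administration.
#' @param interval_h Dosing interval (24 for once daily).
#' @param duration_days Days of dosing.
#' @param start,lower,upper CL_po start and bounds (L/h).
#' @return A `FitSpec`.
#' @export
fit_scenario_stp_clpo <- function(data, dose_mg, interval_h = 12,
                                  duration_days = 7, start = 30,
                                  lower = 1, upper = 150) {
  stp <- builtin_stiripentol()
  ref <- reference_adult()
  predict_fn <- function(p, times) {
    m <- assemble_model(list(stp), ref, cl_override = list(STP = p[["cl_po"]]),
                        prandial = "fed")
    res <- simulate_pbpk(
      m, dose_regimen("STP", dose_mg = dose_mg, interval_h = interval_h,
                      duration_days = duration_days, prandial = "fed"),
      t_end = max(times) + 1, output_step = 1,
      extra_times = times, lag_by_compound = list(STP = 0.75))
    res$conc[match(times, res$time), "STP"]
  }
  fit_spec("cl_po", c(cl_po = start), c(cl_po = lower), c(cl_po = upper),
           predict_fn, data)
}

#' Fit scenario: clobazam fed-state absorption rate constant
#'
#' Frees ka on a single-dose fed profile (all other parameters at
#' their built-in values).
#'
#' @param data Concentration-time data frame.
#' @param dose_mg Single dose (default 20 mg).
#' @param start,lower,upper ka start and bounds (1/h).
#' @return A `FitSpec`.
#' @export
fit_scenario_clb_ka <- function(data, dose_mg = 20, start = 2,
                                lower = 0.1, upper = 10) {
  ref <- reference_adult()
  predict_fn <- function(p, times) {
    clb <- builtin_clobazam()
    clb$ka <- c(fed = p[["ka"]])
    m <- assemble_model(list(clb), ref, prandial = "fed")
    res <- simulate_pbpk(
      m, dose_regimen("CLB", dose_mg = dose_mg, interval_h = 24,
                      duration_days = 1, prandial = "fed"),
      t_end = max(times) + 1, output_step = 1, extra_times = times)
    res$conc[match(times, res$time), "CLB"]
  }
  fit_spec("ka", c(ka = start), c(ka = lower), c(ka = upper),
           predict_fn, data)
}
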