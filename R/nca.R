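#' Area under the concentration-time curve
#'
#' Piecewise trapezoid with the linear-up/log-down rule: ordinary
#' trapezoid on rising or flat segments, logarithmic trapezoid on
#' strictly descending segments with positive endpoints.
#'
#' @param times Strictly increasing sampling times, h.
#' @param concs Concentrations, mg/L (>= 0), same length.
#' @param method "linear-up/log-down" (default) or "linear".
#' @return AUC, mg*h/L.
#' @export
auc_trapezoid <- function(times, concs,
                          method = c("linear-up/log-down", "linear")) {
  method <- match.arg(method)
  if (length(times) < 2) stop("need at least 2 points", call. = FALSE)
  if (length(times) != length(concs)) stop("length mismatch", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (any(concs < 0)) stop("concentrations must be >= 0", call. = FALSE)
  dt <- diff(times)
  c1 <- concs[-length(concs)]
  c2 <- concs[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linear-up/log-down") {
    logdown <- c2 < c1 & c2 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown]) * dt[logdown]
  }
  sum(seg)
}

#' Terminal half-life by log-linear regression
#'
#' Fits the last `n_points` (>= 3) post-peak positive concentrations on
#' the log scale; flagged (NA) when fewer than 3 usable points or
#' r-squared < `min_r2`.
#'
#' @param times,concs Sampling times and concentrations.
#' @param n_points Number of terminal points to use.
#' @param min_r2 Minimum acceptable coefficient of determination.
#' @return List with `t_half` (h, possibly NA), `kel` (1/h) and `r2`.
#' @export
terminal_half_life <- function(times, concs, n_points = 3, min_r2 = 0.9) {
  imax <- which.max(concs)
  idx <- seq_along(times) > imax & concs > 0
  tt <- times[idx]; cc <- concs[idx]
  if (length(tt) < max(3, n_points)) {
    return(list(t_half = NA_real_, kel = NA_real_, r2 = NA_real_))
  }
  keep <- seq(length(tt) - n_points + 1, length(tt))
  fit <- lm(log(cc[keep]) ~ tt[keep])
  # noiseless simulated segments fit essentially perfectly; silence
  # the summary.lm note about it
  r2 <- suppressWarnings(summary(fit)$r.squared)
  kel <- -unname(coef(fit)[2])
  if (!is.finite(kel) || kel <= 0 || r2 < min_r2) {
    return(list(t_half = NA_real_, kel = NA_real_, r2 = r2))
  }
  list(t_half = log(2) / kel, kel = kel, r2 = r2)
}

#' Noncompartmental exposure metrics over an interval
#'
#' AUC (linear-up/log-down), C_max, T_max (ties -> earliest), C_min
#' (trough), C_avg = AUC_tau / tau, and the terminal half-life.
#'
#' @param result A `SimulationResult` (or a list with `time` and
#'   `conc`).
#' @param compound Column name in `result$conc`.
#' @param interval Length-2 numeric, h: the dosing interval to
#'   summarise.
#' @return Object of class `NCAMetrics` (a one-row data frame).
#' @export
summary_metrics <- function(result, compound, interval) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  sel <- result$time >= interval[1] - 1e-9 & result$time <= interval[2] + 1e-9
  if (sum(sel) < 2) {
    stop("interval [", interval[1], ", ", interval[2],
         "] h contains fewer than 2 samples", call. = FALSE)
  }
  tt <- result$time[sel]
  cc <- result$conc[sel, compound]
  tau <- interval[2] - interval[1]
  auc <- auc_trapezoid(tt, cc)
  th <- terminal_half_life(tt, cc)
  out <- data.frame(
    compound = compound, t_start = interval[1], t_end = interval[2],
    auc = auc, cmax = max(cc), tmax = tt[which.max(cc)],
    cmin = min(cc), cavg = auc / tau, t_half = th$t_half, r2 = th$r2
  )
  class(out) <- c("NCAMetrics", class(out))
  out
}

#' Dose-normalize an exposure metric
#'
#' Rescales a concentration metric to a reference daily dose of
#' 1 mg/kg/day (or any stated reference).
#'
#' @param metric Numeric metric value(s).
#' @param dose_mg_per_kg_per_day Administered daily dose, mg/kg/day.
#' @param reference Reference daily dose, mg/kg/day (default 1).
#' @export
dose_normalize <- function(metric, dose_mg_per_kg_per_day, reference = 1) {
  if (any(dose_mg_per_kg_per_day <= 0)) {
    stop("dose must be > 0", call. = FALSE)
  }
  metric * reference / dose_mg_per_kg_per_day
}
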