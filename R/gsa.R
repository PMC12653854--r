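#' Global sensitivity analysis specification
#'
#' @param params Data frame with columns `name`, `lower`, `upper`
#'   (finite, lower < upper).
#' @param outputs Character vector of output names the model wrapper
#'   returns (e.g., `c("auc", "cmax")`).
#' @param morris_r Number of Morris trajectories.
#' @param morris_levels Number of grid levels p (even).
#' @param sobol_n Sobol base sample size N (power of two recommended).
#' @param seed Random seed.
#' @return Object of class `GSASpec`.
#' @export
gsa_spec <- function(params, outputs = c("auc", "cmax"), morris_r = 20,
                     morris_levels = 4, sobol_n = 1024, seed = 1) {
  stopifnot(is.data.frame(params),
            all(c("name", "lower", "upper") %in% names(params)),
            all(is.finite(params$lower)), all(is.finite(params$upper)),
            all(params$lower < params$upper),
            morris_r >= 2, morris_levels >= 2, sobol_n >= 8)
  structure(list(params = params, outputs = outputs, morris_r = morris_r,
                 morris_levels = morris_levels, sobol_n = sobol_n,
                 seed = as.integer(seed)), class = "GSASpec")
}

.gsa_eval <- function(f, X, spec) {
  # X: matrix in unit cube, rows = design points; returns matrix
  # n x n_outputs with NA rows for failed evaluations
  k <- nrow(spec$params)
  lower <- spec$params$lower
  upper <- spec$params$upper
  out <- matrix(NA_real_, nrow(X), length(spec$outputs),
                dimnames = list(NULL, spec$outputs))
  fails <- 0L
  for (i in seq_len(nrow(X))) {
    x <- setNames(lower + X[i, ] * (upper - lower), spec$params$name)
    y <- tryCatch(f(x), error = function(e) NULL)
    if (is.null(y) || any(!is.finite(unlist(y[spec$outputs])))) {
      fails <- fails + 1L
    } else {
      out[i, ] <- unlist(y[spec$outputs])
    }
  }
  if (fails > 0.05 * nrow(X)) {
    warning(fails, " of ", nrow(X), " wrapper evaluations failed",
            call. = FALSE)
  }
  out
}

#' Morris elementary-effects screening
#'
#' Radial one-at-a-time trajectories on a p-level grid in the unit
#' cube; reports `mu_star` (mean absolute elementary effect) and
#' `sigma` (SD of elementary effects) per parameter per output.
#' Elementary effects are computed on the unit-cube scale so that
#' parameters with different units are comparable.
#'
#' @param f Deterministic model wrapper: named parameter vector ->
#'   named list/vector of outputs.
#' @param spec A `GSASpec`.
#' @return Object of class `GSAResult` (data frame: parameter, output,
#'   mu_star, sigma, n_effects).
#' @export
morris_screen <- function(f, spec) {
  stopifnot(inherits(spec, "GSASpec"))
  set.seed(spec$seed)
  k <- nrow(spec$params)
  p <- spec$morris_levels
  delta <- p / (2 * (p - 1))
  base_levels <- seq(0, 1 - delta, length.out = p / 2)
  X <- matrix(NA_real_, spec$morris_r * (k + 1), k)
  perms <- matrix(NA_integer_, spec$morris_r, k)
  dirs <- matrix(NA_real_, spec$morris_r, k)
  row <- 1L
  for (r in seq_len(spec$morris_r)) {
    x <- sample(base_levels, k, replace = TRUE)
    dir <- ifelse(x + delta <= 1, delta, -delta)
    # ensure steps stay inside the cube
    dir[x + dir > 1 | x + dir < 0] <- -dir[x + dir > 1 | x + dir < 0]
    perm <- sample.int(k)
    perms[r, ] <- perm
    dirs[r, ] <- dir
    X[row, ] <- x
    for (j in seq_len(k)) {
      x[perm[j]] <- x[perm[j]] + dir[perm[j]]
      X[row + j, ] <- x
    }
    row <- row + k + 1L
  }
  Y <- .gsa_eval(f, X, spec)
  res <- list()
  for (out_nm in spec$outputs) {
    ee <- matrix(NA_real_, spec$morris_r, k)
    row <- 1L
    for (r in seq_len(spec$morris_r)) {
      y <- Y[row:(row + k), out_nm]
      for (j in seq_len(k)) {
        pj <- perms[r, j]
        ee[r, pj] <- (y[j + 1] - y[j]) / dirs[r, pj]
      }
      row <- row + k + 1L
    }
    res[[out_nm]] <- data.frame(
      parameter = spec$params$name, output = out_nm,
      mu_star = apply(abs(ee), 2, mean, na.rm = TRUE),
      sigma = apply(ee, 2, sd, na.rm = TRUE),
      n_effects = colSums(!is.na(ee)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("GSAResult", class(out))
  out
}

#' Sobol variance-based sensitivity indices
#'
#' Saltelli-style sampling with the Saltelli-2010 first-order estimator
#' and the Jansen total-effect estimator:
#' `S1_i = mean(f(B) (f(AB_i) - f(A))) / V` and
#' `ST_i = mean((f(A) - f(AB_i))^2) / (2 V)`.
#' Bootstrap percentile confidence intervals over design rows.
#'
#' @param f Deterministic model wrapper (see [morris_screen()]).
#' @param spec A `GSASpec`.
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @return Object of class `GSAResult` (data frame: parameter, output,
#'   s1, st, ci bounds).
#' @export
sobol_indices <- function(f, spec, n_boot = 100) {
  stopifnot(inherits(spec, "GSASpec"))
  set.seed(spec$seed)
  k <- nrow(spec$params)
  n <- spec$sobol_n
  A <- matrix(runif(n * k), n, k)
  B <- matrix(runif(n * k), n, k)
  X <- rbind(A, B)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    X <- rbind(X, ABi)
  }
  Y <- .gsa_eval(f, X, spec)
  res <- list()
  for (out_nm in spec$outputs) {
    yA <- Y[seq_len(n), out_nm]
    yB <- Y[n + seq_len(n), out_nm]
    ok <- is.finite(yA) & is.finite(yB)
    for (i in seq_len(k)) {
      ok <- ok & is.finite(Y[(1 + i) * n + seq_len(n), out_nm])
    }
    est <- function(idx) {
      V <- var(c(yA[idx], yB[idx]))
      m <- mean(c(yA[idx], yB[idx]))  # centering reduces estimator noise
      t(vapply(seq_len(k), function(i) {
        yAB <- Y[(1 + i) * n + seq_len(n), out_nm][idx]
        c(s1 = mean((yB[idx] - m) * (yAB - yA[idx])) / V,
          st = mean((yA[idx] - yAB)^2) / (2 * V))
      }, numeric(2)))
    }
    point <- est(which(ok))
    boot <- array(NA_real_, c(k, 2, n_boot))
    for (b in seq_len(n_boot)) {
      boot[, , b] <- est(sample(which(ok), sum(ok), replace = TRUE))
    }
    res[[out_nm]] <- data.frame(
      parameter = spec$params$name, output = out_nm,
      s1 = point[, 1], st = point[, 2],
      s1_lo = apply(boot[, 1, , drop = FALSE], 1, quantile, 0.025),
      s1_hi = apply(boot[, 1, , drop = FALSE], 1, quantile, 0.975),
      st_lo = apply(boot[, 2, , drop = FALSE], 1, quantile, 0.025),
      st_hi = apply(boot[, 2, , drop = FALSE], 1, quantile, 0.975))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("GSAResult", class(out))
  out
}

.range_pm <- function(x, frac = 0.3, cap01 = FALSE) {
  lo <- x * (1 - frac)
  hi <- x * (1 + frac)
  if (cap01) hi <- min(hi, 1)
  c(lo, hi)
}

#' Single-subject GSA wrapper for the clobazam model
#'
#' Evaluates AUC(0-24 h) and C_max of a single oral dose in the
#' reference adult while varying pKa, B/P, logP, fu,p, fa, ka and
#' fu,gut. The whole-liver intrinsic clearance is held at its
#' baseline-derived value so that plasma-binding changes propagate to
#' hepatic clearance the way the well-stirred model dictates.
#'
#' @param dose_mg Single dose (default 20 mg).
#' @return List with `f` (the wrapper) and `spec` (a `GSASpec` with
#'   the default +/-30% ranges, pKa +/-1 unit, fractions capped at 1).
#' @export
gsa_wrapper_clb <- function(dose_mg = 20) {
  base <- builtin_clobazam()
  ref <- reference_adult()
  rc <- reference_clint(base, ref)
  params <- data.frame(
    name = c("pka", "bp", "logp", "fup", "fa", "ka", "fugut"),
    lower = c(base$pka - 1, .range_pm(base$bp)[1], .range_pm(base$logp)[1],
              .range_pm(base$fup)[1], .range_pm(base$fa)[1],
              .range_pm(2.11)[1], .range_pm(base$fugut)[1]),
    upper = c(base$pka + 1, .range_pm(base$bp)[2], .range_pm(base$logp)[2],
              .range_pm(base$fup)[2], .range_pm(base$fa, cap01 = TRUE)[2],
              .range_pm(2.11)[2], .range_pm(base$fugut, cap01 = TRUE)[2]))
  f <- function(x) {
    cp <- base
    cp$pka <- x[["pka"]]; cp$bp <- x[["bp"]]; cp$logp <- x[["logp"]]
    cp$fup <- x[["fup"]]; cp$fa <- x[["fa"]]
    cp$ka <- c(fasted = x[["ka"]]); cp$fugut <- x[["fugut"]]
    # hold the ionisation family at the baseline (moderate base) so a
    # pKa sweep across 7 does not switch equation families mid-design
    kp <- apply_kp_scalar(predict_kp(cp, family = "moderate"),
                          cp$kp_scalar)
    m <- assemble_model(list(cp), ref, clint_override = list(
      CLB = list(clint = rc$clint, residual = rc$residual)),
      kp_sets = list(CLB = kp))
    res <- simulate_pbpk(m, dose_regimen("CLB", dose_mg = dose_mg,
                                         interval_h = 24, duration_days = 1),
                         t_end = 96, output_step = 0.25)
    met <- summary_metrics(res, "CLB", c(0, 24))
    list(auc = met$auc, cmax = max(res$conc[, "CLB"]))
  }
  list(f = f, spec = gsa_spec(params))
}

#' Single-subject GSA wrapper for the stiripentol model
#'
#' Evaluates AUC(0-24 h) and C_max of a single oral dose (default
#' 1000 mg, clearance anchor 35 L/h) in the reference adult while
#' varying fa, fu,gut, ka and the Kp scalar.
#'
#' @param dose_mg Single dose (default 1000 mg).
#' @return List with `f` and `spec` as in [gsa_wrapper_clb()].
#' @export
gsa_wrapper_stp <- function(dose_mg = 1000) {
  base <- builtin_stiripentol()
  ref <- reference_adult()
  cl <- stp_clpo_for_regimen(dose_mg = dose_mg, schedule = "single",
                             population = "adult")
  rc <- reference_clint(base, ref, cl_hepatic_plasma = cl)
  params <- data.frame(
    name = c("fa", "fugut", "ka", "kp_scalar"),
    lower = c(.range_pm(base$fa)[1], .range_pm(base$fugut)[1],
              .range_pm(1.4)[1], .range_pm(base$kp_scalar)[1]),
    upper = c(.range_pm(base$fa, cap01 = TRUE)[2],
              .range_pm(base$fugut, cap01 = TRUE)[2],
              .range_pm(1.4)[2], .range_pm(base$kp_scalar)[2]))
  kp0 <- predict_kp(base)
  f <- function(x) {
    cp <- base
    cp$fa <- x[["fa"]]; cp$fugut <- x[["fugut"]]
    cp$ka <- c(fed = x[["ka"]]); cp$kp_scalar <- x[["kp_scalar"]]
    m <- assemble_model(list(cp), ref, prandial = "fed",
                        clint_override = list(STP = list(
                          clint = rc$clint, residual = rc$residual)),
                        kp_sets = list(STP = apply_kp_scalar(
                          kp0, x[["kp_scalar"]])))
    res <- simulate_pbpk(m, dose_regimen("STP", dose_mg = dose_mg,
                                         interval_h = 24, duration_days = 1,
                                         prandial = "fed"),
                         t_end = 96, output_step = 0.25,
                         lag_by_compound = list(STP = 0.75))
    met <- summary_metrics(res, "STP", c(0, 24))
    list(auc = met$auc, cmax = max(res$conc[, "STP"]))
  }
  list(f = f, spec = gsa_spec(params))
}
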