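# forward map shared by the estimators: victim interaction metric as a
# function of a single scale factor applied to the in vitro Ki map (the
# OATP1B1:OATP1B3 ratio is preserved; a one-dimensional search is the
# identifiable choice). The inhibitor profile is precomputed once.
.ki_forward <- function(victim, phys, iu_fun, ki_ref, window, dt = 0.1) {
  t_end <- window[2]
  ctrl <- .victim_arm(victim, phys, t_end, iu_fun = NULL, ki = NULL, dt = dt)
  m_ctrl <- exposure_metrics(ctrl, window)
  function(ki1, metric = "AUCR", return_profile = FALSE) {
    ki <- ki_ref / ki_ref[["OATP1B1"]] * ki1
    trt <- .victim_arm(victim, phys, t_end, iu_fun = iu_fun, ki = ki,
                       dt = dt)
    if (return_profile) return(trt)
    m_trt <- exposure_metrics(trt, window)
    if (metric == "AUCR") m_trt$auc / m_ctrl$auc
    else m_trt$cmax / m_ctrl$cmax
  }
}

.new_ki_estimate <- function(ki1, ki_ref, objective, fe_assumed, convergence,
                             observed = NA_real_, metric = NA_character_) {
  ki_map <- ki_ref / ki_ref[["OATP1B1"]] * ki1
  structure(
    list(ki_in_vivo = ki1, ki_map = ki_map, objective = objective,
         fe_assumed = fe_assumed, convergence = convergence,
         observed = observed, metric = metric),
    class = "ki_estimate"
  )
}

#' @export
print.ki_estimate <- function(x, ...) {
  cat("<ki_estimate>\n")
  cat(sprintf("  OATP1B1 Ki %.4g uM (%s, fe assumed %s)\n", x$ki_in_vivo,
              x$objective,
              if (is.na(x$fe_assumed)) "model default" else
                format(x$fe_assumed)))
  cat(sprintf("  map: %s\n", paste(sprintf("%s %.4g", names(x$ki_map),
                                           x$ki_map), collapse = ", ")))
  cat(sprintf("  residual %.3g after %s evaluations%s\n",
              x$convergence$residual, x$convergence$iterations,
              if (isTRUE(x$convergence$non_identifiable))
                " [NON-IDENTIFIABLE]" else ""))
  invisible(x)
}

#' Estimate in vivo OATP1B Ki from an observed interaction ratio
#'
#' Inverts the forward interaction model: finds the single scale factor on
#' the inhibitor's in vitro Ki map (OATP1B1:OATP1B3 ratio fixed) such that
#' the simulated CmaxR or AUCR matches the observation. Bisection on log Ki
#' over `[1e-6, 1e4]` uM, matching to within 1e-4 relative.
#'
#' @param observed_ratio Observed interaction ratio (> 1).
#' @param metric `"AUCR"` or `"CmaxR"`.
#' @param victim Calibrated endogenous [victim_params()].
#' @param inhibitor An [inhibitor_params()] supplying the in vitro Ki map.
#' @param regimen Inhibitor [dosing_regimen()].
#' @param phys A [physiology_ref()].
#' @param window Metric window (h).
#' @param fe_assumed Optional renal fraction; when given the victim is first
#'   repartitioned via [repartition_clearance()].
#' @param dt Victim grid (h).
#' @return A `ki_estimate`; see [tidy.ki_estimate()].
#' @export
#' @examples
#' \donttest{
#' v <- calibrate_victim(cpi_victim(), physiology_ref(), fe = 0.10)
#' rif <- example_inhibitor("rifampicin-like")
#' estimate_ki_from_ratio(2.0, "AUCR", v, rif, dosing_regimen(600, 24, 1))
#' }
estimate_ki_from_ratio <- function(observed_ratio, metric = c("AUCR", "CmaxR"),
                                   victim, inhibitor, regimen,
                                   phys = physiology_ref(),
                                   window = c(0, 24), fe_assumed = NULL,
                                   dt = 0.1) {
  metric <- match.arg(metric)
  if (observed_ratio <= 1) {
    abort("observed_ratio must exceed 1",
          class = "coprokin_invalid_parameter")
  }
  if (!is.null(fe_assumed)) {
    victim <- repartition_clearance(victim, phys, fe_assumed)
  }
  bl <- solve_baseline(victim, phys)
  ceiling_static <- 1 / (bl$fe + bl$ft_passive)
  if (observed_ratio >= ceiling_static) {
    abort(sprintf(
      "observed ratio %.3g is at or above the attainable ceiling 1/(1 - sum ft_inhibitable) = %.3g",
      observed_ratio, ceiling_static),
      class = "coprokin_infeasible_observation")
  }
  iu_fun <- .iu_analytic_fun(inhibitor, regimen, phys)
  forward <- .ki_forward(victim, phys, iu_fun, inhibitor$ki, window, dt)
  n_eval <- 0L
  f <- function(log_ki) {
    n_eval <<- n_eval + 1L
    log(forward(exp(log_ki), metric) / observed_ratio)
  }
  lo <- log(1e-6)
  hi <- log(1e4)
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (f_lo < 0 || f_hi > 0) {
    abort(sprintf(
      "no root: simulated %s spans [%.4g, %.4g] over the Ki bracket but %.4g was observed (dynamic ceiling %.4g, static ceiling %.4g)",
      metric, exp(f_hi) * observed_ratio, exp(f_lo) * observed_ratio,
      observed_ratio, exp(f_lo) * observed_ratio, ceiling_static),
      class = "coprokin_infeasible_observation")
  }
  root <- uniroot(f, c(lo, hi), f.lower = f_lo, f.upper = f_hi, tol = 1e-10)
  ki1 <- exp(root$root)
  resid <- abs(exp(f(root$root)) - 1)
  if (resid > 1e-4) {
    abort("ratio match did not reach 1e-4 relative tolerance",
          class = "coprokin_calibration_failure")
  }
  .new_ki_estimate(ki1, inhibitor$ki,
                   objective = if (metric == "AUCR") "aucr_match"
                   else "cmaxr_match",
                   fe_assumed = if (is.null(fe_assumed)) NA_real_
                   else fe_assumed,
                   convergence = list(iterations = n_eval, residual = resid,
                                      non_identifiable = FALSE),
                   observed = observed_ratio, metric = metric)
}

#' Repartition elimination between renal and hepatic routes
#'
#' Changes the assumed renal elimination fraction while holding the total
#' baseline plasma clearance (hence the baseline concentration) fixed: sets
#' `CL_R = fe_new x CL_total` and recalibrates the hepatic scaler so the
#' baseline is unchanged.
#'
#' @param victim Calibrated endogenous [victim_params()].
#' @param phys A [physiology_ref()].
#' @param fe_new New renal fraction in `[0, 1)`.
#' @return The repartitioned, recalibrated `victim_params`.
#' @export
#' @examples
#' \donttest{
#' v <- calibrate_victim(cpi_victim(), physiology_ref(), fe = 0.10)
#' v0 <- repartition_clearance(v, physiology_ref(), 0)
#' solve_baseline(v0, physiology_ref())$css_nM # unchanged
#' }
repartition_clearance <- function(victim, phys, fe_new) {
  if (fe_new < 0 || fe_new >= 1) {
    abort("fe_new must lie in [0, 1)", class = "coprokin_invalid_parameter")
  }
  bl <- solve_baseline(victim, phys)
  v <- victim
  v$cl_renal_plasma <- fe_new * bl$cl_total_plasma
  calibrate_victim(v, phys, css = bl$css_nM)
}

#' Sensitivity of the Ki estimate to the assumed renal fraction
#'
#' For each renal fraction on the grid: repartition the victim's
#' elimination, re-estimate the in vivo Ki from the same observed ratio,
#' then forward-predict the interaction of a downstream dosed victim with
#' that Ki.
#'
#' @inheritParams estimate_ki_from_ratio
#' @param fe_grid Renal fractions within `[0, 0.5]`.
#' @param downstream_victim Dosed [victim_params()] whose AUCR is predicted
#'   with each estimated Ki (default [statin_like_victim()]).
#' @param downstream_regimen [dosing_regimen()] for the downstream victim.
#' @param downstream_window AUC window for the downstream victim (h).
#' @return A tibble of class `fe_sensitivity` with `fe`, `ki_oatp1b1_uM`,
#'   `downstream_aucr`.
#' @export
fe_sensitivity <- function(observed_ratio, metric = c("AUCR", "CmaxR"),
                           victim, inhibitor, regimen,
                           phys = physiology_ref(), window = c(0, 24),
                           fe_grid = c(0, 0.05, 0.10, 0.15),
                           downstream_victim = statin_like_victim(),
                           downstream_regimen = dosing_regimen(10, 24, 1),
                           downstream_window = c(0, 24)) {
  metric <- match.arg(metric)
  if (any(fe_grid < 0 | fe_grid > 0.5)) {
    abort("fe_grid must lie within [0, 0.5]",
          class = "coprokin_invalid_parameter")
  }
  rows <- purrr::map(fe_grid, function(fe) {
    est <- estimate_ki_from_ratio(observed_ratio, metric, victim, inhibitor,
                                  regimen, phys, window, fe_assumed = fe)
    ddi <- simulate_ddi(downstream_victim, inhibitor, regimen, phys,
                        window = downstream_window,
                        victim_regimen = downstream_regimen,
                        ki_override = est$ki_map)
    tibble(fe = fe, ki_oatp1b1_uM = est$ki_in_vivo,
           downstream_aucr = ddi$metrics$auc_ratio)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fe_sensitivity", class(out))
  out
}

#' Estimate in vivo Ki from a biomarker concentration profile
#'
#' Least-squares fit on log concentrations: finds the Ki scale minimizing
#' the sum of squared log residuals between observed treatment-arm CP-I
#' concentrations and model predictions. Complements the ratio-matching
#' estimator for synthetic-data power studies. A flat objective (e.g.
#' inhibitor dose 0) is flagged non-identifiable with a warning.
#'
#' @param profile Data frame with columns `time_h` and `conc_nM` (treatment
#'   arm observations; at least 3 points).
#' @inheritParams estimate_ki_from_ratio
#' @return A `ki_estimate`; `convergence` carries the residual sum of
#'   squares, an approximate curvature-based standard error of log10 Ki, and
#'   the non-identifiability flag.
#' @export
estimate_ki_from_profile <- function(profile, victim, inhibitor, regimen,
                                     phys = physiology_ref(),
                                     fe_assumed = NULL, dt = 0.1) {
  if (nrow(profile) < 3) {
    abort("at least 3 observation times are required",
          class = "coprokin_invalid_parameter")
  }
  if (!is.null(fe_assumed)) {
    victim <- repartition_clearance(victim, phys, fe_assumed)
  }
  t_end <- max(profile$time_h,
               regimen$start_time + regimen$interval * regimen$n_doses)
  iu_fun <- .iu_analytic_fun(inhibitor, regimen, phys)
  forward <- .ki_forward(victim, phys, iu_fun, inhibitor$ki,
                         window = c(0, t_end), dt = dt)
  obs_log <- log(profile$conc_nM)
  ssr <- function(log10_ki) {
    trt <- forward(10^log10_ki, return_profile = TRUE)
    pred <- approxfun(trt$time_h, trt$conc_plasma_nM)(profile$time_h)
    sum((obs_log - log(pred))^2)
  }
  probe <- vapply(c(-6, -3, 0, 2, 4), ssr, numeric(1))
  if (diff(range(probe)) < 1e-10 * (1 + max(probe))) {
    warn("objective is flat in Ki: profile carries no inhibition information")
    return(.new_ki_estimate(
      NA_real_, inhibitor$ki, objective = "profile_lsq",
      fe_assumed = if (is.null(fe_assumed)) NA_real_ else fe_assumed,
      convergence = list(iterations = length(probe), residual = probe[1],
                         se_log10_ki = NA_real_, non_identifiable = TRUE)))
  }
  opt <- optimize(ssr, c(-6, 4), tol = 1e-6)
  log10_ki <- opt$minimum
  # curvature-based SE of log10 Ki: residual variance over half the second
  # derivative of the sum of squares
  h <- 0.05
  d2 <- (ssr(log10_ki + h) - 2 * opt$objective + ssr(log10_ki - h)) / h^2
  sigma2 <- opt$objective / max(nrow(profile) - 1, 1)
  se <- if (d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  .new_ki_estimate(
    10^log10_ki, inhibitor$ki, objective = "profile_lsq",
    fe_assumed = if (is.null(fe_assumed)) NA_real_ else fe_assumed,
    convergence = list(iterations = NA_integer_, residual = opt$objective,
                       se_log10_ki = se, non_identifiable = FALSE))
}

#' Closed-form static Ki solve at constant exposure
#'
#' Inverts the static extended-clearance ratio ([static_aucr()]) for the
#' common Iu/Ki ratio: given an observed AUC ratio, a renal fraction and a
#' constant unbound exposure, returns the implied Ki (same value applied to
#' both OATP1B transporters). Used as the analytic oracle for the
#' renal-fraction sensitivity of Ki estimates.
#'
#' @param observed_aucr Observed ratio (> 1).
#' @param victim A [victim_params()] supplying the pathway split.
#' @param fe Renal fraction.
#' @param iu Constant unbound inhibitor concentration (uM).
#' @return Ki (uM).
#' @export
#' @examples
#' static_ki_solve(4.6, cpi_victim(), fe = 0) /
#'   static_ki_solve(4.6, cpi_victim(), fe = 0.15) # ~3.4-fold
static_ki_solve <- function(observed_aucr, victim, fe, iu = 1) {
  ft <- compute_ft(victim, fe)
  ft_inh <- sum(ft[names(victim$cl_uptake_per_cell)])
  ceiling_static <- 1 / (1 - ft_inh)
  if (observed_aucr <= 1 || observed_aucr >= ceiling_static) {
    abort(sprintf("observed_aucr must lie in (1, %.4g)", ceiling_static),
          class = "coprokin_infeasible_observation")
  }
  # 1/AUCR = ft_inh/(1 + iu/ki) + 1 - ft_inh
  r <- ft_inh / (1 / observed_aucr - (1 - ft_inh)) - 1
  iu / r
}
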