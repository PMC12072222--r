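#' Competitively inhibited intrinsic clearance
#'
#' `CLint / (1 + Iu/Ki)`.
#'
#' @param clint Intrinsic clearance (any units).
#' @param iu Unbound inhibitor concentration (uM).
#' @param ki Inhibition constant (uM).
#' @return Inhibited clearance, same units as `clint`.
#' @export
#' @examples
#' inhibited_clint(100, iu = 1, ki = 1) # halved
inhibited_clint <- function(clint, iu, ki) {
  if (any(ki <= 0)) abort("ki must be positive",
                          class = "coprokin_invalid_parameter")
  if (any(iu < 0)) abort("iu must be nonnegative",
                         class = "coprokin_invalid_parameter")
  clint / (1 + iu / ki)
}

#' Exposure metrics over a window
#'
#' Cmax (grid maximum), Tmax (time attaining it) and trapezoidal AUC over a
#' time window of a concentration-time table.
#'
#' @param data A data frame with a time column and a concentration column.
#' @param window Length-2 numeric `(start, end)` in hours.
#' @param time_col,conc_col Column names.
#' @return A one-row tibble with `cmax`, `tmax_h`, `auc`.
#' @export
#' @examples
#' exposure_metrics(tibble::tibble(time_h = 0:24, conc = 1), c(0, 24),
#'                  conc_col = "conc")
exposure_metrics <- function(data, window, time_col = "time_h",
                             conc_col = "conc_plasma_nM") {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("window must be (start, end) with start < end",
          class = "coprokin_invalid_parameter")
  }
  t <- data[[time_col]]
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 2) {
    abort("simulation grid does not cover the window",
          class = "coprokin_invalid_parameter")
  }
  t <- t[keep]
  conc <- data[[conc_col]][keep]
  i <- which.max(conc)
  tibble(cmax = conc[i], tmax_h = t[i], auc = pracma::trapz(t, conc))
}

# victim metrics for a given iu forcing; shared by simulate_ddi and the Ki
# estimators (which precompute the inhibitor profile once)
.victim_arm <- function(victim, phys, t_end, iu_fun, ki, regimen = NULL,
                        dt = 0.1) {
  init <- if (is.null(regimen)) "steady_state" else "zero"
  simulate_victim(victim, phys, t_end, init = init, iu_fun = iu_fun,
                  ki = ki, regimen = regimen, dt = dt)
}

#' Simulate a control/treatment drug-biomarker interaction
#'
#' Runs the victim model twice from an identical initial state — a control
#' arm without inhibitor and a treatment arm driven by the unbound
#' liver-inlet concentration of the perpetrator — and reports CmaxR and AUCR
#' over the requested window. Endogenous victims (CP-I) start at their
#' baseline steady state and must be calibrated; dosed victims start empty
#' and receive `victim_regimen` in both arms.
#'
#' @param victim A [victim_params()].
#' @param inhibitor An [inhibitor_params()].
#' @param regimen Inhibitor [dosing_regimen()].
#' @param phys A [physiology_ref()].
#' @param window Metric window `(start, end)` in hours (for single-dose
#'   designs the inhibitor dosing day; for multiple-dose the steady-state
#'   day).
#' @param victim_regimen Optional [dosing_regimen()] for a dosed victim.
#' @param t_end Simulation end (h); defaults to covering regimen and window.
#' @param dt Victim output grid (h).
#' @param ki_override Optional named Ki vector (uM) replacing the
#'   inhibitor's, e.g. in vivo estimates.
#' @param driver Inhibition driver: dynamic unbound liver-inlet
#'   concentration (default; OATP1B uptake faces portal blood) or the
#'   systemic unbound concentration for sensitivity checks.
#' @return An object of class `ddi_outcome`: list with `metrics` (one-row
#'   tibble: `cmax_ratio`, `auc_ratio`, `tmax_biomarker_h`, window),
#'   `control_metrics`, `treatment_metrics`, and `profiles` (long tibble of
#'   both arms).
#' @export
#' @examples
#' \donttest{
#' v <- calibrate_victim(cpi_victim(), physiology_ref(), fe = 0.10)
#' out <- simulate_ddi(v, example_inhibitor("rifampicin-like"),
#'                     dosing_regimen(600, 24, 1), physiology_ref(), c(0, 24))
#' tidy(out)
#' }
simulate_ddi <- function(victim, inhibitor, regimen, phys = physiology_ref(),
                         window = c(0, 24), victim_regimen = NULL,
                         t_end = NULL, dt = 0.1, ki_override = NULL,
                         driver = c("inlet", "systemic")) {
  driver <- match.arg(driver)
  endogenous <- victim$k_syn > 0
  if (endogenous && !is.null(victim_regimen)) {
    abort("victim has both endogenous synthesis and a dosing regimen",
          class = "coprokin_ambiguous_victim")
  }
  if (endogenous && !isTRUE(victim$calibrated)) {
    abort("victim baseline must be calibrated before interaction simulation (see calibrate_victim())",
          class = "coprokin_precondition")
  }
  if (is.null(t_end)) {
    t_end <- max(window[2],
                 regimen$start_time + regimen$interval * regimen$n_doses)
  }
  iu_fun <- .iu_analytic_fun(inhibitor, regimen, phys,
                             inlet = driver == "inlet")
  ki <- if (is.null(ki_override)) inhibitor$ki else ki_override
  ctrl <- .victim_arm(victim, phys, t_end, iu_fun = NULL, ki = NULL,
                      regimen = victim_regimen, dt = dt)
  trt <- .victim_arm(victim, phys, t_end, iu_fun = iu_fun, ki = ki,
                     regimen = victim_regimen, dt = dt)
  m_ctrl <- exposure_metrics(ctrl, window)
  m_trt <- exposure_metrics(trt, window)
  metrics <- tibble(
    cmax_ratio = m_trt$cmax / m_ctrl$cmax,
    auc_ratio = m_trt$auc / m_ctrl$auc,
    tmax_biomarker_h = m_trt$tmax_h,
    window_start_h = window[1], window_end_h = window[2]
  )
  profiles <- dplyr::bind_rows(
    dplyr::mutate(ctrl[, c("time_h", "conc_plasma_nM")], arm = "control"),
    dplyr::mutate(trt[, c("time_h", "conc_plasma_nM")], arm = "treatment")
  )
  structure(
    list(metrics = metrics, control_metrics = m_ctrl,
         treatment_metrics = m_trt, profiles = profiles, window = window,
         victim = victim$name, inhibitor = inhibitor$name,
         dose_mg = regimen$dose),
    class = "ddi_outcome"
  )
}

#' @export
print.ddi_outcome <- function(x, ...) {
  cat(sprintf("<ddi_outcome> %s + %s %g mg\n", x$victim, x$inhibitor,
              x$dose_mg))
  cat(sprintf("  window %g-%g h:  CmaxR %.3f  AUCR %.3f  Tmax %.2f h\n",
              x$window[1], x$window[2], x$metrics$cmax_ratio,
              x$metrics$auc_ratio, x$metrics$tmax_biomarker_h))
  invisible(x)
}

#' Static extended-clearance interaction ratio
#'
#' The steady-state AUC ratio implied by intrinsic-clearance shares under a
#' constant unbound inhibitor exposure:
#' `1 / (sum_T ft_T/(1 + Iu/Ki_T) + 1 - sum_T ft_T)`. Valid when hepatic
#' elimination is far from the blood-flow limit; for flow-limited victims it
#' is an upper bound on the dynamic ratio.
#'
#' @param victim A [victim_params()].
#' @param fe Renal elimination fraction used for the pathway split.
#' @param iu Constant unbound inhibitor concentration (uM).
#' @param ki Named Ki vector (uM) per transporter.
#' @return The static AUC ratio.
#' @export
#' @examples
#' static_aucr(cpi_victim(), fe = 0.10, iu = 1,
#'             ki = c(OATP1B1 = 1, OATP1B3 = 1))
static_aucr <- function(victim, fe, iu, ki) {
  ft <- compute_ft(victim, fe)
  trs <- names(victim$cl_uptake_per_cell)
  inhibited <- sum(vapply(trs, function(tr) {
    k <- if (tr %in% names(ki)) ki[[tr]] else Inf
    ft[[tr]] / (1 + iu / k)
  }, numeric(1)))
  1 / (inhibited + 1 - sum(ft[trs]))
}
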