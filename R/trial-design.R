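# potency classes: target ratio of maximal unbound inlet concentration to Ki
.POTENCY_RATIO <- c(weak = 0.5, moderate = 3, strong = 20)
# half-life classes via systemic clearance at V = 115 L
.THALF_CL <- c(short = 20, long = 2.66) # L/h -> t1/2 ~4 h and ~30 h

#' Construct a virtual OATP1B inhibitor scenario
#'
#' Builds one cell of the potency x half-life grid used to compare CmaxR and
#' AUCR as biomarker monitoring metrics: a one-compartment oral inhibitor
#' (fu 0.1, ka 1/h, V 115 L; CL 20 L/h for a ~4 h half-life or 2.66 L/h for
#' ~30 h), dosed once daily to steady state, with the dose chosen so the
#' steady-state maximal unbound liver-inlet concentration over Ki hits the
#' class ratio (weak 0.5, moderate 3, strong 20).
#'
#' @param potency_class `"weak"`, `"moderate"` or `"strong"`.
#' @param t_half_class `"short"` or `"long"`.
#' @param ki Common OATP1B1/1B3 inhibition constant (uM).
#' @param phys A [physiology_ref()].
#' @return An object of class `virtual_inhibitor_scenario` with elements
#'   `potency_class`, `t_half_class`, `params`, `regimen`.
#' @export
#' @examples
#' \donttest{
#' virtual_inhibitor("strong", "short")
#' }
virtual_inhibitor <- function(potency_class = c("weak", "moderate", "strong"),
                              t_half_class = c("short", "long"),
                              ki = 1, phys = physiology_ref()) {
  potency_class <- match.arg(potency_class)
  t_half_class <- match.arg(t_half_class)
  params <- inhibitor_params(
    name = sprintf("virtual %s/%s-t1/2 inhibitor", potency_class,
                   t_half_class),
    molecular_weight = 500, fu_plasma = 0.1, blood_plasma_ratio = 1,
    ka = 1, f_abs = 1, cl_over_f = .THALF_CL[[t_half_class]],
    v_central = 115,
    ki = c(OATP1B1 = ki, OATP1B3 = ki), ki_source = "in_vitro")
  n_doses <- ceiling(7 * half_life(params) / 24) + 5
  probe_dose <- 100
  regimen <- dosing_regimen(probe_dose, 24, n_doses)
  t_end <- regimen$interval * n_doses
  prof <- simulate_inhibitor_pk(params, regimen, t_end, phys)
  ss_day <- prof$time_h >= (n_doses - 1) * 24
  iu_max_unit <- max(prof$conc_inlet_unbound_uM[ss_day])
  dose <- probe_dose * .POTENCY_RATIO[[potency_class]] * ki / iu_max_unit
  structure(
    list(potency_class = potency_class, t_half_class = t_half_class,
         params = params, regimen = dosing_regimen(dose, 24, n_doses)),
    class = "virtual_inhibitor_scenario"
  )
}

#' Simulate a virtual-inhibitor monitoring scenario
#'
#' Runs the biomarker interaction through the full once-daily regimen and
#' reports CmaxR, AUCR(0-24 h) and the biomarker Tmax on the steady-state
#' dosing day. Steady state is certified by requiring the treatment-arm
#' day-over-day AUC change below 0.5%; a non-converged regimen errors.
#'
#' @param scn A [virtual_inhibitor()] scenario.
#' @param victim Calibrated endogenous [victim_params()].
#' @param phys A [physiology_ref()].
#' @param dt Output grid (h).
#' @return An object of class `scenario_result`: `metrics` (one-row tibble
#'   with the class labels, `cmax_ratio`, `auc_ratio`, `tmax_h` relative to
#'   the last dose), the steady-state-day `profile` (treatment arm),
#'   `control_css_nM`, and `window`.
#' @export
simulate_scenario <- function(scn, victim, phys = physiology_ref(),
                              dt = 0.1) {
  n <- scn$regimen$n_doses
  if (n * scn$regimen$interval < 7 * half_life(scn$params)) {
    abort("regimen too short: fewer than 7 half-lives simulated",
          class = "coprokin_invalid_parameter")
  }
  last_dose <- scn$regimen$start_time + (n - 1) * scn$regimen$interval
  window <- c(last_dose, last_dose + 24)
  out <- simulate_ddi(victim, scn$params, scn$regimen, phys,
                      window = window, t_end = window[2], dt = dt)
  trt <- dplyr::filter(out$profiles, .data$arm == "treatment")
  auc_last <- exposure_metrics(trt, window)$auc
  auc_prev <- exposure_metrics(trt, window - 24)$auc
  if (abs(auc_last / auc_prev - 1) > 0.005) {
    abort(sprintf(
      "steady state not reached: day-over-day AUC change %.2f%% exceeds 0.5%%",
      100 * abs(auc_last / auc_prev - 1)),
      class = "coprokin_steady_state")
  }
  css <- solve_baseline(victim, phys)$css_nM
  metrics <- tibble(
    potency_class = scn$potency_class, t_half_class = scn$t_half_class,
    dose_mg = scn$regimen$dose,
    cmax_ratio = out$metrics$cmax_ratio, auc_ratio = out$metrics$auc_ratio,
    tmax_h = out$metrics$tmax_biomarker_h - last_dose
  )
  structure(
    list(metrics = metrics,
         profile = dplyr::mutate(trt, time_h = .data$time_h - last_dose),
         control_css_nM = css, window = window),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<scenario_result> %s/%s: CmaxR %.3f  AUCR %.3f  Tmax %.2f h (dose %.3g mg)\n",
    m$potency_class, m$t_half_class, m$cmax_ratio, m$auc_ratio, m$tmax_h,
    m$dose_mg))
  invisible(x)
}

#' Sparse-sampling error in the Cmax ratio
#'
#' Percent reduction of the biomarker Cmax ratio when a single sample taken
#' at `t` replaces the true peak:
#' `100 x (Cmax - C(t)) / (Cmax - C_control)`, using the control baseline as
#' the floor of the interaction signal. Zero at Tmax by construction.
#'
#' @param result A [simulate_scenario()] result.
#' @param sample_times Sampling times (h after the steady-state-day dose).
#' @return A tibble with `time_h` and `deviation_pct`.
#' @export
sparse_sampling_cmaxr <- function(result, sample_times) {
  prof <- result$profile
  if (any(sample_times < 0 | sample_times > max(prof$time_h))) {
    abort("sample times must fall within the dosing day",
          class = "coprokin_invalid_parameter")
  }
  cmax <- max(prof$conc_plasma_nM)
  conc_at <- approxfun(prof$time_h, prof$conc_plasma_nM)(sample_times)
  tibble(time_h = sample_times,
         deviation_pct = 100 * (cmax - conc_at) /
           (cmax - result$control_css_nM))
}

#' Metric recommendation per scenario class
#'
#' Encodes the monitoring-design rule set: inhibitors with a short half-life
#' reach maximal inhibition after a single dose, long half-life requires
#' multiple dosing; for strong/moderate short-half-life inhibitors CmaxR is
#' the appropriate (more sensitive) metric and sampling is Tmax-sensitive;
#' for weak/short and strong/long scenarios AUCR is as sensitive as CmaxR.
#'
#' @param results A data frame with columns `potency_class` and
#'   `t_half_class` covering the four scenario classes (strong/short,
#'   moderate/short, weak/short, strong/long), e.g. bound
#'   [simulate_scenario()] metrics.
#' @return The input with appended `required_dosing`, `recommended_metric`,
#'   `tmax_sensitive` columns.
#' @export
recommend_metric <- function(results) {
  required <- tibble(
    potency_class = c("strong", "moderate", "weak", "strong"),
    t_half_class = c("short", "short", "short", "long"))
  have <- dplyr::distinct(results[, c("potency_class", "t_half_class")])
  missing <- dplyr::anti_join(required, have,
                              by = c("potency_class", "t_half_class"))
  if (nrow(missing) > 0) {
    abort(sprintf("scenario grid incomplete; missing: %s",
                  paste(missing$potency_class, missing$t_half_class,
                        sep = "/", collapse = ", ")),
          class = "coprokin_invalid_parameter")
  }
  dplyr::mutate(
    results,
    required_dosing = ifelse(.data$t_half_class == "short", "single dose",
                             "multiple dose"),
    recommended_metric = ifelse(
      .data$t_half_class == "short" & .data$potency_class %in%
        c("strong", "moderate"), "CmaxR", "CmaxR and AUCR"),
    tmax_sensitive = .data$t_half_class == "short" &
      .data$potency_class %in% c("strong", "moderate")
  )
}

#' Run the default four-scenario monitoring grid
#'
#' Simulates the weak/short, moderate/short, strong/short and strong/long
#' virtual-inhibitor scenarios and appends the metric recommendation.
#'
#' @param victim Calibrated endogenous [victim_params()].
#' @param phys A [physiology_ref()].
#' @param ki Common Ki of the virtual inhibitors (uM).
#' @param dt Output grid (h).
#' @return A list with `results` (list of `scenario_result`) and
#'   `recommendation` (tibble from [recommend_metric()]).
#' @export
run_trial_design_grid <- function(victim, phys = physiology_ref(), ki = 1,
                                  dt = 0.1) {
  grid <- list(
    c("weak", "short"), c("moderate", "short"),
    c("strong", "short"), c("strong", "long"))
  results <- purrr::map(grid, function(g) {
    scn <- virtual_inhibitor(g[1], g[2], ki = ki, phys = phys)
    simulate_scenario(scn, victim, phys, dt = dt)
  })
  metrics <- dplyr::bind_rows(purrr::map(results, "metrics"))
  list(results = results, recommendation = recommend_metric(metrics))
}
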