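# local seed scoping so generators are pure functions of (config, seed)
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic per-subject baseline dataset
#'
#' Emulates the structure of clinical CP-I baseline panels: per covariate
#' arm, subject baselines log-normally distributed around the model-predicted
#' scenario mean (between-subject factor, median-preserving), with an
#' additional multiplicative log-normal residual on the observation.
#'
#' @param scenarios Data frame with `ethnicity`, `genotype`, `sex` columns.
#' @param victim Reference calibrated [victim_params()].
#' @param phys Reference [physiology_ref()].
#' @param n_per_arm Subjects per scenario.
#' @param cv_between Between-subject CV of the true baseline.
#' @param cv_residual Residual (observation) CV.
#' @param seed Integer seed.
#' @return A tibble: `subject_id`, covariates, `css_true_nM`,
#'   `css_observed_nM`. The scenario-level truth (model `css_nM` per arm) is
#'   attached as attribute `truth`.
#' @export
generate_baseline_dataset <- function(scenarios = default_scenarios(),
                                      victim, phys = physiology_ref(),
                                      n_per_arm = 10, cv_between = 0.35,
                                      cv_residual = 0.1, seed = 1L) {
  if (n_per_arm < 1) abort("n_per_arm must be at least 1",
                           class = "coprokin_invalid_parameter")
  truth <- baseline_scenario_table(scenarios, victim, phys)
  out <- .with_seed(seed, {
    rows <- purrr::pmap(
      list(truth$ethnicity, truth$genotype, truth$sex, truth$css_nM),
      function(eth, gt, sx, css) {
        true <- css * exp(rnorm(n_per_arm, 0, .sdlog(cv_between)))
        obs <- true * exp(rnorm(n_per_arm, 0, .sdlog(cv_residual)))
        tibble(ethnicity = eth, genotype = gt, sex = sx,
               css_true_nM = true, css_observed_nM = obs)
      })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::mutate(out, subject_id = dplyr::row_number(),
                       .before = 1)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic paired control/treatment interaction dataset
#'
#' Simulates the biomarker interaction at a known true Ki (a scale factor on
#' the inhibitor's in vitro Ki map), samples both arms at the stated times,
#' and applies multiplicative log-normal residual error. The truth record is
#' attached for recovery studies.
#'
#' @param victim Calibrated endogenous [victim_params()].
#' @param inhibitor An [inhibitor_params()].
#' @param regimen Inhibitor [dosing_regimen()].
#' @param phys A [physiology_ref()].
#' @param true_ki_scale Scale applied to the in vitro Ki map (truth).
#' @param sampling_times Sampling times (h post first inhibitor dose).
#' @param cv_residual Residual CV.
#' @param n_subjects Subjects (paired control/treatment profiles each).
#' @param seed Integer seed.
#' @return A tibble: `subject_id`, `arm`, `time_h`, `conc_nM`; attribute
#'   `truth` holds `true_ki_scale`, the true Ki map, and the noise level.
#' @export
generate_ddi_dataset <- function(victim, inhibitor, regimen,
                                 phys = physiology_ref(),
                                 true_ki_scale = 1,
                                 sampling_times = c(0, 1, 2, 4, 6, 8, 12, 24),
                                 cv_residual = 0.2, n_subjects = 1,
                                 seed = 1L) {
  t_end <- max(sampling_times,
               regimen$start_time + regimen$interval * regimen$n_doses)
  ki_true <- inhibitor$ki * true_ki_scale
  out <- simulate_ddi(victim, inhibitor, regimen, phys,
                      window = range(c(0, sampling_times, 1)),
                      t_end = t_end, ki_override = ki_true)
  sample_arm <- function(arm) {
    prof <- dplyr::filter(out$profiles, .data$arm == !!arm)
    approxfun(prof$time_h, prof$conc_plasma_nM)(sampling_times)
  }
  pred <- list(control = sample_arm("control"),
               treatment = sample_arm("treatment"))
  data <- .with_seed(seed, {
    rows <- purrr::map(seq_len(n_subjects), function(i) {
      dplyr::bind_rows(purrr::imap(pred, function(p, arm) {
        tibble(subject_id = i, arm = arm, time_h = sampling_times,
               conc_nM = p * exp(rnorm(length(p), 0, .sdlog(cv_residual))))
      }))
    })
    dplyr::bind_rows(rows)
  })
  attr(data, "truth") <- list(true_ki_scale = true_ki_scale,
                              ki_map = ki_true, cv_residual = cv_residual,
                              seed = seed)
  data
}

#' Fixture of prediction/observation pairs for criterion testing
#'
#' A deterministic table exercising every branch of the evaluation
#' criteria: pairs exactly on the 1.5-fold and 2-fold boundaries, inside and
#' outside each band, the degenerate Guest point at an observed ratio of 1,
#' and an observed ratio below 1.
#'
#' @return A tibble with `label`, `predicted`, `observed`.
#' @export
evaluation_fixture <- function() {
  tibble(
    label = c("exact", "on_1.5_boundary", "below_1.5", "on_2_boundary",
              "outside_2", "guest_degenerate", "obs_below_1_in",
              "obs_below_1_out", "strong_ddi_in", "strong_ddi_out"),
    predicted = c(1.0, 1.5, 0.5, 2.0, 2.5, 1.0, 0.55, 1.4, 4.0, 9.5),
    observed = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 0.5, 0.5, 4.6, 4.6)
  )
}
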