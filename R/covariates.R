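# covariate lookup tables (White male 521TT is the calibration reference)
.ETHNICITIES <- c("White", "Japanese", "AsianIndian")
.GENOTYPES <- c("TT", "TC", "CC")
.SEXES <- c("M", "F")

# synthesis rate (mg/day/kg): sex-specific, Japanese reduced
.K_SYN <- list(
  White = c(M = 0.0036, F = 0.0032),
  AsianIndian = c(M = 0.0036, F = 0.0032),
  Japanese = c(M = 0.0024, F = 0.0021)
)

# OATP1B1 abundance relative to White wild type; the 58% reduction is
# reported for Japanese only, Asian-Indian kept at the White level
.ETH_OATP1B1 <- c(White = 1, AsianIndian = 1, Japanese = 0.58)

# default demographics (kg)
.BODY_WEIGHT <- list(
  White = c(M = 70, F = 60),
  AsianIndian = c(M = 65, F = 52),
  Japanese = c(M = 65, F = 52)
)

# SLCO1B1 c.521T>C activity multipliers on OATP1B1 intrinsic clearance.
# CC is calibrated so the White mixed-sex CC:TT baseline ratio is 1.40 under
# the flow-limited liver model; TC is the gene-dose midpoint.
.GENOTYPE_OATP1B1 <- c(TT = 1, TC = 0.72, CC = 0.441)

#' Covariate scenario
#'
#' @param ethnicity One of `"White"`, `"Japanese"`, `"AsianIndian"`.
#' @param genotype SLCO1B1 c.521T>C genotype: `"TT"`, `"TC"`, `"CC"`.
#' @param sex `"M"` or `"F"`.
#' @return An object of class `covariate_spec`.
#' @export
#' @examples
#' covariate_spec("Japanese", "TT", "M")
covariate_spec <- function(ethnicity, genotype, sex) {
  if (!ethnicity %in% .ETHNICITIES || !genotype %in% .GENOTYPES ||
      !sex %in% .SEXES) {
    abort(sprintf(
      "unknown covariate level; ethnicity in {%s}, genotype in {%s}, sex in {%s}",
      paste(.ETHNICITIES, collapse = ","), paste(.GENOTYPES, collapse = ","),
      paste(.SEXES, collapse = ",")), class = "coprokin_invalid_parameter")
  }
  structure(list(ethnicity = ethnicity, genotype = genotype, sex = sex),
            class = "covariate_spec")
}

#' All 18 baseline covariate scenarios
#'
#' @return A tibble with columns `ethnicity`, `genotype`, `sex` (3 x 3 x 2
#'   rows).
#' @export
default_scenarios <- function() {
  tidyr::expand_grid(ethnicity = .ETHNICITIES, genotype = .GENOTYPES,
                     sex = .SEXES)
}

#' Apply ethnicity/genotype/sex covariates to the reference model
#'
#' Starting from the White male 521TT reference parameter set (with its
#' calibrated hepatic scaler), adjusts the synthesis rate for
#' ethnicity and sex, multiplies the OATP1B1 intrinsic clearance by the
#' ethnicity abundance scalar and the genotype activity multiplier, and sets
#' the demographic body weight.
#'
#' @param victim Reference [victim_params()] (White male TT, calibrated).
#' @param phys Reference [physiology_ref()].
#' @param cov A [covariate_spec()] (or list with `ethnicity`, `genotype`,
#'   `sex`).
#' @param genotype_scalars Named OATP1B1 activity multipliers per genotype.
#' @param ethnicity_scalars Named OATP1B1 abundance scalars per ethnicity.
#' @param body_weights Demographic body weights, a list by ethnicity of
#'   named M/F vectors.
#' @return List with adjusted `victim` and `phys`.
#' @export
#' @examples
#' ref <- calibrate_victim(cpi_victim(), physiology_ref(), fe = 0.10)
#' jp <- apply_covariates(ref, physiology_ref(),
#'                        covariate_spec("Japanese", "TT", "M"))
#' jp$victim$k_syn
apply_covariates <- function(victim, phys, cov,
                             genotype_scalars = .GENOTYPE_OATP1B1,
                             ethnicity_scalars = .ETH_OATP1B1,
                             body_weights = .BODY_WEIGHT) {
  cov <- covariate_spec(cov$ethnicity, cov$genotype, cov$sex)
  v <- victim
  v$k_syn <- .K_SYN[[cov$ethnicity]][[cov$sex]]
  v$cl_uptake_per_cell[["OATP1B1"]] <-
    victim$cl_uptake_per_cell[["OATP1B1"]] *
    ethnicity_scalars[[cov$ethnicity]] * genotype_scalars[[cov$genotype]]
  p <- phys
  p$body_weight <- body_weights[[cov$ethnicity]][[cov$sex]]
  list(victim = v, phys = p)
}

#' Baseline table across covariate scenarios
#'
#' Deterministic representative-subject baselines, one row per covariate
#' scenario.
#'
#' @param scenarios Data frame with columns `ethnicity`, `genotype`, `sex`;
#'   defaults to all 18 scenarios.
#' @param victim Reference calibrated [victim_params()].
#' @param phys Reference [physiology_ref()].
#' @param ... Passed to [apply_covariates()].
#' @return A tibble with the covariates, `body_weight_kg`, and the
#'   [solve_baseline()] columns.
#' @export
#' @examples
#' \donttest{
#' ref <- calibrate_victim(cpi_victim(), physiology_ref(), fe = 0.10)
#' baseline_scenario_table(victim = ref)
#' }
baseline_scenario_table <- function(scenarios = default_scenarios(),
                                    victim, phys = physiology_ref(), ...) {
  if (nrow(scenarios) == 0) {
    abort("scenarios must be nonempty", class = "coprokin_invalid_parameter")
  }
  rows <- purrr::pmap(
    scenarios[, c("ethnicity", "genotype", "sex")],
    function(ethnicity, genotype, sex) {
      adj <- apply_covariates(victim, phys,
                              covariate_spec(ethnicity, genotype, sex), ...)
      bl <- solve_baseline(adj$victim, adj$phys)
      dplyr::bind_cols(
        tibble(ethnicity = ethnicity, genotype = genotype, sex = sex,
               body_weight_kg = adj$phys$body_weight),
        as_tibble(bl)
      )
    })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("baseline_scenario_table", class(out))
  out
}

#' Population specification
#'
#' Log-normal between-subject variability applied to intrinsic clearances
#' (one common factor across transporters), synthesis rate, renal clearance
#' and body weight. The representative subject is the distribution median.
#'
#' @param covariates A [covariate_spec()].
#' @param n Number of subjects.
#' @param cv_clint,cv_ksyn,cv_clr,cv_bw Coefficients of variation.
#' @param seed Integer seed; draws are reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(covariates, n, cv_clint = 0.35, cv_ksyn = 0.25,
                            cv_clr = 0.30, cv_bw = 0.15, seed = 1L) {
  if (n < 1) abort("n must be at least 1",
                   class = "coprokin_invalid_parameter")
  if (any(c(cv_clint, cv_ksyn, cv_clr, cv_bw) < 0)) {
    abort("CVs must be nonnegative", class = "coprokin_invalid_parameter")
  }
  structure(list(covariates = covariates, n = n, cv_clint = cv_clint,
                 cv_ksyn = cv_ksyn, cv_clr = cv_clr, cv_bw = cv_bw,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# sdlog such that a log-normal has coefficient of variation cv
.sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Sample virtual subjects
#'
#' Draws per-subject multiplicative log-normal factors (median 1) for
#' intrinsic clearances, synthesis rate and renal clearance, and a body
#' weight around the demographic mean.
#'
#' @param spec A [population_spec()].
#' @return A tibble with one row per subject: `subject_id`, the covariates,
#'   `f_clint`, `f_ksyn`, `f_clr`, `body_weight_kg`.
#' @export
sample_population <- function(spec) {
  cov <- spec$covariates
  bw_mean <- .BODY_WEIGHT[[cov$ethnicity]][[cov$sex]]
  .with_seed(spec$seed, {
    tibble(
      subject_id = seq_len(spec$n),
      ethnicity = cov$ethnicity, genotype = cov$genotype, sex = cov$sex,
      f_clint = exp(rnorm(spec$n, 0, .sdlog(spec$cv_clint))),
      f_ksyn = exp(rnorm(spec$n, 0, .sdlog(spec$cv_ksyn))),
      f_clr = exp(rnorm(spec$n, 0, .sdlog(spec$cv_clr))),
      body_weight_kg = bw_mean * exp(rnorm(spec$n, 0, .sdlog(spec$cv_bw)))
    )
  })
}

#' Per-subject baselines for a sampled population
#'
#' Applies the scenario covariates and each subject's variability factors to
#' the reference model and solves the baseline steady state per subject.
#'
#' @param subjects Tibble from [sample_population()].
#' @param victim Reference calibrated [victim_params()].
#' @param phys Reference [physiology_ref()].
#' @return `subjects` with an appended `css_nM` column.
#' @export
simulate_population_baseline <- function(subjects, victim,
                                         phys = physiology_ref()) {
  css <- purrr::pmap_dbl(
    subjects[, c("ethnicity", "genotype", "sex", "f_clint", "f_ksyn",
                 "f_clr", "body_weight_kg")],
    function(ethnicity, genotype, sex, f_clint, f_ksyn, f_clr,
             body_weight_kg) {
      adj <- apply_covariates(victim, phys,
                              covariate_spec(ethnicity, genotype, sex))
      v <- adj$victim
      v$cl_uptake_per_cell <- v$cl_uptake_per_cell * f_clint
      v$cl_passive_per_cell <- v$cl_passive_per_cell * f_clint
      v$cl_efflux_per_cell <- v$cl_efflux_per_cell * f_clint
      v$k_syn <- v$k_syn * f_ksyn
      v$cl_renal_plasma <- v$cl_renal_plasma * f_clr
      p <- adj$phys
      p$body_weight <- body_weight_kg
      solve_baseline(v, p)$css_nM
    })
  dplyr::mutate(subjects, css_nM = css)
}
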