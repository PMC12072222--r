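test_that("competitive inhibition scales intrinsic clearance", {
  expect_equal(inhibited_clint(100, 0, 1), 100)
  expect_equal(inhibited_clint(100, 1, 1), 50)
  expect_equal(inhibited_clint(100, 9, 1), 10)
  expect_error(inhibited_clint(100, 1, 0),
               class = "coprokin_invalid_parameter")
})

test_that("exposure metrics recover analytic values", {
  const <- tibble::tibble(time_h = seq(0, 24, 0.1), conc = 2)
  m <- exposure_metrics(const, c(0, 24), conc_col = "conc")
  expect_equal(m$cmax, 2)
  expect_equal(m$tmax_h, 0)
  expect_equal(m$auc, 48)

  ramp <- tibble::tibble(time_h = seq(0, 1, 0.1), conc = seq(0, 1, 0.1))
  expect_equal(exposure_metrics(ramp, c(0, 1), conc_col = "conc")$auc, 0.5)

  decay <- tibble::tibble(time_h = seq(0, 20, 0.1),
                          conc = exp(-seq(0, 20, 0.1)))
  expect_equal(exposure_metrics(decay, c(0, 20), conc_col = "conc")$auc, 1,
               tolerance = 2e-3)

  expect_error(exposure_metrics(const, c(5, 5), conc_col = "conc"),
               class = "coprokin_invalid_parameter")
})

test_that("a null inhibitor leaves the biomarker at baseline", {
  # effectively infinite Ki
  weak <- test_inhibitor(ki = c(OATP1B1 = 1e9, OATP1B3 = 1e9))
  out <- simulate_ddi(ref_victim, weak, dosing_regimen(500, 24, 1),
                      ref_phys, c(0, 24))
  expect_equal(out$metrics$cmax_ratio, 1, tolerance = 5e-3)
  expect_equal(out$metrics$auc_ratio, 1, tolerance = 5e-3)

  # dose zero reproduces the control arm within solver tolerance
  out0 <- simulate_ddi(ref_victim, test_inhibitor(),
                       dosing_regimen(0, 24, 1), ref_phys, c(0, 24))
  ctrl <- dplyr::filter(out0$profiles, arm == "control")
  trt <- dplyr::filter(out0$profiles, arm == "treatment")
  expect_equal(trt$conc_plasma_nM, ctrl$conc_plasma_nM, tolerance = 1e-8)

  # control Cmax at steady state equals the analytic baseline
  expect_equal(out0$control_metrics$cmax, ref_baseline$css_nM,
               tolerance = 1e-6)
})

test_that("interaction ratios grow monotonically with dose", {
  ratios <- purrr::map_dfr(c(150, 300, 600), function(d) {
    tidy(simulate_ddi(ref_victim, example_inhibitor("rifampicin-like"),
                      dosing_regimen(d, 24, 1), ref_phys, c(0, 24)))
  })
  expect_true(all(diff(ratios$cmax_ratio) > 0))
  expect_true(all(diff(ratios$auc_ratio) > 0))
  expect_true(all(ratios$cmax_ratio >= 1))
  expect_true(all(ratios$auc_ratio >= 1))
  expect_true(all(ratios$cmax_ratio >= ratios$auc_ratio))
})

test_that("dynamic ratio matches the static extended-clearance oracle far from the flow limit", {
  lo <- low_extraction_victim()
  fe <- solve_baseline(lo, ref_phys)$fe
  dyn <- constant_exposure_aucr(lo, iu = 1, ki = unit_ki)
  expect_equal(dyn, static_aucr(lo, fe, iu = 1, ki = unit_ki),
               tolerance = 0.02)
  # the half-inhibition example: fe 0.10, passive ~0 gives ~1.82
  expect_equal(static_aucr(lo, 0.10, iu = 1, ki = unit_ki), 1.81,
               tolerance = 0.01)
})

test_that("static formula is an upper bound, approached at saturation", {
  # for the flow-limited CP-I parameter set the static formula overestimates
  # intermediate inhibition ...
  dyn_mid <- constant_exposure_aucr(ref_victim, iu = 1, ki = unit_ki)
  expect_lt(dyn_mid, static_aucr(ref_victim, 0.10, 1, unit_ki))
  # ... and the saturation ceiling 1/(fe + ft_passive) bounds the dynamic
  # ratio, which approaches it as Iu -> infinity
  ceiling_static <- 1 / (ref_baseline$fe + ref_baseline$ft_passive)
  dyn_inf <- constant_exposure_aucr(ref_victim, iu = 1e7, ki = unit_ki,
                                    t_end = 3000)
  expect_lt(dyn_inf, ceiling_static)
  expect_gt(dyn_inf, 0.9 * ceiling_static)
})

test_that("the engine generalizes to exogenously dosed victims", {
  statin <- statin_like_victim()
  reg_v <- dosing_regimen(10, 24, 1)
  none <- simulate_ddi(statin, test_inhibitor(ki = c(OATP1B1 = 1e9,
                                                     OATP1B3 = 1e9)),
                       dosing_regimen(500, 24, 1), ref_phys, c(0, 24),
                       victim_regimen = reg_v)
  expect_equal(none$metrics$auc_ratio, 1, tolerance = 5e-3)

  strong <- simulate_ddi(statin, test_inhibitor(ki = unit_ki / 10),
                         dosing_regimen(500, 24, 1), ref_phys, c(0, 24),
                         victim_regimen = reg_v)
  mild <- simulate_ddi(statin, test_inhibitor(ki = unit_ki * 10),
                       dosing_regimen(500, 24, 1), ref_phys, c(0, 24),
                       victim_regimen = reg_v)
  expect_gt(strong$metrics$auc_ratio, mild$metrics$auc_ratio)

  # renal-only victim is untouched by OATP1B inhibition
  renal <- statin_like_victim()
  renal$cl_uptake_per_cell[] <- 0
  renal$cl_passive_per_cell <- 0
  out <- simulate_ddi(renal, test_inhibitor(ki = unit_ki / 100),
                      dosing_regimen(500, 24, 1), ref_phys, c(0, 24),
                      victim_regimen = reg_v)
  expect_equal(out$metrics$auc_ratio, 1, tolerance = 1e-6)

  expect_error(simulate_ddi(ref_victim, test_inhibitor(),
                            dosing_regimen(500, 24, 1), ref_phys, c(0, 24),
                            victim_regimen = reg_v),
               class = "coprokin_ambiguous_victim")
})

test_that("uncalibrated endogenous victims are rejected", {
  expect_error(simulate_ddi(cpi_victim(), test_inhibitor(),
                            dosing_regimen(500, 24, 1), ref_phys, c(0, 24)),
               class = "coprokin_precondition")
})

test_that("systemic-unbound driver is weaker than the liver-inlet driver", {
  inh <- test_inhibitor()
  reg <- dosing_regimen(500, 24, 1)
  inlet <- simulate_ddi(ref_victim, inh, reg, ref_phys, c(0, 24))
  sys <- simulate_ddi(ref_victim, inh, reg, ref_phys, c(0, 24),
                      driver = "systemic")
  expect_gt(inlet$metrics$auc_ratio, sys$metrics$auc_ratio)
})
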