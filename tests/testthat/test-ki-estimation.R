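test_that("ratio estimator inverts the forward interaction map", {
  inh <- test_inhibitor()
  reg <- dosing_regimen(500, 24, 1)
  for (k_true in c(0.01, 0.1, 1, 10)) {
    sim <- simulate_ddi(ref_victim, inh, reg, ref_phys, c(0, 24),
                        ki_override = unit_ki * k_true)
    est <- estimate_ki_from_ratio(sim$metrics$auc_ratio, "AUCR", ref_victim,
                                  inh, reg, ref_phys)
    expect_equal(est$ki_in_vivo, k_true, tolerance = 0.01)
  }
})

test_that("ratio estimator respects the attainable ceiling", {
  inh <- test_inhibitor()
  reg <- dosing_regimen(500, 24, 1)
  est <- estimate_ki_from_ratio(1.01, "AUCR", ref_victim, inh, reg,
                                ref_phys)
  expect_true(is.finite(est$ki_in_vivo) && est$ki_in_vivo > 0)
  expect_error(estimate_ki_from_ratio(20, "AUCR", ref_victim, inh, reg,
                                      ref_phys),
               class = "coprokin_infeasible_observation")
  expect_error(estimate_ki_from_ratio(0.9, "AUCR", ref_victim, inh, reg,
                                      ref_phys),
               class = "coprokin_invalid_parameter")
})

test_that("static constant-exposure solve recovers the unit Ki oracle", {
  no_passive <- cpi_victim()
  no_passive$cl_passive_per_cell <- 0
  # fe 0.10, ft_inhibitable 0.9, constant Iu 1, observed 1.82 -> Ki ~1
  expect_equal(static_ki_solve(1.82, no_passive, fe = 0.10, iu = 1), 1,
               tolerance = 0.01)
})

test_that("repartitioning preserves the baseline exactly", {
  same <- repartition_clearance(ref_victim, ref_phys, 0.10)
  expect_equal(same$cl_renal_plasma, ref_victim$cl_renal_plasma,
               tolerance = 1e-3)
  expect_equal(same$hepatic_scaler_gamma, ref_victim$hepatic_scaler_gamma,
               tolerance = 1e-3)

  v0 <- repartition_clearance(ref_victim, ref_phys, 0)
  expect_equal(v0$cl_renal_plasma, 0)
  expect_equal(solve_baseline(v0, ref_phys)$css_nM, ref_baseline$css_nM,
               tolerance = 1e-3)

  v15 <- repartition_clearance(ref_victim, ref_phys, 0.15)
  expect_equal(solve_baseline(v15, ref_phys)$css_nM, ref_baseline$css_nM,
               tolerance = 1e-3)
  expect_equal(compute_ft(v15, 0.15)[["OATP1B1"]], 0.654, tolerance = 1e-3)

  expect_error(repartition_clearance(ref_victim, ref_phys, 1),
               class = "coprokin_invalid_parameter")
})

test_that("estimated Ki falls with the assumed renal fraction and with the observed ratio", {
  inh <- example_inhibitor("rifampicin-like")
  reg <- dosing_regimen(600, 24, 1)
  sens <- fe_sensitivity(3.0, "AUCR", ref_victim, inh, reg, ref_phys,
                         fe_grid = c(0, 0.05, 0.10, 0.15))
  expect_true(all(diff(sens$ki_oatp1b1_uM) < 0))
  # larger renal share -> smaller Ki -> stronger predicted downstream DDI
  expect_true(all(diff(sens$downstream_aucr) > 0))

  k_small <- estimate_ki_from_ratio(1.5, "AUCR", ref_victim, inh, reg,
                                    ref_phys)
  k_large <- estimate_ki_from_ratio(4.0, "AUCR", ref_victim, inh, reg,
                                    ref_phys)
  expect_gt(k_small$ki_in_vivo, k_large$ki_in_vivo)
})

test_that("renal-fraction sensitivity of Ki is ordered by inhibitor strength", {
  inh <- example_inhibitor("rifampicin-like")
  reg <- dosing_regimen(600, 24, 1)
  fold <- function(obs) {
    k0 <- estimate_ki_from_ratio(obs, "AUCR", ref_victim, inh, reg,
                                 ref_phys, fe_assumed = 0)
    k15 <- estimate_ki_from_ratio(obs, "AUCR", ref_victim, inh, reg,
                                  ref_phys, fe_assumed = 0.15)
    k0$ki_in_vivo / k15$ki_in_vivo
  }
  folds <- vapply(c(4.6, 2.0, 1.2), fold, numeric(1))
  expect_true(all(diff(folds) < 0)) # strong > moderate > weak
  expect_gt(folds[1], 1)
})

test_that("profile estimator recovers a noise-free truth and flags flat objectives", {
  inh <- test_inhibitor()
  reg <- dosing_regimen(500, 24, 1)
  d <- generate_ddi_dataset(ref_victim, inh, reg, ref_phys,
                            true_ki_scale = 0.3, cv_residual = 0, seed = 1)
  obs <- d[d$arm == "treatment", c("time_h", "conc_nM")]
  est <- estimate_ki_from_profile(obs, ref_victim, inh, reg, ref_phys)
  expect_equal(est$ki_in_vivo, 0.3 * inh$ki[["OATP1B1"]], tolerance = 0.02)
  expect_false(glance(est)$non_identifiable)

  d0 <- generate_ddi_dataset(ref_victim, inh, dosing_regimen(0, 24, 1),
                             ref_phys, cv_residual = 0, seed = 1)
  obs0 <- d0[d0$arm == "treatment", c("time_h", "conc_nM")]
  expect_warning(
    est0 <- estimate_ki_from_profile(obs0, ref_victim, inh,
                                     dosing_regimen(0, 24, 1), ref_phys),
    "flat")
  expect_true(est0$convergence$non_identifiable)
})

test_that("tidiers expose the estimate as tables", {
  inh <- test_inhibitor(ki = c(OATP1B1 = 2, OATP1B3 = 1))
  reg <- dosing_regimen(500, 24, 1)
  est <- estimate_ki_from_ratio(1.5, "AUCR", ref_victim, inh, reg, ref_phys)
  td <- tidy(est)
  expect_equal(td$transporter, c("OATP1B1", "OATP1B3"))
  # in vitro 2:1 ratio preserved by the one-dimensional search
  expect_equal(td$ki_uM[1] / td$ki_uM[2], 2)
  gl <- glance(est)
  expect_equal(gl$ki_oatp1b1_uM, est$ki_in_vivo)
  expect_lt(gl$residual, 1e-4)
})
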