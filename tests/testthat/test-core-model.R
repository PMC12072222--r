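test_that("per-cell intrinsic clearance scales to whole liver", {
  expect_equal(scale_intrinsic_clearance(106, ref_phys),
               106e-6 * 99 * 1650 * 60)
  expect_equal(scale_intrinsic_clearance(0, ref_phys), 0)
  expect_equal(scale_intrinsic_clearance(106, ref_phys, gamma = 0.5),
               scale_intrinsic_clearance(106, ref_phys) / 2)
  expect_error(scale_intrinsic_clearance(-1, ref_phys),
               class = "coprokin_invalid_parameter")
})

test_that("net hepatic clearance follows the extended-clearance form", {
  v <- cpi_victim()
  scale <- 99 * 1650 * 60e-6
  expect_equal(net_hepatic_intrinsic_clearance(v, ref_phys),
               (106 + 31 + 0.76) * scale * 0.612 / (0.612 + 0.76))
  # bile-commitment fraction from the per-cell values
  expect_equal(0.612 / (0.612 + 0.76), 0.4461, tolerance = 1e-4)

  no_backflux <- cpi_victim()
  no_backflux$cl_passive_per_cell <- 0
  expect_equal(net_hepatic_intrinsic_clearance(no_backflux, ref_phys),
               (106 + 31) * scale)

  fast_bile <- cpi_victim()
  fast_bile$cl_efflux_per_cell[["MRP2"]] <- 1e9
  expect_equal(net_hepatic_intrinsic_clearance(fast_bile, ref_phys),
               (106 + 31 + 0.76) * scale, tolerance = 1e-6)

  degenerate <- cpi_victim()
  degenerate$cl_passive_per_cell <- 0
  degenerate$cl_efflux_per_cell[["MRP2"]] <- 0
  expect_error(net_hepatic_intrinsic_clearance(degenerate, ref_phys),
               class = "coprokin_degenerate_model")
})

test_that("victim derivatives are mass-balanced and competitive", {
  # synthesis only from an empty system
  d <- biomarker_rhs(c(0, 0, 0), ref_victim, ref_phys)
  expect_gt(d[1], 0)
  expect_equal(d[2:3], c(0, 0))

  # exact fixed point at the analytic steady state
  ss <- attr(ref_baseline, "state")
  d_ss <- biomarker_rhs(ss, ref_victim, ref_phys)
  syn <- ref_victim$k_syn * 70 * 1e6 / ref_victim$molecular_weight / 24
  expect_lt(max(abs(d_ss)) / syn, 1e-9)

  # Iu = Ki on both transporters halves the active uptake flux
  v <- cpi_victim()
  v$cl_passive_per_cell <- 0 # isolate the inhibitable flux
  state <- c(0, 1, 0)
  d_ctrl <- biomarker_rhs(state, v, ref_phys)
  d_inh <- biomarker_rhs(state, v, ref_phys, iu = c(OATP1B1 = 1, OATP1B3 = 1),
                         ki = unit_ki)
  expect_equal(d_inh[3], d_ctrl[3] / 2)

  expect_error(biomarker_rhs(c(-1, 0, 0), ref_victim, ref_phys),
               class = "coprokin_integration_domain")
})

test_that("baseline steady state is exact and behaves linearly", {
  expect_equal(ref_baseline$css_nM, 0.6972885, tolerance = 1e-5)
  expect_equal(ref_baseline$cl_total_plasma, 23, tolerance = 1e-6)
  expect_equal(ref_baseline$fe, 0.10, tolerance = 1e-6)

  v2 <- ref_victim
  v2$k_syn <- 2 * v2$k_syn
  expect_equal(solve_baseline(v2, ref_phys)$css_nM, 2 * ref_baseline$css_nM)

  no_renal <- ref_victim
  no_renal$cl_renal_plasma <- 0
  bl <- solve_baseline(no_renal, ref_phys)
  expect_gt(bl$css_nM, ref_baseline$css_nM)
  expect_equal(bl$fe, 0)

  dead <- cpi_victim()
  dead$cl_renal_plasma <- 0
  dead$cl_passive_per_cell <- 0
  dead$cl_efflux_per_cell[["MRP2"]] <- 0
  expect_error(solve_baseline(dead, ref_phys),
               class = "coprokin_degenerate_model")
})

test_that("hepatic scaler calibration matches the well-stirred inversion", {
  gamma <- calibrate_hepatic_scaler(cpi_victim(), ref_phys, fe = 0.10)
  # closed-form oracle: invert CL_H,b = Q x / (Q + x) with x the unbound
  # whole-liver net intrinsic clearance in blood terms
  cl_hb <- (23 - 2.3) / 0.628
  x <- 87 * cl_hb / (87 - cl_hb)
  fu_b <- 0.069 / 0.628
  gamma_oracle <- x / (fu_b * net_hepatic_intrinsic_clearance(cpi_victim(),
                                                              ref_phys))
  expect_equal(gamma, gamma_oracle, tolerance = 1e-2)
  expect_equal(gamma, 0.802, tolerance = 1e-2)

  # calibrating to the model's own baseline returns the identity
  css0 <- solve_baseline(cpi_victim(), ref_phys)$css_nM
  expect_equal(calibrate_hepatic_scaler(cpi_victim(), ref_phys, css = css0),
               1, tolerance = 1e-6)

  # fe below the renal-only floor is unattainable (hepatic clearance is
  # capped by liver blood flow)
  expect_error(calibrate_hepatic_scaler(cpi_victim(), ref_phys, fe = 0.01),
               class = "coprokin_calibration_failure")
  expect_error(calibrate_hepatic_scaler(cpi_victim(), ref_phys, fe = 1),
               class = "coprokin_invalid_parameter")
})

test_that("pathway fractions split by intrinsic-clearance share", {
  ft <- compute_ft(cpi_victim(), fe = 0.10)
  expect_equal(ft[["OATP1B1"]], 0.9 * 106 / 137.76, tolerance = 1e-6)
  expect_equal(ft[["OATP1B1"]], 0.693, tolerance = 1e-3)
  expect_equal(ft[["OATP1B3"]], 0.203, tolerance = 5e-3)
  expect_equal(sum(ft), 1)

  expect_equal(compute_ft(cpi_victim(), 0)[["OATP1B1"]], 106 / 137.76)

  single <- cpi_victim()
  single$cl_uptake_per_cell <- c(OATP1B1 = 50)
  single$raf <- c(OATP1B1 = 1, MRP2 = 1)
  single$cl_passive_per_cell <- 0
  expect_equal(compute_ft(single, 0.5)[["OATP1B1"]], 0.5)

  expect_error(compute_ft(cpi_victim(), 1),
               class = "coprokin_invalid_parameter")
})

test_that("passive share of hepatic uptake is below 1 percent", {
  expect_equal(fraction_passive_uptake(cpi_victim()), 0.76 / 137.76)
  expect_lt(fraction_passive_uptake(cpi_victim()), 0.01)
  v <- cpi_victim()
  v$cl_passive_per_cell <- 0
  expect_equal(fraction_passive_uptake(v), 0)
  v$cl_passive_per_cell <- 137
  expect_equal(fraction_passive_uptake(v), 0.5)
})

test_that("long-run ODE trajectory agrees with the linear steady state", {
  tr <- simulate_victim(ref_victim, ref_phys, 2000, init = "zero")
  expect_equal(tail(tr$conc_plasma_nM, 1), ref_baseline$css_nM,
               tolerance = 1e-4)
})

test_that("mass balance closes over a transient interval", {
  t_end <- 100
  tr <- simulate_victim(ref_victim, ref_phys, t_end, init = "zero")
  syn <- ref_victim$k_syn * 70 * 1e6 / ref_victim$molecular_weight / 24
  input <- syn * t_end
  last <- tr[nrow(tr), ]
  retained <- last$amount_central + last$amount_liver_ec +
    last$amount_liver_ic
  eliminated <- last$cum_renal_nmol + last$cum_bile_nmol
  expect_lt(abs(input - retained - eliminated) / input, 1e-3)
})

test_that("baseline is homogeneous in synthesis and clearances", {
  for (f in c(0.5, 3)) {
    v <- ref_victim
    v$k_syn <- v$k_syn * f
    expect_equal(solve_baseline(v, ref_phys)$css_nM,
                 f * ref_baseline$css_nM)
    # uniform scaling of every clearance-dimension parameter (renal,
    # hepatic intrinsic, flows) scales total clearance exactly
    v2 <- ref_victim
    v2$cl_renal_plasma <- v2$cl_renal_plasma * f
    v2$cl_uptake_per_cell <- v2$cl_uptake_per_cell * f
    v2$cl_passive_per_cell <- v2$cl_passive_per_cell * f
    v2$cl_efflux_per_cell <- v2$cl_efflux_per_cell * f
    p2 <- ref_phys
    p2$q_hepatic_blood <- p2$q_hepatic_blood * f
    expect_equal(solve_baseline(v2, p2)$css_nM, ref_baseline$css_nM / f,
                 tolerance = 1e-9)
  }
})

test_that("baseline decreases when any elimination pathway strengthens", {
  bump <- function(field, transporter = NULL) {
    v <- ref_victim
    if (is.null(transporter)) v[[field]] <- v[[field]] * 1.2
    else v[[field]][[transporter]] <- v[[field]][[transporter]] * 1.2
    solve_baseline(v, ref_phys)$css_nM
  }
  expect_lt(bump("cl_renal_plasma"), ref_baseline$css_nM)
  expect_lt(bump("cl_uptake_per_cell", "OATP1B1"), ref_baseline$css_nM)
  expect_lt(bump("cl_uptake_per_cell", "OATP1B3"), ref_baseline$css_nM)
  expect_lt(bump("cl_efflux_per_cell", "MRP2"), ref_baseline$css_nM)
})

test_that("renal fraction plus hepatic pathway fractions sum to one", {
  for (fe in c(0, 0.05, 0.1, 0.15, 0.3)) {
    expect_equal(sum(compute_ft(cpi_victim(), fe)), 1)
  }
  expect_equal(compute_fe(ref_baseline) +
                 sum(ref_baseline$ft_oatp1b1, ref_baseline$ft_oatp1b3,
                     ref_baseline$ft_passive), 1)
})
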