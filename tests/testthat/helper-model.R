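# shared fixtures, built once per test run
ref_phys <- physiology_ref()
ref_victim <- calibrate_victim(cpi_victim(), ref_phys, fe = 0.10)
ref_baseline <- solve_baseline(ref_victim, ref_phys)

unit_ki <- c(OATP1B1 = 1, OATP1B3 = 1)

# CP-I-like victim with hepatic uptake scaled far below the blood-flow
# limit (extraction ~1.5%), renal clearance set for fe = 0.10; in this
# regime the static extended-clearance formula applies
low_extraction_victim <- function() {
  v <- cpi_victim()
  v$cl_uptake_per_cell <- v$cl_uptake_per_cell / 50
  v$cl_passive_per_cell <- v$cl_passive_per_cell / 50
  v$cl_renal_plasma <- 0
  cl_h <- solve_baseline(v, ref_phys)$cl_total_plasma
  v$cl_renal_plasma <- cl_h / 9
  v$calibrated <- TRUE
  v
}

# simple one-compartment inhibitor used where the specific compound is
# irrelevant
test_inhibitor <- function(ki = unit_ki, cl = 20, v = 115, fu = 0.1,
                           ka = 1) {
  inhibitor_params(name = "test inhibitor", molecular_weight = 500,
                   fu_plasma = fu, blood_plasma_ratio = 1, ka = ka,
                   f_abs = 1, cl_over_f = cl, v_central = v, ki = ki)
}

# steady-state concentration ratio under a constant unbound inhibitor
# exposure (long-run simulation; used as the dynamic route in static-oracle
# comparisons)
constant_exposure_aucr <- function(victim, iu, ki, t_end = 2000) {
  ctrl <- simulate_victim(victim, ref_phys, t_end)
  trt <- simulate_victim(victim, ref_phys, t_end,
                         iu_fun = function(t) rep(iu, length(t)), ki = ki)
  tail(trt$conc_plasma_nM, 1) / tail(ctrl$conc_plasma_nM, 1)
}
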