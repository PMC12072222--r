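# Analytic linear PK for the perpetrator: first-order absorption into a one-
# or two-compartment disposition model, solved by eigen-decomposition and
# superposed across doses. States in umol: gut (full-dose based), central,
# peripheral. Absorption into the circulation carries f_abs.
.inhibitor_ode_matrix <- function(p) {
  two <- p$q_inter > 0 && p$v_peripheral > 0
  n <- if (two) 3 else 2
  A <- matrix(0, n, n)
  A[1, 1] <- -p$ka
  A[2, 1] <- p$ka * p$f_abs
  A[2, 2] <- -(p$cl_over_f + p$q_inter) / p$v_central
  if (two) {
    A[2, 3] <- p$q_inter / p$v_peripheral
    A[3, 2] <- p$q_inter / p$v_central
    A[3, 3] <- -p$q_inter / p$v_peripheral
  }
  A
}

.inhibitor_eigen <- function(p) {
  A <- .inhibitor_ode_matrix(p)
  e <- eigen(A)
  # nudge ka if it collides with a disposition eigenvalue (defective matrix)
  if (min(abs(diff(sort(Re(e$values))))) < 1e-9 * max(abs(e$values))) {
    p$ka <- p$ka * (1 + 1e-7)
    A <- .inhibitor_ode_matrix(p)
    e <- eigen(A)
  }
  list(P = e$vectors, lambda = e$values, Pinv = solve(e$vectors))
}

# gut and central amounts (umol) on a time grid for a dosing regimen
.inhibitor_states <- function(params, regimen, times) {
  dec <- .inhibitor_eigen(params)
  n <- length(dec$lambda)
  dose_umol <- regimen$dose * 1000 / params$molecular_weight
  x0 <- c(dose_umol, rep(0, n - 1))
  w <- dec$Pinv %*% x0
  gut <- numeric(length(times))
  central <- numeric(length(times))
  dose_times <- regimen$start_time +
    regimen$interval * (seq_len(regimen$n_doses) - 1)
  for (td in dose_times) {
    idx <- times >= td
    if (!any(idx)) next
    tau <- times[idx] - td
    states <- dec$P %*% (exp(outer(dec$lambda, tau)) * drop(w))
    gut[idx] <- gut[idx] + Re(states[1, ])
    central[idx] <- central[idx] + Re(states[2, ])
  }
  list(gut = pmax(gut, 0), central = pmax(central, 0),
       dose_times = dose_times)
}

# smooth analytic unbound-inlet forcing function of time; exact within dose
# intervals (kinks only at dose times), which keeps the stiff victim
# integrator from re-stepping across interpolation-grid corners
.iu_analytic_fun <- function(params, regimen, phys, inlet = TRUE) {
  dec <- .inhibitor_eigen(params)
  n <- length(dec$lambda)
  dose_umol <- regimen$dose * 1000 / params$molecular_weight
  w <- drop(dec$Pinv %*% c(dose_umol, rep(0, n - 1)))
  p_gut <- dec$P[1, ]
  p_cen <- dec$P[2, ]
  lam <- dec$lambda
  q_pp <- phys$q_portal_blood * (1 - phys$hematocrit) * .allo_cl(phys)
  dose_times <- regimen$start_time +
    regimen$interval * (seq_len(regimen$n_doses) - 1)
  fu <- params$fu_plasma
  ka_fa <- params$ka * params$f_abs
  v_c <- params$v_central
  function(t) {
    vapply(t, function(tt) {
      td <- dose_times[dose_times <= tt]
      if (length(td) == 0 || dose_umol == 0) return(0)
      gut <- 0
      cen <- 0
      for (d in td) {
        e <- exp(lam * (tt - d)) * w
        gut <- gut + Re(sum(p_gut * e))
        cen <- cen + Re(sum(p_cen * e))
      }
      fu * (max(cen, 0) / v_c +
              if (inlet) ka_fa * max(gut, 0) / q_pp else 0)
    }, numeric(1))
  }
}

#' Unbound liver-inlet inhibitor concentration
#'
#' The driver of sinusoidal uptake inhibition: the unbound plasma
#' concentration at the liver inlet, i.e. the systemic unbound concentration
#' augmented by the first-pass absorption flux diluted into portal plasma
#' flow: `Iu = fu x (C_sys + ka x f_abs x A_gut / Q_portal_plasma)` with
#' `Q_portal_plasma = q_portal_blood x (1 - hematocrit)`.
#'
#' @param conc_sys_plasma Systemic plasma concentration (uM).
#' @param gut_amount Amount remaining in the absorption compartment (umol).
#' @param params An [inhibitor_params()].
#' @param phys A [physiology_ref()].
#' @return Unbound inlet concentration (uM); vectorized over the first two
#'   arguments.
#' @export
unbound_inlet_concentration <- function(conc_sys_plasma, gut_amount, params,
                                        phys) {
  q_pp <- phys$q_portal_blood * (1 - phys$hematocrit) * .allo_cl(phys)
  params$fu_plasma *
    (conc_sys_plasma + params$ka * params$f_abs * gut_amount / q_pp)
}

#' Simulate inhibitor concentration-time profile
#'
#' Closed-form (eigen-decomposition) solution of the linear oral PK model,
#' superposed over all doses of the regimen, reported on a grid of at most
#' 0.1 h spacing together with the unbound liver-inlet concentration that
#' drives uptake inhibition.
#'
#' @param params An [inhibitor_params()].
#' @param regimen A [dosing_regimen()].
#' @param t_end End of simulation (h); must cover the regimen.
#' @param phys A [physiology_ref()].
#' @param dt Grid spacing (h).
#' @return A tibble of class `exposure_profile` with `time_h`,
#'   `conc_plasma_uM`, `conc_inlet_unbound_uM`, `gut_umol`; summary metrics
#'   (`cmax`, `tmax`, `auc` over `[0, t_end]`, both concentration measures)
#'   are attached as attribute `metrics`.
#' @export
#' @examples
#' prof <- simulate_inhibitor_pk(example_inhibitor("rifampicin-like"),
#'                               dosing_regimen(600, 24, 1), 24)
#' attr(prof, "metrics")
simulate_inhibitor_pk <- function(params, regimen, t_end,
                                  phys = physiology_ref(), dt = 0.05) {
  dt <- min(dt, 0.1)
  last_dose <- regimen$start_time + regimen$interval * (regimen$n_doses - 1)
  if (t_end < last_dose) {
    abort("t_end does not cover the dosing regimen",
          class = "coprokin_invalid_parameter")
  }
  times <- sort(unique(c(seq(0, t_end, by = dt), regimen$start_time +
                           regimen$interval *
                           (seq_len(regimen$n_doses) - 1))))
  st <- .inhibitor_states(params, regimen, times)
  conc <- st$central / params$v_central
  inlet <- unbound_inlet_concentration(conc, st$gut, params, phys)
  out <- tibble(time_h = times, conc_plasma_uM = conc,
                conc_inlet_unbound_uM = inlet, gut_umol = st$gut)
  i_max <- which.max(conc)
  attr(out, "metrics") <- tibble(
    cmax_uM = conc[i_max], tmax_h = times[i_max],
    auc_uM_h = pracma::trapz(times, conc),
    cmax_inlet_unbound_uM = max(inlet),
    auc_inlet_unbound_uM_h = pracma::trapz(times, inlet)
  )
  attr(out, "params") <- params
  attr(out, "regimen") <- regimen
  class(out) <- c("exposure_profile", class(out))
  out
}

#' Terminal half-life of an inhibitor
#'
#' From the disposition eigenvalues: `log(2)` over the smallest elimination
#' rate constant. Reduces to `0.693 x V / CL` for a one-compartment model.
#'
#' @param params An [inhibitor_params()].
#' @return Terminal half-life (h).
#' @export
#' @examples
#' half_life(example_inhibitor("probenecid-like"))
half_life <- function(params) {
  if (params$q_inter > 0 && params$v_peripheral > 0) {
    A <- matrix(c(-(params$cl_over_f + params$q_inter) / params$v_central,
                  params$q_inter / params$v_central,
                  params$q_inter / params$v_peripheral,
                  -params$q_inter / params$v_peripheral),
                2, 2)
    lam <- eigen(A)$values
    log(2) / min(abs(Re(lam)))
  } else {
    log(2) * params$v_central / params$cl_over_f
  }
}
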