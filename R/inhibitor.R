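#' Perpetrator (inhibitor) parameter set
#'
#' Linear disposition of an orally dosed OATP1B inhibitor: first-order
#' absorption into a one- or two-compartment model, plus unbound competitive
#' inhibition constants per transporter. Set `q_inter = 0` for a
#' one-compartment model.
#'
#' @param name Compound label.
#' @param molecular_weight Molecular weight (g/mol), needed to express doses
#'   in molar units.
#' @param fu_plasma Unbound fraction in plasma.
#' @param blood_plasma_ratio Blood-to-plasma concentration ratio.
#' @param ka First-order absorption rate constant (1/h).
#' @param f_abs Fraction absorbed, Fa x Fg.
#' @param cl_over_f Systemic clearance (L/h); with `f_abs` carrying overall
#'   oral availability the pair acts as the apparent oral disposition.
#' @param v_central Central volume (L).
#' @param q_inter Intercompartmental clearance (L/h); 0 disables the
#'   peripheral compartment.
#' @param v_peripheral Peripheral volume (L).
#' @param ki Named vector of unbound inhibition constants (uM) per
#'   transporter, e.g. `c(OATP1B1 = 0.16, OATP1B3 = 0.088)`.
#' @param ki_source `"in_vitro"` or `"in_vivo_estimated"`.
#' @return An object of class `inhibitor_params`.
#' @export
inhibitor_params <- function(name = "inhibitor",
                             molecular_weight,
                             fu_plasma,
                             blood_plasma_ratio = 1,
                             ka,
                             f_abs = 1,
                             cl_over_f,
                             v_central,
                             q_inter = 0,
                             v_peripheral = 0,
                             ki,
                             ki_source = c("in_vitro", "in_vivo_estimated")) {
  ki_source <- match.arg(ki_source)
  if (any(c(ka, cl_over_f, v_central) <= 0)) {
    abort("ka, cl_over_f and v_central must be positive",
          class = "coprokin_invalid_parameter")
  }
  if (q_inter < 0 || v_peripheral < 0 || (q_inter > 0 && v_peripheral <= 0)) {
    abort("peripheral compartment requires positive q_inter and v_peripheral",
          class = "coprokin_invalid_parameter")
  }
  if (f_abs <= 0 || f_abs > 1) {
    abort("f_abs must lie in (0, 1]", class = "coprokin_invalid_parameter")
  }
  if (is.null(names(ki)) || any(ki <= 0)) {
    abort("ki must be a named vector of positive values",
          class = "coprokin_invalid_parameter")
  }
  structure(
    list(name = name, molecular_weight = molecular_weight,
         fu_plasma = fu_plasma, blood_plasma_ratio = blood_plasma_ratio,
         ka = ka, f_abs = f_abs, cl_over_f = cl_over_f,
         v_central = v_central, q_inter = q_inter,
         v_peripheral = v_peripheral, ki = ki, ki_source = ki_source),
    class = "inhibitor_params"
  )
}

#' @export
print.inhibitor_params <- function(x, ...) {
  cat(sprintf("<inhibitor_params> %s (MW %.1f)\n", x$name, x$molecular_weight))
  cat(sprintf("  fu %.3f  ka %.2f /h  F %.2f  CL %.2f L/h  Vc %.1f L",
              x$fu_plasma, x$ka, x$f_abs, x$cl_over_f, x$v_central))
  if (x$q_inter > 0) cat(sprintf("  Q %.2f L/h  Vp %.1f L", x$q_inter,
                                 x$v_peripheral))
  cat(sprintf("\n  Ki (uM, %s): %s\n", x$ki_source,
              paste(sprintf("%s %.3g", names(x$ki), x$ki), collapse = ", ")))
  invisible(x)
}

#' Dosing regimen
#'
#' @param dose Dose (mg) per administration.
#' @param interval Dosing interval (h).
#' @param n_doses Number of doses.
#' @param start_time Time of first dose (h).
#' @return An object of class `dosing_regimen`.
#' @export
#' @examples
#' dosing_regimen(600, 24, 1)
dosing_regimen <- function(dose, interval = 24, n_doses = 1, start_time = 0) {
  if (dose < 0) abort("dose must be nonnegative",
                      class = "coprokin_invalid_parameter")
  if (interval <= 0) abort("interval must be positive",
                           class = "coprokin_invalid_parameter")
  if (n_doses < 1) abort("n_doses must be at least 1",
                         class = "coprokin_invalid_parameter")
  structure(list(dose = dose, interval = interval, n_doses = n_doses,
                 start_time = start_time),
            class = "dosing_regimen")
}

#' Illustrative built-in inhibitor parameter sets
#'
#' Rifampicin-like, cyclosporine-like and probenecid-like parameter sets for
#' exploration and testing. The inhibition constants are literature in vitro
#' values (for probenecid, IC50 used directly as Ki under the assumption of
#' substrate concentration well below Km); the disposition parameters are
#' generic plausible values and are NOT validated reproductions of any
#' published trial — supply literature PK parameters for quantitative work.
#'
#' @param name One of `"rifampicin-like"`, `"cyclosporine-like"`,
#'   `"probenecid-like"`.
#' @return An `inhibitor_params` object.
#' @export
#' @examples
#' example_inhibitor("rifampicin-like")
example_inhibitor <- function(name = c("rifampicin-like", "cyclosporine-like",
                                       "probenecid-like")) {
  name <- match.arg(name)
  switch(
    name,
    "rifampicin-like" = inhibitor_params(
      name = "rifampicin-like (illustrative, non-validated)",
      molecular_weight = 822.9, fu_plasma = 0.15, blood_plasma_ratio = 0.9,
      ka = 1.2, f_abs = 0.9, cl_over_f = 12, v_central = 50,
      ki = c(OATP1B1 = 0.16, OATP1B3 = 0.088), ki_source = "in_vitro"),
    "cyclosporine-like" = inhibitor_params(
      name = "cyclosporine-like (illustrative, non-validated)",
      molecular_weight = 1202.6, fu_plasma = 0.06, blood_plasma_ratio = 1.36,
      ka = 0.7, f_abs = 0.4, cl_over_f = 23, v_central = 90,
      q_inter = 25, v_peripheral = 210,
      ki = c(OATP1B1 = 0.019, OATP1B3 = 0.032), ki_source = "in_vitro"),
    "probenecid-like" = inhibitor_params(
      name = "probenecid-like (illustrative, non-validated)",
      molecular_weight = 285.4, fu_plasma = 0.1, blood_plasma_ratio = 0.6,
      ka = 1.0, f_abs = 0.95, cl_over_f = 1.2, v_central = 12,
      ki = c(OATP1B1 = 167, OATP1B3 = 76), ki_source = "in_vitro")
  )
}
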