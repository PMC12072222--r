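#' Victim (biomarker or substrate drug) parameter set
#'
#' Describes the compound whose hepatic disposition is modeled: CP-I itself
#' (endogenous, zero-order synthesis in blood) or a dosed OATP1B substrate
#' such as a statin (set `k_syn = 0` and supply `ka`/`f_abs` plus a dosing
#' regimen at simulation time). Intrinsic clearances are expressed per
#' 10^6 hepatocytes and scaled to whole liver by
#' [scale_intrinsic_clearance()].
#'
#' @param name Compound label.
#' @param molecular_weight Molecular weight (g/mol).
#' @param log_p Octanol-water partition coefficient (carried for provenance;
#'   unused by the lumped distribution model).
#' @param pka_acid,pka_base Acid/base dissociation constants (provenance).
#' @param blood_plasma_ratio Blood-to-plasma concentration ratio.
#' @param fu_plasma Unbound fraction in plasma.
#' @param cl_renal_plasma Renal plasma clearance (L/h), implemented as an
#'   absolute observed clearance (not allometrically scaled).
#' @param k_syn Endogenous zero-order synthesis rate (mg/day/kg); 0 for dosed
#'   victims.
#' @param cl_passive_per_cell Passive diffusion clearance
#'   (uL/min/10^6 cells), acting symmetrically across the sinusoidal
#'   membrane.
#' @param cl_uptake_per_cell Named numeric vector of active sinusoidal uptake
#'   intrinsic clearances (uL/min/10^6 cells); names are transporter labels,
#'   by convention `OATP1B1` and `OATP1B3`.
#' @param cl_efflux_per_cell Named numeric vector of canalicular efflux
#'   intrinsic clearances (uL/min/10^6 cells); `MRP2` drives biliary
#'   secretion.
#' @param raf Named relative activity factors per transporter.
#' @param hepatic_scaler_gamma Calibration scalar applied uniformly to all
#'   per-cell hepatic clearances when scaling to whole liver; see
#'   [calibrate_hepatic_scaler()].
#' @param ka First-order absorption rate constant (1/h) for dosed victims.
#' @param f_abs Fraction absorbed (Fa x Fg) for dosed victims.
#' @param calibrated Logical flag marking that `hepatic_scaler_gamma` has
#'   been reconciled with a clinical baseline target.
#'
#' @return An object of class `victim_params`.
#' @seealso [cpi_victim()], [statin_like_victim()], [calibrate_victim()]
#' @export
victim_params <- function(name = "victim",
                          molecular_weight,
                          log_p = NA_real_,
                          pka_acid = NA_real_,
                          pka_base = NA_real_,
                          blood_plasma_ratio,
                          fu_plasma,
                          cl_renal_plasma,
                          k_syn = 0,
                          cl_passive_per_cell,
                          cl_uptake_per_cell,
                          cl_efflux_per_cell,
                          raf = NULL,
                          hepatic_scaler_gamma = 1,
                          ka = NA_real_,
                          f_abs = NA_real_,
                          calibrated = FALSE) {
  cls <- c(cl_renal_plasma, cl_passive_per_cell, cl_uptake_per_cell,
           cl_efflux_per_cell)
  if (any(!is.finite(cls)) || any(cls < 0)) {
    abort("all clearances must be finite and nonnegative",
          class = "coprokin_invalid_parameter")
  }
  if (fu_plasma <= 0 || fu_plasma > 1) {
    abort("fu_plasma must lie in (0, 1]", class = "coprokin_invalid_parameter")
  }
  if (blood_plasma_ratio <= 0) {
    abort("blood_plasma_ratio must be positive",
          class = "coprokin_invalid_parameter")
  }
  if (k_syn < 0) abort("k_syn must be nonnegative",
                       class = "coprokin_invalid_parameter")
  if (hepatic_scaler_gamma <= 0) {
    abort("hepatic_scaler_gamma must be positive",
          class = "coprokin_invalid_parameter")
  }
  if (is.null(names(cl_uptake_per_cell)) || is.null(names(cl_efflux_per_cell))) {
    abort("uptake and efflux clearances must be named by transporter",
          class = "coprokin_invalid_parameter")
  }
  if (is.null(raf)) {
    raf <- setNames(rep(1, length(c(cl_uptake_per_cell, cl_efflux_per_cell))),
                    c(names(cl_uptake_per_cell), names(cl_efflux_per_cell)))
  }
  structure(
    list(
      name = name,
      molecular_weight = molecular_weight,
      log_p = log_p, pka_acid = pka_acid, pka_base = pka_base,
      blood_plasma_ratio = blood_plasma_ratio,
      fu_plasma = fu_plasma,
      cl_renal_plasma = cl_renal_plasma,
      k_syn = k_syn,
      cl_passive_per_cell = cl_passive_per_cell,
      cl_uptake_per_cell = cl_uptake_per_cell,
      cl_efflux_per_cell = cl_efflux_per_cell,
      raf = raf,
      hepatic_scaler_gamma = hepatic_scaler_gamma,
      ka = ka, f_abs = f_abs,
      calibrated = isTRUE(calibrated)
    ),
    class = "victim_params"
  )
}

#' CP-I victim parameter set
#'
#' The coproporphyrin-I compound file: an ampholyte of MW 654.71 synthesized
#' at a zero-order, weight-proportional rate in blood, taken up into
#' hepatocytes by OATP1B1/OATP1B3 (with a <1% passive component) and secreted
#' into bile by MRP2, with a renal plasma clearance of 2.3 L/h. The default
#' synthesis rate is the White/Asian-Indian male value; covariate helpers
#' adjust it for sex and ethnicity.
#'
#' Returned uncalibrated (`hepatic_scaler_gamma = 1`); reconcile the hepatic
#' side with a baseline target via [calibrate_victim()] before interaction
#' simulations.
#'
#' @param k_syn Synthesis rate (mg/day/kg).
#' @param hepatic_scaler_gamma Hepatic activity scaler.
#' @param calibrated Mark the parameter set as calibrated.
#' @return A `victim_params` object.
#' @export
#' @examples
#' v <- cpi_victim()
#' v$cl_uptake_per_cell
cpi_victim <- function(k_syn = 0.0036, hepatic_scaler_gamma = 1,
                       calibrated = FALSE) {
  victim_params(
    name = "CP-I",
    molecular_weight = 654.71,
    log_p = 2.53,
    pka_acid = 3.56,
    pka_base = 5.18,
    blood_plasma_ratio = 0.628,
    fu_plasma = 0.069,
    cl_renal_plasma = 2.3,
    k_syn = k_syn,
    cl_passive_per_cell = 0.76,
    cl_uptake_per_cell = c(OATP1B1 = 106, OATP1B3 = 31),
    cl_efflux_per_cell = c(MRP2 = 0.612),
    raf = c(OATP1B1 = 1, OATP1B3 = 1, MRP2 = 1),
    hepatic_scaler_gamma = hepatic_scaler_gamma,
    calibrated = calibrated
  )
}

#' Generic statin-like dosed victim
#'
#' An illustrative exogenously dosed OATP1B substrate used as the downstream
#' victim in renal-fraction sensitivity analyses: hepatic uptake dominated by
#' OATP1B (active share of sinusoidal uptake ~78%, so the OATP1B fraction of
#' total elimination is ~0.7 at a renal fraction of 0.1). Not a model of any
#' specific marketed statin.
#'
#' @return A `victim_params` object with `k_syn = 0` and oral absorption
#'   parameters set.
#' @export
statin_like_victim <- function() {
  victim_params(
    name = "statin-like victim (synthetic)",
    molecular_weight = 480,
    blood_plasma_ratio = 0.7,
    fu_plasma = 0.1,
    cl_renal_plasma = 2.54,
    k_syn = 0,
    cl_passive_per_cell = 10,
    cl_uptake_per_cell = c(OATP1B1 = 26.25, OATP1B3 = 8.75),
    cl_efflux_per_cell = c(MRP2 = 50),
    ka = 1,
    f_abs = 0.5,
    calibrated = TRUE
  )
}

#' @export
print.victim_params <- function(x, ...) {
  cat(sprintf("<victim_params> %s (MW %.2f)\n", x$name, x$molecular_weight))
  cat(sprintf("  fu,p %.3f  B/P %.3f  CL_R %.2f L/h  k_syn %.4g mg/day/kg\n",
              x$fu_plasma, x$blood_plasma_ratio, x$cl_renal_plasma, x$k_syn))
  cat(sprintf("  per-cell CLint (uL/min/10^6): uptake [%s]  passive %.3g  efflux [%s]\n",
              paste(sprintf("%s %.4g", names(x$cl_uptake_per_cell),
                            x$cl_uptake_per_cell), collapse = ", "),
              x$cl_passive_per_cell,
              paste(sprintf("%s %.4g", names(x$cl_efflux_per_cell),
                            x$cl_efflux_per_cell), collapse = ", ")))
  cat(sprintf("  gamma %.4g (%s)\n", x$hepatic_scaler_gamma,
              if (x$calibrated) "calibrated" else "uncalibrated"))
  invisible(x)
}
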