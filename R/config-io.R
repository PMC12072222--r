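# YAML compound/inhibitor parameter files with units embedded in key names

.victim_yaml_map <- c(
  name = "name",
  molecular_weight = "molecular_weight_g_mol",
  log_p = "log_p",
  pka_acid = "pka_acid",
  pka_base = "pka_base",
  blood_plasma_ratio = "blood_plasma_ratio",
  fu_plasma = "fu_plasma",
  cl_renal_plasma = "cl_renal_plasma_L_h",
  k_syn = "k_syn_mg_day_kg",
  cl_passive_per_cell = "cl_passive_uL_min_1e6cells",
  cl_uptake_per_cell = "cl_uptake_uL_min_1e6cells",
  cl_efflux_per_cell = "cl_efflux_uL_min_1e6cells",
  raf = "raf",
  hepatic_scaler_gamma = "hepatic_scaler_gamma",
  ka = "ka_per_h",
  f_abs = "f_abs",
  calibrated = "calibrated"
)

#' Write a victim parameter file
#'
#' Serializes a [victim_params()] to YAML with units embedded in the keys.
#'
#' @param victim A `victim_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_config <- function(victim, path) {
  x <- unclass(victim)
  names(x) <- .victim_yaml_map[names(x)]
  x <- purrr::map(x, function(v) if (is.numeric(v) && !is.null(names(v)))
    as.list(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a victim parameter file
#'
#' @param path YAML file written by [write_compound_config()] (or authored
#'   by hand with the same keys).
#' @return A `victim_params`.
#' @export
read_compound_config <- function(path) {
  x <- yaml::read_yaml(path)
  inv <- setNames(names(.victim_yaml_map), .victim_yaml_map)
  names(x) <- inv[names(x)]
  for (f in c("cl_uptake_per_cell", "cl_efflux_per_cell", "raf")) {
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  do.call(victim_params, x)
}

#' Write an inhibitor parameter file
#'
#' Serializes an [inhibitor_params()] plus an optional regimen block to
#' YAML.
#'
#' @param inhibitor An `inhibitor_params`.
#' @param path Output path.
#' @param regimen Optional [dosing_regimen()].
#' @return `path`, invisibly.
#' @export
write_inhibitor_config <- function(inhibitor, path, regimen = NULL) {
  x <- list(
    name = inhibitor$name,
    molecular_weight_g_mol = inhibitor$molecular_weight,
    fu_plasma = inhibitor$fu_plasma,
    blood_plasma_ratio = inhibitor$blood_plasma_ratio,
    ka_per_h = inhibitor$ka,
    f_abs = inhibitor$f_abs,
    cl_over_f_L_h = inhibitor$cl_over_f,
    v_central_L = inhibitor$v_central,
    q_inter_L_h = inhibitor$q_inter,
    v_peripheral_L = inhibitor$v_peripheral,
    ki_uM = as.list(inhibitor$ki),
    ki_source = inhibitor$ki_source
  )
  if (!is.null(regimen)) {
    x$regimen <- list(dose_mg = regimen$dose, interval_h = regimen$interval,
                      n_doses = regimen$n_doses,
                      start_time_h = regimen$start_time)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read an inhibitor parameter file
#'
#' @param path YAML file written by [write_inhibitor_config()].
#' @return An `inhibitor_params`; if the file carries a `regimen` block it
#'   is attached as attribute `regimen`.
#' @export
read_inhibitor_config <- function(path) {
  x <- yaml::read_yaml(path)
  inh <- inhibitor_params(
    name = x$name, molecular_weight = x$molecular_weight_g_mol,
    fu_plasma = x$fu_plasma, blood_plasma_ratio = x$blood_plasma_ratio,
    ka = x$ka_per_h, f_abs = x$f_abs, cl_over_f = x$cl_over_f_L_h,
    v_central = x$v_central_L, q_inter = x$q_inter_L_h %||% 0,
    v_peripheral = x$v_peripheral_L %||% 0,
    ki = unlist(x$ki_uM), ki_source = x$ki_source %||% "in_vitro")
  if (!is.null(x$regimen)) {
    attr(inh, "regimen") <- dosing_regimen(
      x$regimen$dose_mg, x$regimen$interval_h, x$regimen$n_doses,
      x$regimen$start_time_h %||% 0)
  }
  inh
}

`%||%` <- function(a, b) if (is.null(a)) b else a
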