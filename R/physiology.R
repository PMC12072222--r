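#' Reference-subject physiology
#'
#' Bundles the physiological constants of the lumped liver model: body
#' weight, liver mass, hepatocellularity, hepatic and portal blood flows,
#' haematocrit, and the three distribution volumes (central plasma, liver
#' extracellular, liver intracellular). Defaults describe a 70-kg reference
#' adult; covariate helpers adjust `body_weight` and the model scales flows
#' and whole-liver intrinsic clearances by `(body_weight/70)^0.75` and
#' volumes by `(body_weight/70)`.
#'
#' @param body_weight Body weight (kg).
#' @param liver_mass Liver mass (g).
#' @param hepatocellularity Hepatocellularity (10^6 cells per g liver).
#' @param q_hepatic_blood Total hepatic blood flow (L/h).
#' @param q_portal_blood Portal vein blood flow (L/h), must be below
#'   `q_hepatic_blood`.
#' @param hematocrit Haematocrit (fraction of blood volume).
#' @param v_central_plasma Central (systemic plasma) volume (L).
#' @param v_liver_extracellular Liver extracellular (sinusoidal plus
#'   interstitial) volume (L).
#' @param v_liver_intracellular Liver intracellular (hepatocyte) volume (L).
#' @param allometric_exponent_cl Allometric exponent applied to flows and
#'   whole-liver intrinsic clearances.
#'
#' @return An object of class `physiology_ref`.
#' @export
#' @examples
#' physiology_ref()
#' physiology_ref(body_weight = 60)
physiology_ref <- function(body_weight = 70,
                           liver_mass = 1650,
                           hepatocellularity = 99,
                           q_hepatic_blood = 87,
                           q_portal_blood = 66,
                           hematocrit = 0.45,
                           v_central_plasma = 5,
                           v_liver_extracellular = 0.283,
                           v_liver_intracellular = 1.04,
                           allometric_exponent_cl = 0.75) {
  vals <- c(body_weight, liver_mass, hepatocellularity, q_hepatic_blood,
            q_portal_blood, v_central_plasma, v_liver_extracellular,
            v_liver_intracellular)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all physiological quantities must be finite and positive",
          class = "coprokin_invalid_parameter")
  }
  if (q_portal_blood >= q_hepatic_blood) {
    abort("portal blood flow must be below total hepatic blood flow",
          class = "coprokin_invalid_parameter")
  }
  if (hematocrit <= 0 || hematocrit >= 1) {
    abort("hematocrit must lie in (0, 1)",
          class = "coprokin_invalid_parameter")
  }
  structure(
    list(
      body_weight = body_weight,
      liver_mass = liver_mass,
      hepatocellularity = hepatocellularity,
      q_hepatic_blood = q_hepatic_blood,
      q_portal_blood = q_portal_blood,
      hematocrit = hematocrit,
      v_central_plasma = v_central_plasma,
      v_liver_extracellular = v_liver_extracellular,
      v_liver_intracellular = v_liver_intracellular,
      allometric_exponent_cl = allometric_exponent_cl
    ),
    class = "physiology_ref"
  )
}

#' @export
print.physiology_ref <- function(x, ...) {
  cat("<physiology_ref>\n")
  cat(sprintf("  body weight   %.1f kg\n", x$body_weight))
  cat(sprintf("  liver         %.0f g x %.0f x 10^6 cells/g\n",
              x$liver_mass, x$hepatocellularity))
  cat(sprintf("  Q hepatic     %.1f L/h blood (portal %.1f L/h, Hct %.2f)\n",
              x$q_hepatic_blood, x$q_portal_blood, x$hematocrit))
  cat(sprintf("  volumes       Vc %.2f / Vec %.3f / Vic %.2f L\n",
              x$v_central_plasma, x$v_liver_extracellular,
              x$v_liver_intracellular))
  invisible(x)
}

# allometric scalar for clearances/flows
.allo_cl <- function(phys) (phys$body_weight / .REF_BW)^phys$allometric_exponent_cl
# allometric scalar for volumes
.allo_v <- function(phys) phys$body_weight / .REF_BW
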