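#' Tidy a Ki estimate
#'
#' @param x A `ki_estimate`.
#' @param ... Ignored.
#' @return A tibble with one row per transporter: `transporter`, `ki_uM`,
#'   plus the objective and assumed renal fraction.
#' @method tidy ki_estimate
#' @export
tidy.ki_estimate <- function(x, ...) {
  tibble(transporter = names(x$ki_map), ki_uM = unname(x$ki_map),
         objective = x$objective, fe_assumed = x$fe_assumed)
}

#' Glance at a Ki estimate
#'
#' @param x A `ki_estimate`.
#' @param ... Ignored.
#' @return A one-row tibble: `ki_oatp1b1_uM`, `objective`, `fe_assumed`,
#'   `residual`, `non_identifiable`.
#' @method glance ki_estimate
#' @export
glance.ki_estimate <- function(x, ...) {
  tibble(ki_oatp1b1_uM = x$ki_in_vivo, objective = x$objective,
         fe_assumed = x$fe_assumed, residual = x$convergence$residual,
         non_identifiable = isTRUE(x$convergence$non_identifiable))
}

#' Tidy a DDI outcome
#'
#' @param x A `ddi_outcome`.
#' @param ... Ignored.
#' @return A one-row tibble of the interaction metrics.
#' @method tidy ddi_outcome
#' @export
tidy.ddi_outcome <- function(x, ...) {
  dplyr::bind_cols(
    tibble(victim = x$victim, inhibitor = x$inhibitor,
           dose_mg = x$dose_mg),
    x$metrics
  )
}

#' Glance at a DDI outcome
#'
#' @param x A `ddi_outcome`.
#' @param ... Ignored.
#' @return A one-row tibble: the two ratios plus control and treatment
#'   exposure metrics.
#' @method glance ddi_outcome
#' @export
glance.ddi_outcome <- function(x, ...) {
  tibble(cmax_ratio = x$metrics$cmax_ratio,
         auc_ratio = x$metrics$auc_ratio,
         control_cmax = x$control_metrics$cmax,
         control_auc = x$control_metrics$auc,
         treatment_cmax = x$treatment_metrics$cmax,
         treatment_auc = x$treatment_metrics$auc)
}
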