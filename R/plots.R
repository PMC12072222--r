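#' Plot an inhibitor exposure profile
#'
#' Systemic plasma and unbound liver-inlet concentration against time.
#'
#' @param object An `exposure_profile` from [simulate_inhibitor_pk()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot exposure_profile
#' @export
autoplot.exposure_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_h", "conc_plasma_uM",
                          "conc_inlet_unbound_uM")],
    -"time_h", names_to = "measure", values_to = "conc_uM")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$conc_uM,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(conc_plasma_uM = "grey30", conc_inlet_unbound_uM = "firebrick"),
      labels = c(conc_plasma_uM = "systemic plasma",
                 conc_inlet_unbound_uM = "unbound liver inlet")) +
    ggplot2::labs(x = "time (h)", y = expression(concentration~(mu*M)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a drug-biomarker interaction outcome
#'
#' Control and treatment biomarker concentration-time profiles with the
#' metric window shaded.
#'
#' @param object A `ddi_outcome` from [simulate_ddi()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ddi_outcome
#' @export
autoplot.ddi_outcome <- function(object, ...) {
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(.data$time_h, .data$conc_plasma_nM,
                               colour = .data$arm)) +
    ggplot2::annotate("rect", xmin = object$window[1],
                      xmax = object$window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "CP-I plasma concentration (nM)",
                  colour = NULL,
                  subtitle = sprintf("CmaxR %.2f, AUCR %.2f",
                                     object$metrics$cmax_ratio,
                                     object$metrics$auc_ratio)) +
    ggplot2::theme_minimal()
}

#' Plot baseline across covariate scenarios
#'
#' @param object A `baseline_scenario_table`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot baseline_scenario_table
#' @export
autoplot.baseline_scenario_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$genotype, .data$css_nM,
                               colour = .data$ethnicity,
                               shape = .data$sex)) +
    ggplot2::geom_point(size = 2.5,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "SLCO1B1 c.521T>C genotype",
                  y = "predicted CP-I baseline (nM)") +
    ggplot2::theme_minimal()
}

#' Plot Ki sensitivity to the assumed renal fraction
#'
#' Estimated OATP1B1 Ki (log scale) and the downstream victim AUC ratio
#' against the assumed renal elimination fraction.
#'
#' @param object An `fe_sensitivity` table from [fe_sensitivity()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot fe_sensitivity
#' @export
autoplot.fe_sensitivity <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"fe",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$fe, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "assumed renal elimination fraction fe", y = NULL) +
    ggplot2::theme_minimal()
}
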