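#' Fold-error criterion
#'
#' TRUE when `1/k <= predicted/observed <= k`; boundaries inclusive.
#' Vectorized over prediction-observation pairs.
#'
#' @param predicted,observed Positive values (ratios or concentrations, same
#'   units).
#' @param k Fold limit (> 1), e.g. 1.5 or 2.
#' @return Logical vector.
#' @export
#' @examples
#' within_fold(1.4, 1.0, 1.5)
#' within_fold(0.5, 1.0, 1.5)
within_fold <- function(predicted, observed, k = 2) {
  if (k <= 1) abort("fold limit k must exceed 1",
                    class = "coprokin_invalid_parameter")
  if (any(predicted <= 0) || any(observed <= 0)) {
    abort("predicted and observed values must be positive",
          class = "coprokin_invalid_parameter")
  }
  r <- predicted / observed
  r >= 1 / k & r <= k
}

#' Guest-criterion acceptance limits
#'
#' The interaction-prediction acceptance band that narrows as the observed
#' ratio approaches 1: for `r_obs >= 1` the limit is
#' `L = (delta + 2 (r_obs - 1)) / r_obs` and the acceptable predicted range
#' is `[r_obs/L, r_obs x L]`; for `r_obs < 1` the band is computed on
#' `1/r_obs` and inverted.
#'
#' @param r_obs Observed ratio(s), positive.
#' @param delta Variability term (>= 1); 1 gives the strict band, 1.25
#'   relaxes it to the bioequivalence width at `r_obs = 1`.
#' @return A tibble with columns `r_obs`, `lower`, `upper`.
#' @export
#' @examples
#' guest_limits(2)        # [1.33, 3.0]
#' guest_limits(1, 1.25)  # [0.8, 1.25]
guest_limits <- function(r_obs, delta = 1) {
  if (any(r_obs <= 0)) abort("r_obs must be positive",
                             class = "coprokin_invalid_parameter")
  if (delta < 1) abort("delta must be at least 1",
                       class = "coprokin_invalid_parameter")
  r_eff <- pmax(r_obs, 1 / r_obs)
  limit <- (delta + 2 * (r_eff - 1)) / r_eff
  tibble(r_obs = r_obs, lower = r_obs / limit, upper = r_obs * limit)
}

#' Guest-criterion membership
#'
#' @inheritParams within_fold
#' @param delta Guest variability term, see [guest_limits()].
#' @return Logical vector: prediction within the Guest band of its
#'   observation (boundaries inclusive).
#' @export
within_guest <- function(predicted, observed, delta = 1) {
  if (any(predicted <= 0)) abort("predicted values must be positive",
                                 class = "coprokin_invalid_parameter")
  lim <- guest_limits(observed, delta)
  predicted >= lim$lower & predicted <= lim$upper
}

#' Geometric mean fold error
#'
#' `10^mean(|log10(pred/obs)|)` by default (conventional GMFE, always >= 1);
#' with `absolute = FALSE` the signed variant `10^mean(log10(pred/obs))`,
#' which is the geometric mean prediction ratio (bias: < 1 indicates
#' underprediction).
#'
#' @inheritParams within_fold
#' @param absolute Use absolute log fold errors (default).
#' @return Scalar fold error.
#' @export
#' @examples
#' gmfe(c(2, 1), c(1, 2))            # 2 (absolute)
#' gmfe(c(2, 1), c(1, 2), FALSE)     # 1 (signed, errors cancel)
gmfe <- function(predicted, observed, absolute = TRUE) {
  if (length(predicted) == 0) abort("empty prediction set",
                                    class = "coprokin_invalid_parameter")
  if (any(predicted <= 0) || any(observed <= 0)) {
    abort("predicted and observed values must be positive",
          class = "coprokin_invalid_parameter")
  }
  lfe <- log10(predicted / observed)
  if (absolute) lfe <- abs(lfe)
  10^mean(lfe)
}

#' Summarize prediction accuracy of a pred/obs table
#'
#' Applies the 1.5-fold, 2-fold and Guest criteria and the geometric mean
#' fold error to a table of prediction-observation pairs.
#'
#' @param data Data frame of pairs.
#' @param predicted,observed Column names.
#' @param delta Guest variability term.
#' @return One-row tibble: `n`, `pct_within_1_5`, `pct_within_2`,
#'   `pct_within_guest`, `gmfe`, `gm_ratio` (signed bias).
#' @export
#' @examples
#' evaluate_predictions(evaluation_fixture())
evaluate_predictions <- function(data, predicted = "predicted",
                                 observed = "observed", delta = 1) {
  p <- data[[predicted]]
  o <- data[[observed]]
  tibble(
    n = length(p),
    pct_within_1_5 = 100 * mean(within_fold(p, o, 1.5)),
    pct_within_2 = 100 * mean(within_fold(p, o, 2)),
    pct_within_guest = 100 * mean(within_guest(p, o, delta)),
    gmfe = gmfe(p, o),
    gm_ratio = gmfe(p, o, absolute = FALSE)
  )
}
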