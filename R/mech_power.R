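#' Mechanical power of pressure-controlled ventilation
#'
#' Simplified mechanical-power equation for pressure-controlled modes with
#' decelerating flow:
#'
#'   M_P = 0.098 * RR * VT * (dP + PEEP)   [J/min]
#'
#' with VT in liters. Linear in each argument; M_P depends on the pressure
#' terms only through their sum dP + PEEP.
#'
#' @param rr respiratory rate, breaths/min.
#' @param vt_l tidal volume, liters.
#' @param dp driving pressure (PIP - PEEP), cmH2O.
#' @param peep cmH2O.
#' @return J/min.
#' @export
#' @examples
#' mechanical_power(12, 0.017 * 46, 49, 2)  # injurious-phase group means: ~47
#' mechanical_power(20, 0.276, 14, 12)      # 14.06
mechanical_power <- function(rr, vt_l, dp, peep) {
  if (any(c(rr, vt_l, dp, peep) < 0)) stop("mechanical_power: inputs must be non-negative")
  0.098 * rr * vt_l * (dp + peep)
}

#' Summarize per-breath mechanical power over a window
#'
#' @param breaths data.frame of breath records containing an `mp` column
#'   (J/min), e.g. a slice of an experiment log.
#' @param window optional label attached to the result.
#' @return list with `window`, `n`, `mean`, `sd`.
#' @export
phase_mp_summary <- function(breaths, window = "window") {
  if (is.null(breaths) || nrow(breaths) == 0) stop("phase_mp_summary: empty window")
  mp <- breaths$mp
  list(window = window, n = length(mp), mean = mean(mp),
       sd = if (length(mp) > 1) sd(mp) else 0)
}
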