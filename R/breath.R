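#' Ventilator settings
#'
#' Two pressure-controlled contracts are supported. `PCV_VG` (volume
#' guarantee) titrates the driving pressure once per breath from the previous
#' breath's dynamic compliance, dP = VT_target / Crs(prev), capped at
#' `pip_limit`; delivered VT then follows the current breath's realized
#' compliance. `PCV_FIXED_DP` applies a fixed driving pressure (recruitment
#' maneuvers and PEEP trials).
#'
#' @param mode `"PCV_VG"` or `"PCV_FIXED_DP"`.
#' @param fio2 inspired oxygen fraction, in [0.21, 1].
#' @param peep cmH2O, >= 0.
#' @param rr breaths/min, >= 1.
#' @param vt_target mL/kg (PCV_VG mode).
#' @param dp driving pressure cmH2O (PCV_FIXED_DP mode).
#' @param ie inspiratory:expiratory ratio label (metadata only).
#' @param pip_limit absolute PIP cap, cmH2O.
#' @return object of class `vent_settings`.
#' @export
vent_settings <- function(mode = c("PCV_VG", "PCV_FIXED_DP"), fio2 = 1.0, peep = 5,
                          rr = 20, vt_target = NULL, dp = NULL, ie = "1:2",
                          pip_limit = 60) {
  mode <- match.arg(mode)
  stopifnot(fio2 >= 0.21, fio2 <= 1, peep >= 0, rr >= 1, pip_limit > peep)
  if (mode == "PCV_VG" && is.null(vt_target)) stop("PCV_VG requires vt_target (mL/kg)")
  if (mode == "PCV_FIXED_DP" && is.null(dp)) stop("PCV_FIXED_DP requires dp (cmH2O)")
  structure(list(mode = mode, fio2 = fio2, peep = peep, rr = rr,
                 vt_target = vt_target, dp = dp, ie = ie, pip_limit = pip_limit),
            class = "vent_settings")
}

protocol_halt <- function(message, pig) {
  structure(class = c("pigvent_halt", "error", "condition"),
            list(message = message, call = sys.call(-1), pig = pig))
}

#' Simulate one quasi-static breath
#'
#' Unit rules: (a) closed units whose opening pressure is reached by PIP open
#' during inspiration; (b) at end-expiration, open units whose closing
#' pressure exceeds PEEP collapse; (c) units that opened and re-collapsed
#' within the same breath are *cyclic* — they suffer atelectrauma and
#' consolidate with `cyclic_consolidation_prob`, and their closing pressures
#' creep upward by `cyclic_pressure_creep` per event (surfactant
#' inactivation; opening pressures follow at `cyclic_creep_opening_frac`,
#' and the creep saturates at `cyclic_creep_ceiling`); open units whose
#' tidal strain exceeds
#' `overdistension_strain_threshold` consolidate with
#' `overdistension_consolidation_prob`; (d) realized dynamic compliance is
#' `stiff_compliance + compliance_scale * end-inspiratory open fraction *
#' od_factor(PIP)` where the overdistension factor is ~1 at low PIP, and
#' VT = Crs * dP.
#'
#' @param pig a living `pig`.
#' @param settings a [vent_settings()] object.
#' @return `list(pig =, record =)` where `record` is a named numeric vector
#'   with the realized breath (pip, peep, dp, vt_ml, rr, fio2, crs, mp) and
#'   the aeration bookkeeping used by gas exchange (frac_open_insp,
#'   frac_open_exp, frac_cyclic, frac_never, frac_consolidated).
#' @export
step_breath <- function(pig, settings) {
  if (!pig$alive) stop(protocol_halt("pig is dead: protocol halt", pig))
  lung <- pig$params$lung
  injury <- pig$params$injury
  bw <- pig$bw

  if (settings$mode == "PCV_VG") {
    dp_target <- settings$vt_target * bw / pig$crs_last
    # ventilators ramp the inspiratory pressure; rate-limiting also keeps the
    # VG feedback loop stable when compliance changes abruptly
    lim <- lung$dp_rate_limit
    dp <- max(min(dp_target, pig$dp_last + lim), pig$dp_last - lim)
    dp <- max(1, min(dp, settings$pip_limit - settings$peep))
  } else {
    dp <- min(settings$dp, settings$pip_limit - settings$peep)
  }
  pig$dp_last <- dp
  peep <- settings$peep
  pip <- peep + dp

  open0 <- pig$state == 1L
  closed0 <- pig$state == 0L
  n <- length(pig$state)

  opened_now <- closed0 & pig$opening <= pip
  open_insp <- open0 | opened_now
  close_now <- open_insp & pig$closing > peep
  open_end <- open_insp & !close_now
  cyclic <- opened_now & close_now

  frac_insp <- sum(open_insp) / n
  s_od <- od_factor(pip, lung, sum(pig$state == 2L) / n)
  crs <- pig$stiff_compliance + pig$compliance_scale * frac_insp * s_od
  vt <- crs * dp

  # injury draws (only for candidate units, deterministic under seed)
  # per-unit strain: tidal volume shared by open units over per-unit capacity
  capacity <- pig$compliance_scale * lung$capacity_cmh2o
  strain <- if (frac_insp > 0) vt / (frac_insp * capacity) else 0
  cons <- logical(n)
  ci <- which(cyclic)
  if (length(ci) && injury$cyclic_consolidation_prob > 0) {
    cons[ci[runif(length(ci)) < injury$cyclic_consolidation_prob]] <- TRUE
  }
  if (strain > injury$overdistension_strain_threshold &&
      injury$overdistension_consolidation_prob > 0) {
    oi <- which(open_insp & !cons)
    if (length(oi)) {
      cons[oi[runif(length(oi)) < injury$overdistension_consolidation_prob]] <- TRUE
    }
  }
  if (length(ci) && injury$cyclic_pressure_creep > 0) {
    # atelectrauma destabilizes units: closing pressures creep upward (towards
    # a saturation ceiling — surfactant inactivation cannot push alveolar
    # instability beyond mid-range airway pressures), opening pressures by a
    # fraction (the unit becomes harder to keep open faster than harder to open)
    cl <- pig$closing[ci]
    pig$closing[ci] <- pmin(cl + injury$cyclic_pressure_creep,
                            pmax(cl, injury$cyclic_creep_ceiling))
    pig$opening[ci] <- pig$opening[ci] +
      injury$cyclic_creep_opening_frac * injury$cyclic_pressure_creep
    pig$opening[ci] <- pmax(pig$opening[ci], pig$closing[ci] + 0.5)
  }

  state <- pig$state
  state[open_end] <- 1L
  state[close_now] <- 0L
  state[cons] <- 2L
  pig$state <- state
  pig$cumulative_cyclic_events <- pig$cumulative_cyclic_events + length(ci)
  pig$crs_last <- crs

  record <- c(
    pip = pip, peep = peep, dp = dp, vt_ml = vt, rr = settings$rr,
    fio2 = settings$fio2, crs = crs, mp = mechanical_power(settings$rr, vt / 1000, dp, peep),
    frac_open_insp = frac_insp,
    frac_open_exp = sum(open_end) / n,
    frac_cyclic = length(ci) / n,
    frac_never = sum(closed0 & !opened_now) / n,
    frac_consolidated = sum(state == 2L) / n,
    s_od = s_od,
    strain = strain
  )
  list(pig = pig, record = record)
}
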