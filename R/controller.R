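#' ARDSNet-style closed-loop controller
#'
#' Implements the automated protective-ventilation algorithm: an SpO2 target
#' band of 88-95% drives single-row moves along a "higher PEEP / lower FiO2"
#' table (with a dwell time between moves to prevent oscillation); tidal
#' volume is stepped down 6 -> 5 -> 4 mL/kg whenever observed PIP strictly
#' exceeds 30 cmH2O (no automatic re-escalation); arterial pH, supplied once
#' every 30 simulated minutes, titrates the respiratory rate in steps of
#' +/- 5/min between `rr_min` and the hard cap of 35/min.
#'
#' @param params parameter list from [pv_params()]; the PEEP/FiO2 table and
#'   all bands/limits live under `params$controller`.
#' @param rr_init initial respiratory rate, breaths/min.
#' @param index_init initial table row (1-based). Default is the row pair
#'   (FiO2 0.5, PEEP 16), a mid-table clinical handover point.
#' @param t0 simulation time at instantiation, s.
#' @return object of class `vent_controller`.
#' @export
make_controller <- function(params = pv_params(), rr_init = 20, index_init = NULL,
                            t0 = 0) {
  cp <- params$controller
  table <- data.frame(fio2 = cp$table$fio2, peep = cp$table$peep)
  stopifnot(!is.unsorted(table$fio2), !is.unsorted(table$peep))
  if (is.null(index_init)) {
    index_init <- which(table$fio2 >= 0.5 & table$peep >= 16)[1]
    if (is.na(index_init)) index_init <- 1L
  }
  stopifnot(index_init >= 1, index_init <= nrow(table))
  structure(list(
    table = table,
    index = as.integer(index_init),
    vt_step = 6,
    rr = min(rr_init, cp$rr_max),
    spo2_low = cp$spo2_low, spo2_high = cp$spo2_high,
    ph_low = cp$ph_low, ph_high = cp$ph_high,
    rr_step = cp$rr_step, rr_max = cp$rr_max, rr_min = cp$rr_min,
    pip_threshold = cp$pip_threshold,
    dwell_s = cp$dwell_s, oxy_eval_s = cp$oxy_eval_s,
    ph_interval_s = cp$ph_interval_s,
    pip_limit = cp$pip_limit,
    last_move_time = -Inf, last_eval_time = -Inf, last_ph_time = t0,
    events = list()
  ), class = "vent_controller")
}

log_event <- function(ctrl, now, rule, from, to) {
  ctrl$events[[length(ctrl$events) + 1L]] <-
    data.frame(time_s = now, rule = rule, from = from, to = to)
  ctrl
}

#' Oxygenation rule: move along the PEEP/FiO2 table from SpO2
#'
#' Below-band SpO2 (< 88%) moves one row toward higher PEEP/FiO2; above-band
#' (> 95%) one row toward lower, each clamped at the table ends and rate-
#' limited by the dwell time. Emitted settings are always an exact table row.
#'
#' @param ctrl a `vent_controller`.
#' @param spo2 pulse-oximeter saturation, fraction.
#' @param now simulation time, s.
#' @return updated controller.
#' @export
tick_oxygenation <- function(ctrl, spo2, now) {
  if (now - ctrl$last_move_time < ctrl$dwell_s) return(ctrl)
  old <- ctrl$index
  if (spo2 < ctrl$spo2_low) {
    ctrl$index <- min(ctrl$index + 1L, nrow(ctrl$table))
  } else if (spo2 > ctrl$spo2_high) {
    ctrl$index <- max(ctrl$index - 1L, 1L)
  }
  if (ctrl$index != old) {
    ctrl$last_move_time <- now
    ctrl <- log_event(ctrl, now, "peep_fio2_table", old, ctrl$index)
  }
  ctrl
}

#' Tidal-volume rule: step down on high PIP
#'
#' When observed PIP strictly exceeds 30 cmH2O the tidal-volume setpoint
#' drops one level along 6 -> 5 -> 4 mL/kg (floor 4). Reduction only; the
#' setpoint is never re-escalated automatically.
#'
#' @param ctrl a `vent_controller`.
#' @param observed_pip cmH2O.
#' @param now simulation time, s (for the event log).
#' @return updated controller.
#' @export
tick_tidal_volume <- function(ctrl, observed_pip, now = NA_real_) {
  if (observed_pip > ctrl$pip_threshold && ctrl$vt_step > 4) {
    old <- ctrl$vt_step
    ctrl$vt_step <- ctrl$vt_step - 1
    ctrl <- log_event(ctrl, now, "vt_step_down", old, ctrl$vt_step)
  }
  ctrl
}

#' Acid-base rule: titrate RR from arterial pH
#'
#' pH < 7.30 raises RR by 5/min (cap 35); pH > 7.45 lowers it by 5/min
#' (floor `rr_min`). Intended to be driven on the 30-min pH input schedule.
#'
#' @param ctrl a `vent_controller`.
#' @param ph arterial pH.
#' @param now simulation time, s.
#' @return updated controller.
#' @export
tick_acid_base <- function(ctrl, ph, now = NA_real_) {
  old <- ctrl$rr
  if (ph < ctrl$ph_low) {
    ctrl$rr <- min(ctrl$rr + ctrl$rr_step, ctrl$rr_max)
  } else if (ph > ctrl$ph_high) {
    ctrl$rr <- max(ctrl$rr - ctrl$rr_step, ctrl$rr_min)
  }
  if (!is.na(now)) ctrl$last_ph_time <- now
  if (ctrl$rr != old) ctrl <- log_event(ctrl, now, "rr_titration", old, ctrl$rr)
  ctrl
}

#' One composite controller evaluation
#'
#' Applies the oxygenation rule on its 30-s evaluation cadence, the
#' tidal-volume rule on every breath summary, and the acid-base rule on the
#' 30-min pH schedule, then emits the commanded settings: PCV with volume
#' guarantee at the current VT step, (FiO2, PEEP) from the current table row,
#' RR from state, I:E 1:2. Deterministic given its input sequence.
#'
#' @param ctrl a `vent_controller`.
#' @param bg a `blood_gas` (supplies SpO2 and pH).
#' @param last_breath breath record from [step_breath()] (supplies PIP), or
#'   `NULL` before the first breath.
#' @param now simulation time, s.
#' @return `list(ctrl =, settings =)`.
#' @export
controller_step <- function(ctrl, bg, last_breath, now) {
  if (now - ctrl$last_eval_time >= ctrl$oxy_eval_s) {
    ctrl <- tick_oxygenation(ctrl, bg$spo2, now)
    # tidal volume is judged on the same evaluation cadence, so single-breath
    # pressure transients do not trigger an (irreversible) VT reduction
    if (!is.null(last_breath)) {
      ctrl <- tick_tidal_volume(ctrl, last_breath[["pip"]], now)
    }
    ctrl$last_eval_time <- now
  }
  if (now - ctrl$last_ph_time >= ctrl$ph_interval_s) {
    ctrl <- tick_acid_base(ctrl, bg$ph, now)
  }
  row <- ctrl$table[ctrl$index, ]
  settings <- vent_settings(
    mode = "PCV_VG", fio2 = row$fio2, peep = row$peep, rr = ctrl$rr,
    vt_target = ctrl$vt_step, ie = "1:2", pip_limit = ctrl$pip_limit
  )
  list(ctrl = ctrl, settings = settings)
}

#' Controller event log as a data frame
#' @param ctrl a `vent_controller`.
#' @return data.frame with columns time_s, rule, from, to.
#' @export
controller_events <- function(ctrl) {
  if (!length(ctrl$events)) {
    return(data.frame(time_s = numeric(), rule = character(),
                      from = numeric(), to = numeric()))
  }
  do.call(rbind, ctrl$events)
}
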