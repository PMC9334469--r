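## Protocol engine: baseline, lavage, recruitment maneuvers, volume history,
## decremental PEEP trials, ventilation phases, full two-arm experiment.

breath_cols <- c(
  "time_s", "pip", "peep", "dp", "vt_ml", "rr", "fio2", "crs", "mp",
  "frac_open_insp", "frac_open_exp", "frac_cyclic", "frac_never",
  "frac_consolidated", "s_od", "strain",
  "pao2", "paco2", "ph", "spo2", "co", "do2", "pf"
)

update_death <- function(pig, pao2, dt) {
  d <- pig$params$death
  if (pao2 < d$pao2_threshold) {
    pig$hypox_s <- pig$hypox_s + dt
    if (pig$hypox_s >= d$sustain_s) pig$alive <- FALSE
  } else {
    pig$hypox_s <- 0
  }
  pig
}

# Run n_breaths at fixed settings; stops early (truncated log) on death.
run_segment <- function(pig, settings, n_breaths, t0) {
  out <- matrix(NA_real_, n_breaths, length(breath_cols),
                dimnames = list(NULL, breath_cols))
  t <- t0
  bg <- NULL
  used <- 0L
  for (i in seq_len(n_breaths)) {
    sb <- step_breath(pig, settings)
    pig <- sb$pig
    rec <- sb$record
    bg <- blood_gas(pig, rec)
    dt <- 60 / settings$rr
    t <- t + dt
    pig <- update_death(pig, bg$pao2, dt)
    out[i, ] <- c(t, rec, bg$pao2, bg$paco2, bg$ph, bg$spo2, bg$co, bg$do2,
                  bg$pf_ratio)
    used <- i
    if (!pig$alive) break
  }
  list(pig = pig, records = out[seq_len(used), , drop = FALSE], bg = bg, t = t)
}

#' Baseline ventilation with RR servo on PaCO2
#'
#' One hour of protective ventilation (PCV-VG, VT 6 mL/kg, PEEP 7, I:E 1:2,
#' FiO2 1.0) with the respiratory rate adjusted every 5 simulated minutes in
#' steps of 2/min to hold PaCO2 in 37-45 mmHg. If the band cannot be reached
#' within the RR limits a warning is emitted and the run continues.
#'
#' @param pig a healthy `pig`.
#' @param params parameter list.
#' @param minutes baseline duration.
#' @param t0 start time, s.
#' @param rr_init starting respiratory rate.
#' @return list with `pig`, `records`, `bg` (final), `rr` (final), `t`.
#' @export
run_baseline <- function(pig, params = pig$params, minutes = params$protocol$baseline_min,
                         t0 = 0, rr_init = 16) {
  cp <- params$controller
  rr <- rr_init
  t <- t0
  blocks <- max(1L, ceiling(minutes / 5))
  recs <- vector("list", blocks)
  bg <- NULL
  for (b in seq_len(blocks)) {
    s <- vent_settings("PCV_VG", fio2 = 1.0, peep = 7, rr = rr, vt_target = 6,
                       pip_limit = cp$pip_limit)
    seg <- run_segment(pig, s, n_breaths = round(5 * rr), t0 = t)
    pig <- seg$pig; t <- seg$t; bg <- seg$bg; recs[[b]] <- seg$records
    if (!pig$alive) break
    if (bg$paco2 > 45) rr <- min(rr + 2, cp$rr_max)
    if (bg$paco2 < 37) rr <- max(rr - 2, cp$rr_min)
  }
  if (pig$alive && (bg$paco2 > 45 || bg$paco2 < 37)) {
    warning("baseline: PaCO2 ", round(bg$paco2, 1),
            " mmHg outside 37-45 band at RR limit")
  }
  list(pig = pig, records = do.call(rbind, recs), bg = bg, rr = rr, t = t)
}

#' Saline-lavage procedure to the hypoxemia criterion
#'
#' Repeats lavage cycles, each followed by a 10-min qualification window of
#' VT 6 mL/kg / PEEP 6 / FiO2 1.0 ventilation, until PaO2 stays below
#' 100 mmHg for the entire window. Errors if the criterion is not met within
#' `lavage_max_cycles` cycles (mis-calibrated injury parameters).
#'
#' @param pig a `pig` after baseline.
#' @param params parameter list.
#' @param t0 start time, s.
#' @param rr respiratory rate during qualification windows.
#' @return list with `pig`, `bg` (the qualifying blood gas), `n_cycles`,
#'   `records`, `t`.
#' @export
run_lavage <- function(pig, params = pig$params, t0 = 0, rr = 16) {
  pr <- params$protocol
  t <- t0
  recs <- list()
  for (cycle in seq_len(pr$lavage_max_cycles)) {
    pig <- apply_lavage_cycle(pig, params$injury)
    s <- vent_settings("PCV_VG", fio2 = 1.0, peep = 6, rr = rr, vt_target = 6,
                       pip_limit = params$controller$pip_limit)
    # settle period before the judged window: gas exchange carries over from
    # the previous state for a few breaths after each lavage
    n_settle <- round(pr$lavage_settle_min * rr)
    seg <- run_segment(pig, s, n_breaths = n_settle + round(pr$lavage_window_min * rr),
                       t0 = t)
    pig <- seg$pig; t <- seg$t
    recs[[length(recs) + 1L]] <- seg$records
    if (!pig$alive) {
      return(list(pig = pig, bg = seg$bg, n_cycles = cycle,
                  records = do.call(rbind, recs), t = t))
    }
    judged <- seg$records[-seq_len(min(n_settle, nrow(seg$records) - 1)), , drop = FALSE]
    if (all(judged[, "pao2"] < 100)) {
      return(list(pig = pig, bg = seg$bg, n_cycles = cycle,
                  records = do.call(rbind, recs), t = t))
    }
  }
  stop("run_lavage: PaO2 < 100 mmHg criterion not reached within ",
       pr$lavage_max_cycles, " cycles; injury parameters are mis-calibrated")
}

#' Alveolar recruitment maneuver with standardized post-RM assessment
#'
#' Ladder: PEEP 12 -> 16 -> 20 -> 24 at fixed driving pressure 20 cmH2O
#' (RR 20, 5 breaths per rung), then 5 cycles at PIP 50 / PEEP 24, then
#' 5 min at PEEP 15 / VT 6 mL/kg during which the standardized assessment
#' (blood gas, dynamic Crs, M_P, cardiac output) is taken at minute 5.
#'
#' @param pig a living `pig`.
#' @param params parameter list.
#' @param t0 start time, s.
#' @return list with `pig`, `records`, `assessment` (list: bg, crs, mp, co,
#'   breath), `max_pip_commanded`, `t`. On death mid-maneuver the log is
#'   truncated and `assessment` is `NULL`.
#' @export
run_recruitment_maneuver <- function(pig, params = pig$params, t0 = 0) {
  pr <- params$protocol
  t <- t0
  recs <- list()
  max_pip <- -Inf
  rungs <- c(12, 16, 20, 24)
  for (peep in rungs) {
    s <- vent_settings("PCV_FIXED_DP", fio2 = 1.0, peep = peep, rr = 20, dp = 20)
    max_pip <- max(max_pip, peep + 20)
    seg <- run_segment(pig, s, pr$rm_rung_breaths, t0 = t)
    pig <- seg$pig; t <- seg$t; recs[[length(recs) + 1L]] <- seg$records
    if (!pig$alive) {
      return(list(pig = pig, records = do.call(rbind, recs), assessment = NULL,
                  max_pip_commanded = max_pip, t = t))
    }
  }
  # plateau: PIP 50 at PEEP 24
  s <- vent_settings("PCV_FIXED_DP", fio2 = 1.0, peep = 24, rr = 20, dp = 50 - 24)
  max_pip <- max(max_pip, 50)
  seg <- run_segment(pig, s, 5, t0 = t)
  pig <- seg$pig; t <- seg$t; recs[[length(recs) + 1L]] <- seg$records
  if (!pig$alive) {
    return(list(pig = pig, records = do.call(rbind, recs), assessment = NULL,
                max_pip_commanded = max_pip, t = t))
  }
  # standardized conditions: PEEP 15, VT 6 mL/kg, 5 min
  s <- vent_settings("PCV_VG", fio2 = 1.0, peep = 15, rr = 20, vt_target = 6,
                     pip_limit = params$controller$pip_limit)
  seg <- run_segment(pig, s, pr$rm_hold_min * 20, t0 = t)
  pig <- seg$pig; t <- seg$t; recs[[length(recs) + 1L]] <- seg$records
  assessment <- NULL
  if (pig$alive) {
    last <- seg$records[nrow(seg$records), ]
    assessment <- list(bg = seg$bg, crs = unname(last["crs"]),
                       mp = unname(last["mp"]), co = unname(last["co"]),
                       breath = last)
  }
  list(pig = pig, records = do.call(rbind, recs), assessment = assessment,
       max_pip_commanded = max_pip, t = t)
}

#' Volume-history standardization
#'
#' 10 cycles at VT 10 mL/kg, PEEP 0, RR 10, I:E 1:1, followed by a 5-s
#' ventilator disconnection at airway pressure 0, which collapses every unit
#' with a positive closing pressure. Ensures each PEEP trial starts from the
#' same (fully derecruited) volume history.
#'
#' @param pig a living `pig`.
#' @param params parameter list.
#' @param t0 start time, s.
#' @return list with `pig`, `records`, `t`.
#' @export
run_volume_history <- function(pig, params = pig$params, t0 = 0) {
  s <- vent_settings("PCV_VG", fio2 = 1.0, peep = 0, rr = 10, vt_target = 10,
                     ie = "1:1", pip_limit = params$controller$pip_limit)
  seg <- run_segment(pig, s, 10, t0 = t0)
  pig <- seg$pig
  # disconnection: airway pressure 0 for 5 s
  pig$state[pig$state == 1L & pig$closing > 0] <- 0L
  list(pig = pig, records = seg$records, t = seg$t + 5)
}

#' Decremental PEEP trial
#'
#' Ascent PEEP 12 -> 24 in steps of 4 (5 cycles each), then descent
#' 24, 22, ..., 6 with 10 simulated minutes (200 breaths at RR 20) per step,
#' all at constant driving pressure 14 cmH2O, RR 20, FiO2 1.0. Measurements
#' (PaO2, PaCO2, Crs, CO, DO2, P/F) are recorded at the end of each descent
#' step. The descent stops early when P/F drops below 80 mmHg (termination
#' reason `"hypoxemia"`), on death (`"death"`), otherwise at the 6 cmH2O
#' floor (`"min_peep"`).
#'
#' @param pig a living `pig` after volume-history standardization.
#' @param params parameter list.
#' @param t0 start time, s.
#' @return object of class `peep_trial`: list with `steps` (data.frame:
#'   peep, pao2, paco2, crs, co, do2, pf), `terminated_reason`, `records`,
#'   `pig`, `t`.
#' @export
run_peep_trial <- function(pig, params = pig$params, t0 = 0) {
  pr <- params$protocol
  t <- t0
  recs <- list()
  steps <- list()
  reason <- "min_peep"
  for (peep in c(12, 16, 20, 24)) { # ascent, no measurements
    s <- vent_settings("PCV_FIXED_DP", fio2 = 1.0, peep = peep, rr = 20, dp = 14)
    seg <- run_segment(pig, s, pr$trial_dwell_ascent, t0 = t)
    pig <- seg$pig; t <- seg$t; recs[[length(recs) + 1L]] <- seg$records
    if (!pig$alive) {
      reason <- "death"
      break
    }
  }
  if (pig$alive) {
    for (peep in seq(24, 6, by = -2)) {
      s <- vent_settings("PCV_FIXED_DP", fio2 = 1.0, peep = peep, rr = 20, dp = 14)
      seg <- run_segment(pig, s, pr$trial_step_breaths, t0 = t)
      pig <- seg$pig; t <- seg$t; recs[[length(recs) + 1L]] <- seg$records
      if (!pig$alive) {
        reason <- "death"
        break
      }
      last <- seg$records[nrow(seg$records), ]
      steps[[length(steps) + 1L]] <- data.frame(
        peep = peep, pao2 = seg$bg$pao2, paco2 = seg$bg$paco2,
        crs = unname(last["crs"]), co = seg$bg$co, do2 = seg$bg$do2,
        pf = seg$bg$pf_ratio
      )
      if (seg$bg$pf_ratio < 80) {
        reason <- "hypoxemia"
        break
      }
    }
  }
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(peep = numeric(), pao2 = numeric(), paco2 = numeric(),
                 crs = numeric(), co = numeric(), do2 = numeric(), pf = numeric()),
    terminated_reason = reason,
    records = do.call(rbind, recs),
    pig = pig, t = t
  ), class = "peep_trial")
}

#' @export
print.peep_trial <- function(x, ...) {
  cat(sprintf("<peep trial> %d descent steps, terminated: %s\n",
              nrow(x$steps), x$terminated_reason))
  print(round(x$steps, 1), row.names = FALSE)
  invisible(x)
}

# One ventilation phase under the closed-loop controller.
run_phase_controlled <- function(pig, ctrl, hours, t0, bg0, last_rec = NULL) {
  t_end <- t0 + hours * 3600
  cap <- ceiling(hours * 3600 / (60 / ctrl$rr_max)) + 10L
  out <- matrix(NA_real_, cap, length(breath_cols),
                dimnames = list(NULL, breath_cols))
  t <- t0
  bg <- bg0
  rec <- last_rec
  i <- 0L
  while (t < t_end && pig$alive) {
    cs <- controller_step(ctrl, bg, rec, t)
    ctrl <- cs$ctrl
    sb <- step_breath(pig, cs$settings)
    pig <- sb$pig
    rec <- sb$record
    bg <- blood_gas(pig, rec)
    dt <- 60 / cs$settings$rr
    t <- t + dt
    pig <- update_death(pig, bg$pao2, dt)
    i <- i + 1L
    out[i, ] <- c(t, rec, bg$pao2, bg$paco2, bg$ph, bg$spo2, bg$co, bg$do2,
                  bg$pf_ratio)
  }
  list(pig = pig, ctrl = ctrl, records = out[seq_len(i), , drop = FALSE],
       bg = bg, rec = rec, t = t)
}

# Injurious phase: fixed high-VT / low-PEEP / RR 12 ventilation.
run_phase_injurious <- function(pig, hours, t0, params) {
  s <- vent_settings("PCV_VG", fio2 = 1.0, peep = 2, rr = 12, vt_target = 17,
                     pip_limit = params$controller$pip_limit)
  run_segment(pig, s, n_breaths = round(hours * 3600 / (60 / 12)), t0 = t0)
}

as_breaths_df <- function(stage_recs) {
  keep <- !vapply(stage_recs, is.null, logical(1))
  stage_recs <- stage_recs[keep]
  dfs <- lapply(names(stage_recs), function(nm) {
    m <- stage_recs[[nm]]
    if (is.null(m) || nrow(m) == 0) return(NULL)
    cbind(data.frame(stage = nm), as.data.frame(m))
  })
  do.call(rbind, dfs)
}

#' Run the full two-arm experiment on one pig
#'
#' Executes the complete protocol: 60-min baseline (RR servo on PaCO2),
#' lavage to the hypoxemia criterion, then three blocks of recruitment
#' maneuver + volume history + decremental PEEP trial bracketing two 3-h
#' ventilation phases. Phase 1 is either closed-loop protective ventilation
#' (`arm = "protective"`) or fixed injurious ventilation (VT 17 mL/kg,
#' PEEP 2, RR 12; `arm = "injurious"`); phase 2 is closed-loop protective
#' ventilation in both arms. On death the remaining stages are skipped and a
#' partial log is returned. Re-running with the same pig and seed reproduces
#' the log exactly.
#'
#' @param arm `"protective"` or `"injurious"`.
#' @param pig a healthy `pig` (e.g. from [make_cohort()]).
#' @param seed integer seed for the trajectory RNG.
#' @param params parameter list; the pig's own by default.
#' @return object of class `experiment_log`: list with `arm`, `pig_id`,
#'   `seed`, `bw`, `breaths` (data.frame with a `stage` column), `snapshots`
#'   (baseline / post_lavage blood gases, post-RM assessments), `trials`
#'   (list of up to three `peep_trial`s), `events` (deaths + controller
#'   events), `pig` (final state), `alive`, `lavage_cycles`.
#' @export
run_full_experiment <- function(arm = c("protective", "injurious"), pig, seed = 1,
                                params = pig$params) {
  arm <- match.arg(arm)
  set.seed(as.integer(seed))
  pr <- params$protocol
  stage_recs <- list()
  snapshots <- list()
  trials <- list()
  events <- list()
  deaths <- function(t, stage) data.frame(time_s = t, event = "death", stage = stage)

  bl <- run_baseline(pig, params, t0 = 0)
  pig <- bl$pig; t <- bl$t
  stage_recs$baseline <- bl$records
  snapshots$baseline <- bl$bg
  rr_base <- bl$rr
  lavage_cycles <- NA_integer_

  if (pig$alive) {
    lv <- run_lavage(pig, params, t0 = t, rr = rr_base)
    pig <- lv$pig; t <- lv$t
    stage_recs$lavage <- lv$records
    snapshots$post_lavage <- lv$bg
    lavage_cycles <- lv$n_cycles
  }

  ctrl <- NULL
  for (block in 1:3) {
    if (!pig$alive) {
      events[[length(events) + 1L]] <- deaths(t, paste0("block", block))
      break
    }
    rm <- run_recruitment_maneuver(pig, params, t0 = t)
    pig <- rm$pig; t <- rm$t
    stage_recs[[paste0("rm", block)]] <- rm$records
    snapshots[[paste0("post_rm", block)]] <- rm$assessment
    if (!pig$alive) {
      events[[length(events) + 1L]] <- deaths(t, paste0("rm", block))
      break
    }
    vh <- run_volume_history(pig, params, t0 = t)
    pig <- vh$pig; t <- vh$t
    stage_recs[[paste0("volume_history", block)]] <- vh$records
    tr <- run_peep_trial(pig, params, t0 = t)
    pig <- tr$pig; t <- tr$t
    stage_recs[[paste0("trial", block)]] <- tr$records
    trials[[block]] <- tr
    if (!pig$alive) {
      events[[length(events) + 1L]] <- deaths(t, paste0("trial", block))
      break
    }
    if (block == 3) break
    phase_nm <- paste0("phase", block)
    if (block == 1 && arm == "injurious") {
      ph <- run_phase_injurious(pig, pr$phase_hours, t0 = t, params = params)
      pig <- ph$pig; t <- ph$t
      stage_recs[[phase_nm]] <- ph$records
      last_bg <- ph$bg
    } else {
      if (is.null(ctrl)) {
        ctrl <- make_controller(params, rr_init = if (arm == "protective") rr_base else 20,
                                t0 = t)
        ctrl$last_ph_time <- t - ctrl$ph_interval_s # pH entered at handover
      }
      # seed the controller with the trial-end gas state
      bg0 <- blood_gas(pig, tail_record(stage_recs[[paste0("trial", block)]]))
      ph <- run_phase_controlled(pig, ctrl, pr$phase_hours, t0 = t, bg0 = bg0)
      pig <- ph$pig; ctrl <- ph$ctrl; t <- ph$t
      stage_recs[[phase_nm]] <- ph$records
      last_bg <- ph$bg
    }
    if (!pig$alive) {
      events[[length(events) + 1L]] <- deaths(t, phase_nm)
      break
    }
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(), event = character(), stage = character())
  structure(list(
    arm = arm, pig_id = pig$id, seed = seed, bw = pig$bw,
    breaths = as_breaths_df(stage_recs),
    snapshots = snapshots, trials = trials, events = ev,
    controller_events = if (!is.null(ctrl)) controller_events(ctrl) else NULL,
    pig = pig, alive = pig$alive, lavage_cycles = lavage_cycles
  ), class = "experiment_log")
}

tail_record <- function(records) {
  records[nrow(records), ]
}

#' @export
print.experiment_log <- function(x, ...) {
  cat(sprintf(
    "<experiment log> %s arm, %s (BW %.1f kg), %d breaths, %d trials, %s\n",
    x$arm, x$pig_id, x$bw, nrow(x$breaths), length(x$trials),
    if (x$alive) "survived" else "died"
  ))
  invisible(x)
}
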