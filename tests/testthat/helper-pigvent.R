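# Shared fixtures: all built in code at test time.

# A three-unit pig with hand-chosen thresholds, used for hand-enumerated
# transition examples. Injury probabilities are zero unless asked for.
tiny_pig <- function(opening = c(10, 20, 30), closing = c(5, 15, 25),
                     state = rep(0L, length(opening)),
                     injury_overrides = list()) {
  params <- pv_params(overrides = list(
    lung = list(n_units = length(opening)),
    injury = modifyList(list(
      cyclic_consolidation_prob = 0, overdistension_consolidation_prob = 0,
      cyclic_pressure_creep = 0
    ), injury_overrides)
  ))
  pig <- make_pig(50, params, id = "tiny")
  pig$opening <- opening
  pig$closing <- closing
  pig$state <- as.integer(state)
  pig
}

# Reduced protocol durations for logic tests (the full-length protocol is
# exercised by the acceptance suite).
short_params <- function(overrides = list()) {
  pv_params(overrides = modifyList(list(
    protocol = list(baseline_min = 10, phase_hours = 0.25,
                    trial_step_breaths = 20, rm_hold_min = 2,
                    lavage_window_min = 3, lavage_settle_min = 1)
  ), overrides))
}

# Independent brute-force reference for one quasi-static breath on a handful
# of units: plain per-unit loop over the stated rules (no injury draws).
enumerate_breath <- function(opening, closing, state, pip, peep) {
  n <- length(opening)
  cyclic <- 0L
  for (i in seq_len(n)) {
    if (state[i] == 2L) next
    opened_now <- FALSE
    if (state[i] == 0L && opening[i] <= pip) {
      state[i] <- 1L
      opened_now <- TRUE
    }
    if (state[i] == 1L && closing[i] > peep) {
      state[i] <- 0L
      if (opened_now) cyclic <- cyclic + 1L
    }
  }
  list(state = state, cyclic = cyclic)
}

# Independent grid-search oracle for the venous-admixture fixed point:
# residual of the content-mixing balance, minimized over a fine PaO2 grid.
# Shares the documented physiological floor (PaO2 >= 3 mmHg: mixing targets
# below the content at 3 mmHg are not survivable states).
grid_shunt_pao2 <- function(shunt, pao2_alv, hb, co, vo2, step = 0.01) {
  content <- function(p) 1.34 * hb * (1 / (23400 / (p^3 + 150 * p) + 1)) + 0.003 * p
  cc <- content(pao2_alv)
  target <- max(cc - shunt / (1 - shunt) * vo2 / (10 * co), content(3))
  grid <- seq(3, pao2_alv, by = step)
  grid[which.min(abs(content(grid) - target))]
}
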