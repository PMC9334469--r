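# Protocol-engine logic on shortened schedules (durations reduced; the
# full-length protocol is exercised in the acceptance suite).

test_that("baseline servo brings PaCO2 into the 37-45 mmHg band", {
  params <- pv_params()
  pig <- make_cohort(1, seed = 41, params = params)[[1]]
  set.seed(41)
  bl <- run_baseline(pig, params, minutes = 30)
  expect_gte(bl$bg$paco2, 37)
  expect_lte(bl$bg$paco2, 45)
  expect_true(all(bl$records[, "peep"] == 7))
  expect_equal(unique(bl$records[, "fio2"]), 1.0)
})

test_that("baseline on a pig without CO2 production pins PaCO2 at the floor and RR at minimum", {
  params <- short_params()
  pig <- make_cohort(1, seed = 42, params = params)[[1]]
  pig$vco2 <- 0
  set.seed(42)
  expect_warning(bl <- run_baseline(pig, params, minutes = 30), "outside 37-45")
  expect_equal(bl$bg$paco2, 10) # lower cap of the CO2 relation
  expect_equal(bl$rr, params$controller$rr_min)
})

test_that("lavage loop terminates at the qualifying hypoxemia criterion", {
  params <- pv_params()
  pig <- make_cohort(1, seed = 43, params = params)[[1]]
  set.seed(43)
  bl <- run_baseline(pig, params, minutes = 10)
  baseline_pao2 <- bl$bg$pao2
  lv <- run_lavage(bl$pig, params, t0 = bl$t, rr = bl$rr)
  expect_lt(lv$bg$pao2, 100)
  expect_lt(lv$bg$pao2, baseline_pao2)
  expect_gte(lv$n_cycles, 1)
  expect_lte(lv$n_cycles, params$protocol$lavage_max_cycles)
})

test_that("lavage with disabled injury never qualifies and raises a calibration error", {
  params <- pv_params(overrides = list(
    injury = list(lavage_shift_mean = 0, lavage_shift_sd = 0, lavage_closing_sd = 0,
                  lavage_compliance_loss = 0, lavage_deadspace_gain = 0),
    protocol = list(lavage_max_cycles = 4, lavage_window_min = 2,
                    lavage_settle_min = 1)
  ))
  pig <- make_cohort(1, seed = 44, params = params)[[1]]
  set.seed(44)
  expect_error(run_lavage(pig, params), "not reached")
})

test_that("recruitment maneuver commands a maximum PIP of exactly 50 cmH2O", {
  params <- short_params()
  pig <- make_cohort(1, seed = 45, params = params)[[1]]
  set.seed(45)
  for (i in 1:3) pig <- apply_lavage_cycle(pig)
  rm <- run_recruitment_maneuver(pig, params)
  expect_equal(rm$max_pip_commanded, 50)
  expect_equal(max(rm$records[, "pip"]), 50)
  # ladder rungs present: PEEP 12 -> 16 -> 20 -> 24, 5 breaths each, dP 20
  ladder <- rm$records[rm$records[, "dp"] == 20, "peep"]
  expect_equal(as.vector(table(ladder)[c("12", "16", "20", "24")]), rep(5L, 4))
})

test_that("recruitment restores oxygenation in a lavage-only pig", {
  params <- short_params()
  pig <- make_cohort(1, seed = 46, params = params)[[1]]
  set.seed(46)
  bl <- run_baseline(pig, params)
  lv <- run_lavage(bl$pig, params, t0 = bl$t, rr = bl$rr)
  rm <- run_recruitment_maneuver(lv$pig, params, t0 = lv$t)
  expect_gt(rm$assessment$bg$pao2, lv$bg$pao2 + 100)
})

test_that("a fully consolidated lung is not recruitable", {
  pig <- tiny_pig(state = rep(2L, 3))
  before <- aeration_fraction(pig)
  rm <- run_recruitment_maneuver(pig, short_params())
  expect_equal(aeration_fraction(rm$pig), before)
})

test_that("volume history standardization ends fully derecruited", {
  params <- short_params()
  pig <- make_cohort(1, seed = 47, params = params)[[1]]
  set.seed(47)
  for (i in 1:3) pig <- apply_lavage_cycle(pig)
  pig$closing <- pmax(pig$closing, 0.1) # all units collapsible at pressure 0
  vh <- run_volume_history(pig, params)
  expect_equal(nrow(vh$records), 10)
  expect_true(all(vh$records[, "peep"] == 0))
  expect_true(all(vh$records[, "rr"] == 10))
  # with every closing pressure positive, disconnection closes everything
  expect_equal(aeration_fraction(vh$pig), 0)
  # repeatable from identical state
  vh2 <- run_volume_history(pig, params)
  expect_identical(vh$pig$state, vh2$pig$state)
})

test_that("decremental trial walks the protocol grid at constant driving pressure", {
  params <- short_params()
  pig <- make_cohort(1, seed = 48, params = params)[[1]]
  set.seed(48)
  for (i in 1:3) pig <- apply_lavage_cycle(pig)
  rm <- run_recruitment_maneuver(pig, params)
  vh <- run_volume_history(rm$pig, params, t0 = rm$t)
  tr <- run_peep_trial(vh$pig, params, t0 = vh$t)
  expect_s3_class(tr, "peep_trial")
  expect_true(all(tr$steps$peep %in% seq(24, 6, by = -2)))
  expect_lte(nrow(tr$steps), 10)
  expect_true(all(diff(tr$steps$peep) == -2))
  descent <- tr$records[tr$records[, "dp"] == 14, ]
  expect_true(all(descent[, "pip"] - descent[, "peep"] == 14))
  expect_true(tr$terminated_reason %in% c("min_peep", "hypoxemia", "death"))
  if (tr$terminated_reason == "hypoxemia") {
    expect_lt(tr$steps$pf[nrow(tr$steps)], 80)
  } else if (tr$terminated_reason == "min_peep") {
    expect_equal(min(tr$steps$peep), 6)
  }
  # cardiac output recovers monotonically during the descent
  expect_true(all(diff(tr$steps$co) >= 0))
})

test_that("a hypoxemia-engineered pig stops the trial early with the right reason", {
  # most units consolidated: P/F collapses within a few descent steps
  pig <- tiny_pig(opening = c(5, 30, 35, 40, 45), closing = c(2, 28, 33, 38, 43),
                  state = c(1L, 2L, 2L, 2L, 2L))
  pig$vd_alv_frac <- 0.2
  tr <- run_peep_trial(pig, short_params())
  expect_equal(tr$terminated_reason, "hypoxemia")
  expect_gt(min(tr$steps$peep), 6)
  expect_lt(tr$steps$pf[nrow(tr$steps)], 80)
})

test_that("dead pigs halt the protocol rather than continuing silently", {
  pig <- make_cohort(1, seed = 49)[[1]]
  pig$alive <- FALSE
  expect_error(step_breath(pig, vent_settings("PCV_VG", peep = 5, vt_target = 6,
                                              rr = 20)),
               class = "pigvent_halt")
})
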