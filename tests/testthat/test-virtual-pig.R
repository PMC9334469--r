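test_that("cohort generation reproduces body-weight distribution and is seeded", {
  cohort <- make_cohort(6, bw_mean = 46, bw_sd = 3, seed = 1)
  expect_length(cohort, 6)
  bws <- vapply(cohort, function(p) p$bw, numeric(1))
  expect_lt(abs(mean(bws) - 46), 4)

  single <- make_cohort(1, bw_mean = 46, bw_sd = 0, seed = 5)
  expect_equal(single[[1]]$bw, 46)

  a <- make_cohort(3, seed = 7)
  b <- make_cohort(3, seed = 7)
  expect_identical(lapply(a, `[`, c("bw", "opening", "closing", "state")),
                   lapply(b, `[`, c("bw", "opening", "closing", "state")))

  expect_error(make_cohort(0), "positive")
  expect_error(make_cohort(3, bw_mean = -1), "positive")
})

test_that("healthy pigs have baseline compliance in the calibration band", {
  cohort <- make_cohort(4, seed = 11)
  for (pig in cohort) {
    sb <- step_breath(pig, vent_settings("PCV_FIXED_DP", peep = 7, dp = 14, rr = 20))
    expect_gt(sb$record[["crs"]], 22)
    expect_lt(sb$record[["crs"]], 36)
  }
})

test_that("unit invariants hold at creation", {
  pig <- make_cohort(1, seed = 3)[[1]]
  expect_true(all(pig$closing < pig$opening))
  expect_true(all(pig$opening >= 0.5))
  expect_true(pig$compliance_scale > pig$stiff_compliance)
})

test_that("aeration fraction matches hand enumeration on a three-unit lung", {
  pig <- tiny_pig() # opening 10/20/30, closing 5/15/25, all closed
  expect_equal(aeration_fraction(pig), 0)
  pig$state <- rep(1L, 3)
  expect_equal(aeration_fraction(pig), 1)
  pig$state <- rep(2L, 3)
  expect_equal(aeration_fraction(pig), 0)

  # PIP 22 / PEEP 6: unit 1 opens and stays (closing 5 < 6); unit 2 opens then
  # re-closes (cyclic); unit 3 never opens -> aeration 1/3, one cyclic event
  pig <- tiny_pig()
  sb <- step_breath(pig, vent_settings("PCV_FIXED_DP", peep = 6, dp = 16, rr = 20,
                                       fio2 = 1))
  expect_equal(aeration_fraction(sb$pig), 1 / 3)
  expect_equal(sb$record[["frac_cyclic"]] * 3, 1)
  expect_equal(sb$pig$cumulative_cyclic_events, 1)
})

test_that("step_breath matches brute-force enumeration on small lungs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    opening <- sort(runif(n, 1, 40))
    closing <- opening - runif(n, 0.5, 10)
    state <- sample(0:2, n, replace = TRUE)
    peep <- runif(1, 0, 15)
    dp <- runif(1, 5, 30)
    pig <- tiny_pig(opening, closing, state)
    sb <- step_breath(pig, vent_settings("PCV_FIXED_DP", peep = peep, dp = dp, rr = 20))
    ref <- enumerate_breath(opening, closing, state, pip = peep + dp, peep = peep)
    expect_identical(sb$pig$state, ref$state)
    expect_equal(sb$record[["frac_cyclic"]] * n, ref$cyclic)
  }
})

test_that("a breath below all opening pressures moves no units and delivers stiff volume", {
  pig <- tiny_pig(opening = c(20, 25, 30), closing = c(10, 12, 15))
  sb <- step_breath(pig, vent_settings("PCV_FIXED_DP", peep = 0, dp = 5, rr = 20))
  expect_identical(sb$pig$state, pig$state)
  expect_equal(sb$record[["vt_ml"]], pig$stiff_compliance * 5, tolerance = 1e-6)
})

test_that("with injury probabilities zero, consolidation never changes", {
  pig <- make_cohort(1, seed = 9, params = pv_params(overrides = list(
    injury = list(cyclic_consolidation_prob = 0,
                  overdistension_consolidation_prob = 0)
  )))[[1]]
  before <- consolidated_fraction(pig)
  set.seed(1)
  for (i in 1:50) {
    peep <- sample(c(0, 2, 6, 12), 1)
    pig <- step_breath(pig, vent_settings("PCV_FIXED_DP", peep = peep, dp = 25,
                                          rr = 20))$pig
  }
  expect_equal(consolidated_fraction(pig), before)
})

test_that("consolidated fraction is non-decreasing over any ventilation history", {
  pig <- make_cohort(1, seed = 21)[[1]]
  set.seed(2)
  for (i in 1:5) pig <- apply_lavage_cycle(pig)
  prev <- consolidated_fraction(pig)
  for (i in 1:300) {
    pig <- step_breath(pig, vent_settings("PCV_VG", peep = 2, vt_target = 17,
                                          rr = 12))$pig
    cf <- consolidated_fraction(pig)
    expect_gte(cf, prev)
    prev <- cf
  }
  expect_gt(prev, 0) # injurious ventilation does consolidate
})

test_that("quasi-static aeration is monotone in PIP and PEEP", {
  base <- make_cohort(1, seed = 33, params = pv_params(overrides = list(
    injury = list(cyclic_consolidation_prob = 0,
                  overdistension_consolidation_prob = 0,
                  cyclic_pressure_creep = 0)
  )))[[1]]
  set.seed(1)
  for (i in 1:3) base <- apply_lavage_cycle(base)
  base$state[] <- 0L

  aer_at <- function(pig, peep, pip) {
    sb <- step_breath(pig, vent_settings("PCV_FIXED_DP", peep = peep,
                                         dp = pip - peep, rr = 20))
    sb$record[["frac_open_insp"]]
  }
  pips <- seq(10, 45, by = 5)
  aer_pip <- vapply(pips, function(p) aer_at(base, 5, p), numeric(1))
  expect_true(all(diff(aer_pip) >= 0))

  peeps <- seq(0, 20, by = 4)
  aer_peep <- vapply(peeps, function(pe) {
    pig <- base
    for (k in 1:5) {
      sb <- step_breath(pig, vent_settings("PCV_FIXED_DP", peep = pe, dp = 28 - pe,
                                           rr = 20))
      pig <- sb$pig
    }
    sb$record[["frac_open_exp"]]
  }, numeric(1))
  expect_true(all(diff(aer_peep) >= 0))
})

test_that("without injury the hysteresis loop closes after a pressure sweep", {
  pig <- tiny_pig(opening = c(8, 16, 24, 32), closing = c(4, 9, 14, 19))
  start <- pig$state
  for (pip in c(10, 20, 30, 40, 30, 20, 10)) {
    pig <- step_breath(pig, vent_settings("PCV_FIXED_DP", peep = 0, dp = pip,
                                          rr = 20))$pig
  }
  # at PEEP 0 all closing pressures are positive: every unit re-closed
  expect_identical(pig$state, start)
})

test_that("lavage raises thresholds monotonically and respects degenerate parameters", {
  pig <- make_cohort(1, seed = 13)[[1]]
  null_injury <- modifyList(pig$params$injury, list(
    lavage_shift_mean = 0, lavage_shift_sd = 0, lavage_closing_sd = 0,
    lavage_compliance_loss = 0, lavage_deadspace_gain = 0
  ))
  same <- apply_lavage_cycle(pig, null_injury)
  expect_equal(same$opening, pig$opening)
  expect_equal(same$closing, pig$closing)
  expect_equal(same$compliance_scale, pig$compliance_scale)

  set.seed(4)
  after <- apply_lavage_cycle(pig)
  expect_gt(mean(after$opening), mean(pig$opening))
  expect_gte(min(after$closing - pig$closing), 0)
  expect_true(all(after$closing < after$opening))
  expect_lt(after$compliance_scale, pig$compliance_scale)

  # monotone injury: at fixed pressures the recruitable set only shrinks
  opens_before <- pig$opening <= 25
  opens_after <- after$opening <= 25
  expect_true(all(opens_after <= opens_before))
})

test_that("cardiac output follows the PEEP response and its floor", {
  pig <- make_cohort(1, seed = 2)[[1]]
  expect_equal(cardiac_output(pig, 5), pig$co_base)
  expect_equal(cardiac_output(pig, 0), pig$co_base)
  pig$co_base <- 4
  pig$co_peep_slope <- 0.015
  expect_equal(cardiac_output(pig, 15), 4 * 0.85)
  # decremental sweep: CO non-decreasing as PEEP falls
  co <- vapply(seq(24, 6, by = -2), function(p) cardiac_output(pig, p), numeric(1))
  expect_true(all(diff(co) >= 0))
  # floor at 30% of baseline
  expect_equal(cardiac_output(pig, 100), 4 * 0.3)
})

test_that("a full state trajectory is reproducible under a fixed seed", {
  run <- function() {
    pig <- make_cohort(1, seed = 77)[[1]]
    set.seed(123)
    for (i in 1:2) pig <- apply_lavage_cycle(pig)
    out <- numeric(0)
    for (i in 1:100) {
      sb <- step_breath(pig, vent_settings("PCV_VG", peep = 4, vt_target = 12, rr = 15))
      pig <- sb$pig
      out <- c(out, sb$record)
    }
    list(pig = pig, out = out)
  }
  a <- run(); b <- run()
  expect_identical(a$out, b$out)
  expect_identical(a$pig$state, b$pig$state)
})
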