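#' Create a virtual pig
#'
#' A pig is a population of threshold-opening/closing alveolar units plus
#' whole-animal gas-exchange and hemodynamic parameters. Each unit opens
#' during inspiration when PIP reaches its opening pressure and collapses at
#' end-expiration when PEEP falls below its closing pressure; closing lies
#' below opening, giving the lung pressure-volume hysteresis. Units destroyed
#' by ventilator-induced injury become consolidated and never re-aerate.
#'
#' Healthy opening pressures are Normal(`opening_mean`, `opening_sd`) clipped
#' at `opening_min`; closing = opening − Uniform(`gap_min`, `gap_max`).
#' Perfusion is uniform across units.
#'
#' @param bw body weight, kg.
#' @param params parameter list from [pv_params()].
#' @param id optional pig identifier.
#' @return object of class `pig`.
#' @export
make_pig <- function(bw, params = pv_params(), id = "pig") {
  stopifnot(bw > 0)
  lung <- params$lung
  n <- lung$n_units
  opening <- pmax(lung$opening_min, rnorm(n, lung$opening_mean, lung$opening_sd))
  closing <- opening - runif(n, lung$gap_min, lung$gap_max)
  pig <- list(
    id = id,
    bw = bw,
    opening = opening,
    closing = closing,
    state = rep(1L, n), # 0 closed, 1 open, 2 consolidated; start ventilated/open
    compliance_scale = lung$compliance_per_kg * bw,
    stiff_compliance = lung$stiff_compliance,
    hb = params$gas$hb,
    hco3 = params$gas$hco3,
    vo2 = params$gas$vo2_per_kg * bw,
    vco2 = params$gas$rq * params$gas$vo2_per_kg * bw,
    vd_aw = params$gas$vd_aw_per_kg * bw,
    co_base = params$hemo$co_base,
    co_peep_slope = params$hemo$co_peep_slope,
    alive = TRUE,
    crs_last = lung$stiff_compliance + lung$compliance_per_kg * bw,
    dp_last = 10,
    vd_alv_frac = 0, # surfactant-dysfunction alveolar dead space, grows with lavage
    cumulative_cyclic_events = 0,
    hypox_s = 0,
    params = params
  )
  class(pig) <- "pig"
  pig
}

#' Generate a cohort of virtual pigs
#'
#' Body weights are drawn Normal(`bw_mean`, `bw_sd`); the unit populations of
#' the pigs are independent. A fixed seed reproduces the cohort exactly.
#'
#' @param n number of pigs (>= 1).
#' @param bw_mean,bw_sd body-weight distribution, kg.
#' @param seed integer RNG seed.
#' @param params parameter list from [pv_params()].
#' @return list of `pig` objects.
#' @export
#' @examples
#' cohort <- make_cohort(3, seed = 1)
#' sapply(cohort, function(p) p$bw)
make_cohort <- function(n, bw_mean = 46, bw_sd = 3, seed = 1, params = pv_params()) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive count")
  if (bw_mean <= 0) stop("bw_mean must be positive")
  if (bw_sd < 0) stop("bw_sd must be non-negative")
  set.seed(as.integer(seed))
  bws <- rnorm(n, bw_mean, bw_sd)
  bws <- pmax(bws, 1) # degenerate guard
  lapply(seq_len(n), function(i) make_pig(bws[i], params, id = sprintf("pig%02d", i)))
}

#' Fraction of alveolar units open at end-expiration
#' @param pig a `pig` object.
#' @return fraction in [0, 1].
#' @export
aeration_fraction <- function(pig) {
  stopifnot(length(pig$state) >= 1)
  mean(pig$state == 1L)
}

#' Fraction of consolidated (permanently destroyed) units
#' @param pig a `pig` object.
#' @return fraction in [0, 1].
#' @export
consolidated_fraction <- function(pig) {
  mean(pig$state == 2L)
}

#' Apply one saline-lavage cycle
#'
#' Each cycle depletes surfactant in a random subset of non-consolidated
#' units (probability `lavage_hit_prob` per unit). A hit unit's opening
#' pressure rises by a truncated-normal draw (`lavage_shift_mean`,
#' `lavage_shift_sd`, floored at 0) and its closing pressure by a smaller
#' independent draw (mean `lavage_closing_frac * lavage_shift_mean`, sd
#' `lavage_closing_sd`), widening the hysteresis gap as surfactant is washed
#' out; repeated cycles leave a bimodal closing-pressure distribution of
#' spared versus repeatedly hit units. The aerated compliance scale shrinks
#' by `lavage_compliance_loss` and the surfactant-dysfunction alveolar
#' dead-space fraction grows by `lavage_deadspace_gain`. Injury is monotone:
#' at any fixed airway pressures, post-lavage aeration cannot exceed
#' pre-lavage aeration.
#'
#' @param pig a `pig` object.
#' @param injury injury parameter list; defaults to the pig's own.
#' @return the modified pig.
#' @export
apply_lavage_cycle <- function(pig, injury = pig$params$injury) {
  stopifnot(pig$alive)
  idx <- which(pig$state != 2L)
  # each cycle depletes surfactant in a random subset of units: repeatedly hit
  # units accumulate high thresholds, spared units keep low closing pressures
  idx <- idx[runif(length(idx)) < injury$lavage_hit_prob]
  m <- length(idx)
  shift <- pmax(0, rnorm(m, injury$lavage_shift_mean, injury$lavage_shift_sd))
  cl_shift <- pmax(0, rnorm(m, injury$lavage_closing_frac * injury$lavage_shift_mean,
                            injury$lavage_closing_sd))
  pig$opening[idx] <- pig$opening[idx] + shift
  pig$closing[idx] <- pmin(pig$closing[idx] + cl_shift, pig$opening[idx] - 0.5)
  # closing < opening preserved by the clamp
  pig$compliance_scale <- pig$compliance_scale * (1 - injury$lavage_compliance_loss)
  pig$vd_alv_frac <- pig$vd_alv_frac + injury$lavage_deadspace_gain
  pig
}

#' PEEP-dependent cardiac output
#'
#' Crude venous-return model: CO falls linearly with PEEP above 5 cmH2O and
#' is floored at 30% of baseline. Strictly non-increasing in PEEP, so cardiac
#' output recovers monotonically during a decremental PEEP trial.
#'
#' @param pig a `pig` object.
#' @param peep cmH2O, >= 0.
#' @return L/min.
#' @export
#' @examples
#' p <- make_cohort(1, seed = 1)[[1]]
#' cardiac_output(p, 5)   # co_base exactly
#' cardiac_output(p, 15)  # reduced
cardiac_output <- function(pig, peep) {
  stopifnot(peep >= 0)
  pig$co_base * max(0.3, 1 - pig$co_peep_slope * max(0, peep - 5))
}

#' @export
print.pig <- function(x, ...) {
  cat(sprintf(
    "<pig %s> BW %.1f kg, %d units (%.0f%% open, %.0f%% consolidated), Crs(last) %.1f mL/cmH2O, %s\n",
    x$id, x$bw, length(x$state), 100 * aeration_fraction(x),
    100 * consolidated_fraction(x), x$crs_last,
    if (x$alive) "alive" else "dead"
  ))
  invisible(x)
}
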