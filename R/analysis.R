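#' Best PEEP from a decremental trial
#'
#' Argmax of the chosen criterion over the measured descent steps; ties are
#' broken toward the lower PEEP (less exposure for equal benefit).
#'
#' @param trial a `peep_trial` (or any list with a `steps` data.frame
#'   containing `peep` plus the criterion column).
#' @param criterion `"crs"` (compliance), `"pao2"` (oxygenation) or `"do2"`
#'   (oxygen delivery).
#' @return object of class `best_peep`: list with `criterion`, `best_peep`,
#'   `best_value`, `curve` (data.frame peep/value).
#' @export
#' @examples
#' tr <- list(steps = data.frame(peep = c(12, 10, 8), crs = c(20, 25, 22)))
#' best_peep(tr, "crs")$best_peep # 10
best_peep <- function(trial, criterion = c("crs", "pao2", "do2")) {
  criterion <- match.arg(criterion)
  steps <- trial$steps
  if (is.null(steps) || nrow(steps) == 0) stop("best_peep: trial has no measured steps")
  value <- steps[[criterion]]
  cand <- which(value == max(value))
  bp <- min(steps$peep[cand])
  structure(list(criterion = criterion, best_peep = bp, best_value = max(value),
                 curve = data.frame(peep = steps$peep, value = value)),
            class = "best_peep")
}

#' Group-level best PEEP from the mean response curve
#'
#' Averages the per-animal curves at each PEEP level (using only PEEPs
#' measured in every animal, since early hypoxemic termination truncates
#' individual descents), then takes the argmax with ties toward lower PEEP.
#'
#' @param trials list of `peep_trial`s, one per animal.
#' @param criterion as in [best_peep()].
#' @return `best_peep` object computed on the mean curve; also carries
#'   `n_animals` and `individual` (per-animal best PEEPs).
#' @export
group_best_peep <- function(trials, criterion = c("crs", "pao2", "do2")) {
  criterion <- match.arg(criterion)
  trials <- Filter(function(tr) nrow(tr$steps) > 0, trials)
  if (!length(trials)) stop("group_best_peep: no trials with measured steps")
  common <- Reduce(intersect, lapply(trials, function(tr) tr$steps$peep))
  if (!length(common)) stop("group_best_peep: no PEEP level measured in all animals")
  curves <- vapply(trials, function(tr) {
    s <- tr$steps
    s[[criterion]][match(common, s$peep)]
  }, numeric(length(common)))
  curves <- matrix(curves, nrow = length(common))
  mean_curve <- rowMeans(curves)
  cand <- which(mean_curve == max(mean_curve))
  bp <- min(common[cand])
  structure(list(
    criterion = criterion, best_peep = bp, best_value = max(mean_curve),
    curve = data.frame(peep = common, value = mean_curve),
    n_animals = length(trials),
    individual = vapply(trials, function(tr) best_peep(tr, criterion)$best_peep,
                        numeric(1))
  ), class = "best_peep")
}

#' @export
print.best_peep <- function(x, ...) {
  cat(sprintf("<best PEEP by %s> %g cmH2O (value %.1f)\n",
              x$criterion, x$best_peep, x$best_value))
  invisible(x)
}

#' Relative deviation from the post-lavage value
#'
#' 100 * (post_RM - post_lavage) / post_lavage, the percent recovery (or
#' further loss) of a variable after a recruitment maneuver relative to its
#' value after the initial lavage injury.
#'
#' @param post_rm_value value after the recruitment maneuver.
#' @param post_lavage_value value after initial lavage (> 0).
#' @return percent. Vectorized.
#' @export
#' @examples
#' deviation_from_lavage(29.8, 11.7) # +154.7 %
deviation_from_lavage <- function(post_rm_value, post_lavage_value) {
  if (any(post_lavage_value <= 0)) stop("deviation_from_lavage: baseline must be positive")
  100 * (post_rm_value - post_lavage_value) / post_lavage_value
}

#' Relative treatment effects (descriptive)
#'
#' For each subgroup, the probability-scale rank measure
#' RTE = (mean mid-rank of the subgroup - 0.5) / N, i.e. the proportion of
#' the pooled data smaller than (or, for ties, half-equal to) a random
#' observation from the subgroup. The size-weighted mean over subgroups is
#' exactly 0.5.
#'
#' @param values numeric vector of all observations (pooled).
#' @param subgroup factor/character vector of subgroup labels, same length.
#' @return data.frame with columns `subgroup`, `n`, `rte`.
#' @export
#' @examples
#' relative_treatment_effect(c(1, 2, 3, 4), c("A", "A", "B", "B"))
relative_treatment_effect <- function(values, subgroup) {
  stopifnot(length(values) == length(subgroup), length(values) >= 2)
  subgroup <- as.character(subgroup)
  if (anyNA(values) || anyNA(subgroup)) stop("relative_treatment_effect: NA input")
  tab <- table(subgroup)
  if (any(tab == 0)) stop("relative_treatment_effect: empty subgroup")
  r <- rank(values) # mid-ranks
  n <- length(values)
  res <- aggregate(r, by = list(subgroup = subgroup), FUN = mean)
  data.frame(subgroup = res$subgroup,
             n = as.integer(tab[res$subgroup]),
             rte = (res$x - 0.5) / n)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' U statistic from mid-ranks. For combined sample sizes n_a + n_b <= 12 the
#' two-sided p-value is computed by full enumeration of all group-label
#' assignments (exact even under ties); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with `u` (U of sample `a`), `p_value`, `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mid <- na * nb / 2
  if (n <= 12) {
    idx <- combn(n, na)
    us <- apply(idx, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    p <- mean(abs(us - mid) >= abs(u_a - mid) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u_a - mid) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(-z))
    method <- "normal approximation, tie-corrected"
  }
  list(u = u_a, p_value = p, method = method)
}

#' Cohort summary tables
#'
#' Two descriptive tables over a collection of experiment logs, mirroring a
#' per-instant layout (baseline, after lavage, after each RM) and a per-hour
#' phase layout. Values are group means +/- SD of PIP, PEEP, driving
#' pressure, VT (mL/kg), RR, M_P, Crs, PaO2, PaCO2 and CO.
#'
#' @param logs list of `experiment_log`s (may mix arms; arm labels are taken
#'   from the logs).
#' @return list of data.frames `instants` and `phases`, long format:
#'   arm, instant/phase label, variable, mean, sd, n.
#' @export
cohort_summary <- function(logs) {
  if (!length(logs)) stop("cohort_summary: no logs")
  if (!all(vapply(logs, function(l) inherits(l, "experiment_log"), logical(1)))) {
    stop("cohort_summary: inputs must be experiment logs with arm labels")
  }
  inst_rows <- list()
  for (log in logs) {
    grab <- function(instant, bg, breath) {
      if (is.null(bg)) return(NULL)
      vals <- c(
        PIP = unname(breath["pip"]), PEEP = unname(breath["peep"]),
        dP = unname(breath["dp"]), VT_mlkg = unname(breath["vt_ml"]) / log$bw,
        RR = unname(breath["rr"]), MP = unname(breath["mp"]),
        Crs = unname(breath["crs"]), PaO2 = bg$pao2, PaCO2 = bg$paco2,
        CO = bg$co
      )
      data.frame(arm = log$arm, pig_id = log$pig_id, instant = instant,
                 variable = names(vals), value = unname(vals))
    }
    br <- log$breaths
    last_of <- function(stage) {
      rows <- br[br$stage == stage, ]
      if (nrow(rows) == 0) return(NULL)
      v <- as.numeric(rows[nrow(rows), -1])
      names(v) <- names(rows)[-1]
      v
    }
    inst_rows[[length(inst_rows) + 1L]] <- grab("baseline", log$snapshots$baseline, last_of("baseline"))
    inst_rows[[length(inst_rows) + 1L]] <- grab("after_lavage", log$snapshots$post_lavage, last_of("lavage"))
    for (k in 1:3) {
      a <- log$snapshots[[paste0("post_rm", k)]]
      if (!is.null(a)) {
        inst_rows[[length(inst_rows) + 1L]] <- grab(paste0("post_rm", k), a$bg, a$breath)
      }
    }
  }
  inst <- do.call(rbind, inst_rows)

  phase_rows <- list()
  for (log in logs) {
    br <- log$breaths
    for (ph in c("phase1", "phase2")) {
      rows <- br[br$stage == ph, ]
      if (nrow(rows) == 0) next
      t0 <- min(rows$time_s)
      hr <- ceiling(pmax(rows$time_s - t0, 1e-9) / 3600)
      for (h in sort(unique(hr))) {
        sub <- rows[hr == h, ]
        vals <- c(PIP = mean(sub$pip), PEEP = mean(sub$peep), dP = mean(sub$dp),
                  VT_mlkg = mean(sub$vt_ml) / log$bw, RR = mean(sub$rr),
                  MP = mean(sub$mp), Crs = mean(sub$crs), PaO2 = mean(sub$pao2),
                  PaCO2 = mean(sub$paco2), CO = mean(sub$co))
        phase_rows[[length(phase_rows) + 1L]] <- data.frame(
          arm = log$arm, pig_id = log$pig_id, phase = ph, hour = h,
          variable = names(vals), value = unname(vals))
      }
    }
  }
  phases <- do.call(rbind, phase_rows)

  summarize <- function(df, by) {
    if (is.null(df)) return(NULL)
    agg <- aggregate(df$value, by = df[by], FUN = function(x) c(mean(x), sd(x), length(x)))
    out <- cbind(agg[by], mean = agg$x[, 1],
                 sd = ifelse(is.na(agg$x[, 2]), 0, agg$x[, 2]),
                 n = as.integer(agg$x[, 3]))
    out[do.call(order, out[by]), ]
  }
  list(instants = summarize(inst, c("arm", "instant", "variable")),
       phases = summarize(phases, c("arm", "phase", "hour", "variable")))
}
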