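#' Write the per-breath log of an experiment as CSV
#'
#' Columns: stage, time_s, PIP, PEEP, dP, VT_mL, RR, FiO2, Crs, MP, aeration,
#' consolidated_fraction, PaO2, PaCO2, pH, SpO2, CO.
#'
#' @param log an `experiment_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_breaths_csv <- function(log, path) {
  br <- log$breaths
  out <- data.frame(
    stage = br$stage, time_s = br$time_s, PIP = br$pip, PEEP = br$peep,
    dP = br$dp, VT_mL = br$vt_ml, RR = br$rr, FiO2 = br$fio2, Crs = br$crs,
    MP = br$mp, aeration = br$frac_open_exp,
    consolidated_fraction = br$frac_consolidated,
    PaO2 = br$pao2, PaCO2 = br$paco2, pH = br$ph, SpO2 = br$spo2, CO = br$co
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-breath CSV written by [write_breaths_csv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_breaths_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write the PEEP-trial tables of one or more experiments as CSV
#'
#' One row per pig x trial x descent step: pig_id, trial_index, peep, pao2,
#' paco2, crs, co, do2, pf, terminated_reason.
#'
#' @param logs list of `experiment_log`s (or a single log).
#' @param path output file.
#' @return the table, invisibly.
#' @export
write_trials_csv <- function(logs, path) {
  if (inherits(logs, "experiment_log")) logs <- list(logs)
  rows <- list()
  for (log in logs) {
    for (k in seq_along(log$trials)) {
      tr <- log$trials[[k]]
      if (is.null(tr) || nrow(tr$steps) == 0) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(pig_id = log$pig_id, arm = log$arm, trial_index = k),
        tr$steps,
        data.frame(terminated_reason = tr$terminated_reason)
      )
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a trials CSV written by [write_trials_csv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_trials_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a JSON summary of one experiment
#'
#' Serializes the animal parameters, protocol milestones (lavage cycles,
#' snapshots), per-trial best PEEPs under all three criteria, and survival.
#'
#' @param log an `experiment_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(log, path) {
  snap_num <- function(bg) {
    if (is.null(bg)) return(NULL)
    list(pao2 = bg$pao2, paco2 = bg$paco2, ph = bg$ph, spo2 = bg$spo2,
         pf = bg$pf_ratio, co = bg$co, do2 = bg$do2)
  }
  trials <- lapply(log$trials, function(tr) {
    if (is.null(tr) || nrow(tr$steps) == 0) return(NULL)
    list(
      terminated_reason = tr$terminated_reason,
      lowest_peep = min(tr$steps$peep),
      best_peep = list(
        crs = best_peep(tr, "crs")$best_peep,
        pao2 = best_peep(tr, "pao2")$best_peep,
        do2 = best_peep(tr, "do2")$best_peep
      ),
      steps = tr$steps
    )
  })
  obj <- list(
    pig_id = log$pig_id, arm = log$arm, seed = log$seed, bw_kg = log$bw,
    alive = log$alive, lavage_cycles = log$lavage_cycles,
    consolidated_fraction = consolidated_fraction(log$pig),
    snapshots = list(
      baseline = snap_num(log$snapshots$baseline),
      post_lavage = snap_num(log$snapshots$post_lavage),
      post_rm1 = snap_num(log$snapshots$post_rm1$bg),
      post_rm2 = snap_num(log$snapshots$post_rm2$bg),
      post_rm3 = snap_num(log$snapshots$post_rm3$bg)
    ),
    trials = trials
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Serialize a pig (without its parameter block) to JSON
#' @param pig a `pig`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pig_json <- function(pig, path) {
  obj <- pig[setdiff(names(pig), "params")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
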