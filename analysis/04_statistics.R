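#!/usr/bin/env Rscript
# Descriptive statistics over the two arms: the per-instant and per-hour
# cohort summary tables, Mann-Whitney U comparisons of the key endpoints at
# each protocol instant, relative treatment effects, and the mechanical-power
# phase summaries.

suppressPackageStartupMessages(library(pigvent))

logs <- readRDS("results/experiment/logs.rds")
out_dir <- "results/statistics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cs <- cohort_summary(unname(logs))
write.csv(cs$instants, file.path(out_dir, "summary_instants.csv"), row.names = FALSE)
write.csv(cs$phases, file.path(out_dir, "summary_phases.csv"), row.names = FALSE)

# wide mean +/- SD layout, one row per variable x instant
wide <- reshape(transform(cs$instants,
                          cell = sprintf("%.1f +/- %.1f", mean, sd))[
                            , c("arm", "instant", "variable", "cell")],
                direction = "wide", idvar = c("variable", "instant"),
                timevar = "arm")
write.csv(wide, file.path(out_dir, "summary_table_wide.csv"), row.names = FALSE)

arms <- split(unname(logs), vapply(logs, `[[`, character(1), "arm"))
instant_value <- function(l, instant, what) {
  if (instant == "post_lavage") {
    bg <- l$snapshots$post_lavage
    if (is.null(bg)) return(NA_real_)
    if (what == "pf") bg$pf_ratio else bg[[what]]
  } else {
    a <- l$snapshots[[instant]]
    if (is.null(a)) return(NA_real_)
    if (what == "crs") a$crs else if (what == "pf") a$bg$pf_ratio else a$bg[[what]]
  }
}

cat("Mann-Whitney U comparisons (protective vs injurious):\n")
mw_rows <- list()
for (instant in c("post_lavage", "post_rm1", "post_rm2", "post_rm3")) {
  for (what in c("pf", "crs", "paco2")) {
    if (instant == "post_lavage" && what == "crs") next
    a <- vapply(arms$protective, instant_value, numeric(1), instant, what)
    b <- vapply(arms$injurious, instant_value, numeric(1), instant, what)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) next
    ts <- rank_sum_test(a, b)
    mw_rows[[length(mw_rows) + 1L]] <- data.frame(
      instant = instant, variable = what,
      mean_protective = mean(a), mean_injurious = mean(b),
      u = ts$u, p_value = ts$p_value, method = ts$method)
  }
}
mw <- do.call(rbind, mw_rows)
print(transform(mw[, 1:6], mean_protective = round(mean_protective, 1),
                mean_injurious = round(mean_injurious, 1),
                p_value = signif(p_value, 3)), row.names = FALSE)
write.csv(mw, file.path(out_dir, "mann_whitney.csv"), row.names = FALSE)

# relative treatment effects of post-RM3 P/F across arms
pf3 <- lapply(arms, function(v) {
  x <- vapply(v, instant_value, numeric(1), "post_rm3", "pf")
  x[!is.na(x)]
})
rte <- relative_treatment_effect(unlist(pf3),
                                 rep(names(pf3), lengths(pf3)))
cat("\nrelative treatment effects, post-RM3 P/F:\n")
print(rte, row.names = FALSE)
write.csv(rte, file.path(out_dir, "rte_post_rm3_pf.csv"), row.names = FALSE)

# mechanical power by phase
mp_rows <- list()
for (arm in names(arms)) {
  for (l in arms[[arm]]) {
    for (ph in c("phase1", "phase2")) {
      b <- l$breaths[l$breaths$stage == ph, ]
      if (!nrow(b)) next
      s <- phase_mp_summary(b, ph)
      mp_rows[[length(mp_rows) + 1L]] <- data.frame(
        arm = arm, pig_id = l$pig_id, phase = ph, mp_mean = s$mean, mp_sd = s$sd)
    }
  }
}
mp <- do.call(rbind, mp_rows)
write.csv(mp, file.path(out_dir, "mechanical_power_phases.csv"), row.names = FALSE)
agg <- aggregate(mp_mean ~ arm + phase, mp, function(x) c(mean(x), sd(x)))
cat("\nmechanical power by phase (group mean +/- SD, J/min):\n")
print(data.frame(arm = agg$arm, phase = agg$phase,
                 mean = round(agg$mp_mean[, 1], 1),
                 sd = round(agg$mp_mean[, 2], 1)), row.names = FALSE)
cat("\nwritten to", out_dir, "\n")
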