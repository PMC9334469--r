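#!/usr/bin/env Rscript
# Decremental PEEP-trial analysis: group-mean response curves per arm and
# trial, best PEEP under the compliance / oxygenation / oxygen-delivery
# criteria (group curve and per-animal), and the recovery of Crs and PaO2
# after each recruitment maneuver relative to the post-lavage values.

suppressPackageStartupMessages(library(pigvent))

logs <- readRDS("results/experiment/logs.rds")
out_dir <- "results/best_peep"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

arms <- split(logs, vapply(logs, `[[`, character(1), "arm"))

bp_rows <- list()
curve_rows <- list()
for (arm in names(arms)) {
  for (k in 1:3) {
    trials <- Filter(function(tr) !is.null(tr) && nrow(tr$steps) > 0,
                     lapply(arms[[arm]], function(l) {
                       if (length(l$trials) >= k) l$trials[[k]]
                     }))
    if (!length(trials)) next
    for (crit in c("crs", "pao2", "do2")) {
      g <- group_best_peep(trials, crit)
      bp_rows[[length(bp_rows) + 1L]] <- data.frame(
        arm = arm, trial = k, criterion = crit, n = g$n_animals,
        best_peep_group = g$best_peep, best_value_group = g$best_value,
        best_peep_indiv_mean = mean(g$individual),
        best_peep_indiv_sd = sd(g$individual))
      curve_rows[[length(curve_rows) + 1L]] <- cbind(
        data.frame(arm = arm, trial = k, criterion = crit), g$curve)
    }
  }
}
best_peep_tab <- do.call(rbind, bp_rows)
write.csv(best_peep_tab, file.path(out_dir, "best_peep.csv"), row.names = FALSE)
write.csv(do.call(rbind, curve_rows), file.path(out_dir, "group_curves.csv"),
          row.names = FALSE)

cat("group-level best PEEP (cmH2O):\n")
print(best_peep_tab[best_peep_tab$criterion %in% c("crs", "pao2"),
                    c("arm", "trial", "criterion", "best_peep_group",
                      "best_value_group")],
      row.names = FALSE)

# recovery after each RM relative to the post-lavage state (percent)
dev_rows <- list()
for (arm in names(arms)) {
  for (l in arms[[arm]]) {
    lav <- l$snapshots$post_lavage
    lav_crs <- {
      b <- l$breaths
      tail(b$crs[b$stage == "lavage"], 1)
    }
    for (k in 1:3) {
      a <- l$snapshots[[paste0("post_rm", k)]]
      if (is.null(a)) next
      dev_rows[[length(dev_rows) + 1L]] <- data.frame(
        arm = arm, pig_id = l$pig_id, rm = k,
        crs_dev_pct = deviation_from_lavage(a$crs, lav_crs),
        pao2_dev_pct = deviation_from_lavage(a$bg$pao2, lav$pao2))
    }
  }
}
dev <- do.call(rbind, dev_rows)
write.csv(dev, file.path(out_dir, "deviation_from_lavage.csv"), row.names = FALSE)

agg <- aggregate(cbind(crs_dev_pct, pao2_dev_pct) ~ arm + rm, dev, mean)
agg[-(1:2)] <- round(agg[-(1:2)], 1)
cat("\nmean recovery vs post-lavage (%):\n")
print(agg, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  curves <- do.call(rbind, curve_rows)
  p <- ggplot(subset(curves, criterion %in% c("crs", "pao2")),
              aes(peep, value, colour = arm)) +
    geom_line() + geom_point(size = 1) +
    facet_grid(criterion ~ trial, scales = "free_y",
               labeller = labeller(criterion = c(crs = "Crs [mL/cmH2O]",
                                                 pao2 = "PaO2 [mmHg]"),
                                   trial = function(x) paste("PEEP trial", x))) +
    labs(x = "PEEP [cmH2O]", y = NULL,
         title = "Decremental PEEP trials: group mean response curves") +
    theme_bw()
  ggsave(file.path(out_dir, "peep_trial_curves.pdf"), p, width = 9, height = 5)
}
cat("\nwritten to", out_dir, "\n")
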