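# pigvent

Breath-by-breath simulation of a **two-hit porcine model of acute lung
injury** — saline-lavage surfactant depletion followed by either protective
(automated closed-loop) or injurious (high tidal volume, low PEEP)
ventilation — together with the protocol and analysis machinery used to
study it: recruitment maneuvers, decremental PEEP trials with best-PEEP
identification, mechanical-power tracking, and nonparametric descriptive
statistics.

Single-hit lavage models recover too easily: one recruitment maneuver (RM)
reopens the surfactant-depleted alveoli and oxygenation normalizes, which
limits their value for testing ventilation strategies. Adding a transient
phase of injurious ventilation (VT 17 mL/kg, PEEP 2 cmH2O, RR 12/min) after
lavage produces a lung with *low recruitability* and persistently impaired
gas exchange. `pigvent` reproduces that contrast on virtual animals so the
closed-loop protective-ventilation algorithm and the PEEP-titration analysis
can be exercised end-to-end.

## The model in brief

* **Lung**: 500 alveolar units with threshold opening/closing pressures
  (closing < opening, giving hysteresis) and an irreversible *consolidated*
  state. Dynamic compliance of a breath is
  `Crs = C_stiff + C_scale · f_insp · s_od(PIP)`, with `f_insp` the
  end-inspiratory open fraction and `s_od` a sigmoid overdistension factor;
  delivered volume is `VT = Crs · ΔP`. Pressure-controlled ventilation with
  volume guarantee retargets `ΔP = VT_target / Crs` once per breath.
* **Injury**: lavage cycles shift unit thresholds (opening-dominant) until
  PaO2 < 100 mmHg at FiO2 1.0 / PEEP 6 is sustained 10 min; ventilator-induced
  injury consolidates cyclically recruited units (atelectrauma) and
  over-strained units (volutrauma) with small per-breath probabilities.
* **Gas exchange**: alveolar gas equation, Severinghaus dissociation curve,
  Berggren venous admixture `CaO2 = CcO2 − s/(1−s) · VO2/(10·CO)` inverted
  numerically; `PaCO2 = 863·VCO2/VA` with a mechanistic dead-space model;
  Henderson–Hasselbalch pH at fixed bicarbonate; cardiac output declining
  with PEEP.
* **Controller** (ARDSNet-style closed loop): SpO2 88–95 % drives single-row
  moves on the "higher PEEP / lower FiO2" table; VT steps 6 → 5 → 4 mL/kg when
  PIP exceeds 30 cmH2O; pH entered every 30 min titrates RR by ±5/min up to
  the 35/min cap.
* **Mechanical power** (pressure-controlled, simplified):
  `M_P = 0.098 · RR · VT · (ΔP + PEEP)` J/min with VT in liters.
* **Statistics**: best PEEP as the argmax of compliance / PaO2 / DO2 over the
  decremental-trial descent (group-mean curves and per-animal), relative
  treatment effects from mid-ranks, Mann–Whitney U with exact enumeration
  for combined n ≤ 12.

All parameters live in `inst/extdata/default_params.yaml` (see
`pv_params()`); the methods vignette (`vignettes/two-hit-model.Rmd`)
documents the model, its calibration and its limitations.

## Worked example

One virtual pig through baseline, lavage, a recruitment maneuver and a
decremental PEEP trial (~30 s):

```r
library(pigvent)
params <- pv_params()
pig <- make_cohort(1, bw_mean = 46, bw_sd = 3, seed = 7, params = params)[[1]]
set.seed(7)
bl  <- run_baseline(pig, params)                        # 60 min, RR servo on PaCO2
lv  <- run_lavage(bl$pig, params, t0 = bl$t, rr = bl$rr)
lv$n_cycles
#> [1] 3
lv$bg                                                   # qualifying blood gas
#> <blood gas> PaO2 96 mmHg, PaCO2 62 mmHg, pH 7.21, SpO2 97%, P/F 96, CO 3.9 L/min, DO2 526 mL/min
rm1 <- run_recruitment_maneuver(lv$pig, params, t0 = lv$t)
rm1$assessment$bg                                       # prompt post-RM recovery
#> <blood gas> PaO2 602 mmHg, PaCO2 38 mmHg, pH 7.43, SpO2 100%, P/F 602, CO 3.4 L/min, DO2 517 mL/min
vh <- run_volume_history(rm1$pig, params, t0 = rm1$t)
tr <- run_peep_trial(vh$pig, params, t0 = vh$t)
tr
#> <peep trial> 10 descent steps, terminated: min_peep
#>  peep  pao2 paco2  crs  co   do2    pf
#>    24 513.1  91.2 17.7 2.9 427.2 513.1
#>    22 531.1  79.6 17.8 3.0 446.7 531.1
#>    20 546.5  69.8 17.9 3.1 466.2 546.5
#>    18 553.0  61.0 18.2 3.2 484.8 553.0
#>    16 555.2  50.4 19.3 3.3 503.1 555.2
#>    14 542.8  40.4 21.7 3.5 519.9 542.8
#>    12 489.5  35.3 23.9 3.6 532.2 489.5
#>    10 346.5  37.6 23.5 3.7 534.0 346.5
#>     8 184.6  44.0 21.8 3.8 531.1 184.6
#>     6  97.7  52.8 20.1 3.9 526.8  97.7
best_peep(tr, "crs")
#> <best PEEP by crs> 12 cmH2O (value 23.9)
best_peep(tr, "pao2")
#> <best PEEP by pao2> 16 cmH2O (value 555.2)
```

The trial shows the model's central physiology: compliance peaks at
PEEP 12 cmH2O (below that the lung derecruits, above it overdistends) while
oxygenation peaks higher, at PEEP 16 cmH2O — the 4 cmH2O disparity between
the two "best PEEP" definitions. The simplified pressure-controlled power of
the injurious settings on a 46-kg animal:

```r
mechanical_power(rr = 12, vt_l = 0.017 * 46, dp = 49, peep = 2)
#> [1] 46.90123   # J/min
```

## The full study

The numbered drivers under `analysis/` run the complete two-arm experiment
(6 virtual pigs per arm, ~5 min total) and write tidy tables under
`results/`:

```sh
Rscript analysis/01_cohort.R       # cohorts + baseline characteristics
Rscript analysis/02_experiment.R   # full protocol, per-pig breaths/trials/summary
Rscript analysis/03_best_peep.R    # group PEEP-trial curves, best PEEP, RM recovery
Rscript analysis/04_statistics.R   # summary tables, Mann-Whitney, RTE, phase M_P
```

`PIGVENT_SEED` (default 1) selects the cohort seed. Headline group results
with the shipped calibration: best-compliance PEEP 12 cmH2O (protective arm,
all three trials) vs 16 cmH2O (injurious arm, trials 2–3); post-RM3 P/F
above 300 mmHg in the protective arm vs below 300 in the injurious arm;
phase-1 mechanical power ~51 vs ~12 J/min.

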