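---
title: "A two-hit porcine lung-injury simulator for closed-loop ventilation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-hit porcine lung-injury simulator for closed-loop ventilation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigvent)
```

## The problem this package models

Saline-lavage surfactant depletion is the classic porcine model of acute
hypoxemic lung failure, but it recovers too easily: a single recruitment
maneuver reopens the collapsed alveoli and oxygenation normalizes, which is
not how ARDS behaves in patients. A two-hit design — lavage followed by a
period of deliberately injurious ventilation (high tidal volume, minimal
PEEP) — produces a lung with *low recruitability*: recruitment maneuvers no
longer restore compliance or oxygenation, and the PEEP needed to keep the
lung open is higher. `pigvent` is a breath-by-breath simulator of that
experiment, including the automated ARDSNet-style closed-loop controller
used to deliver protective ventilation, the recruitment-maneuver and
decremental PEEP-trial protocol machinery, mechanical-power tracking, and
the nonparametric descriptive statistics used to compare the two arms.

Everything is driven from a single YAML parameter file
(`inst/extdata/default_params.yaml`, loaded by `pv_params()`); the numbered
scripts under `analysis/` run the full study and write tidy CSV outputs.

## The virtual lung

The lung is a population of `n_units = 500` independent alveolar units with
threshold behavior:

* a **closed** unit opens during inspiration when PIP reaches its
  *opening pressure*;
* an **open** unit collapses at end-expiration when PEEP is below its
  *closing pressure*;
* a **consolidated** unit (destroyed by ventilator-induced injury) never
  re-aerates.

Closing pressures sit below opening pressures (healthy gap 1–3 cmH2O), so
the lung shows pressure–volume hysteresis: a recruited lung can be held open
at pressures far below those needed to open it. Units that open during
inspiration and re-collapse within the same breath are **cyclic** — they are
the substrate of atelectrauma.

The realized dynamic compliance of a breath is

```
Crs = stiff_compliance + compliance_scale × f_insp × s_od(PIP)
```

where `f_insp` is the end-inspiratory open fraction and `s_od` is an
overdistension factor: a descending sigmoid in PIP (half-effect
`od_p50 = 27.5` cmH2O, width 1.5 cmH2O, floor `od_min = 0.55`) normalized to
1 at low pressure. The factor represents the flattening of the
pressure–volume curve as open units approach their capacity; without it, a
decremental PEEP trial at constant driving pressure would show compliance
increasing monotonically with PEEP and no interior "best PEEP" could exist.
Its width grows with the consolidated fraction (saturating at 30 %
consolidation): an injured lung is mechanically heterogeneous, so its
population-level volume limit is reached over a broader pressure range. This
is what separates the two arms' best-compliance PEEP (12 vs 16 cmH2O, see
below) — in the stiff, heterogeneous post-VILI lung the trade-off between
recruitment and overdistension resolves at a higher PEEP.

Delivered tidal volume is `VT = Crs × ΔP`. Two ventilator contracts exist:
`PCV_VG` (volume guarantee: ΔP is retargeted once per breath as
`VT_target / Crs(previous breath)`, rate-limited to ±2 cmH2O per breath and
capped at `pip_limit`) and `PCV_FIXED_DP` (fixed driving pressure, used by
recruitment maneuvers and PEEP trials). The rate limit mirrors the pressure
ramping of real ventilators and keeps the volume-guarantee feedback loop
stable when compliance changes abruptly (e.g. at phase transitions).

## Injury processes

**Lavage.** Each saline lavage cycle depletes surfactant in a random subset
of units (`lavage_hit_prob = 0.4`). A hit unit's opening pressure rises by
~13 cmH2O and its closing pressure by ~4.6 cmH2O; the compliance scale falls
8 % per cycle and an alveolar dead-space fraction of 0.06 per cycle
accumulates (surfactant dysfunction produces ventilation–perfusion mismatch
beyond what the open/closed geometry captures). Two modelling choices here
are deliberate and load-bearing:

* *The shift is opening-dominant.* Surfactant depletion's signature is a
  wide hysteresis gap — a lung that is hard to open (opening pressures
  ~30 cmH2O, hence post-lavage PIP ≈ 30 and low collapsed-state compliance)
  but easy to keep open once recruited (closing pressures mostly below
  15 cmH2O, hence the prompt post-RM recovery of oxygenation at PEEP 15).
  A symmetric shift of both thresholds cannot produce both at once.
* *Hits are per-unit-per-cycle random.* Repeatedly hit units accumulate high
  thresholds while spared units keep low closing pressures, giving a bimodal
  closing-pressure distribution. The spared mode keeps the low-PEEP end of a
  decremental trial oxygenated (the descent reaches the 6 cmH2O floor); the
  shifted tail keeps oxygenation shunt-limited through PEEP 14 so that the
  best-oxygenation PEEP lands above the best-compliance PEEP.

Lavage cycles repeat until PaO2 at FiO2 1.0 / PEEP 6 stays below 100 mmHg
for 10 consecutive minutes (judged after a 3-min settle period, so the
criterion is not defeated by oxygenation carried over from the pre-cycle
state). The cycle count is emergent — with the defaults, cohorts qualify in
3–4 cycles with qualifying PaO2 ≈ 65–95 mmHg.

**Ventilator-induced injury.** Two per-breath mechanisms, both stochastic:

* *Atelectrauma*: each cyclic unit consolidates with probability
  1.35 × 10⁻⁴ per breath, and its closing pressure creeps upward by
  0.0015 cmH2O per cyclic event (opening by half that), saturating at a
  ceiling of 15.8 cmH2O. The creep represents progressive surfactant
  inactivation by cyclic stress; its ceiling encodes that atelectrauma
  destabilizes end-expiratory patency only up to mid-range airway pressures.
  Three hours of VT 17 mL/kg at PEEP 2 (RR 12) expose essentially every
  recruitable unit to cyclic stress every breath.
* *Volutrauma*: when per-unit tidal strain (tidal volume shared over open
  units, relative to per-unit capacity) exceeds 1, open units consolidate
  with probability 0.6 × 10⁻⁴ per breath, and the excess strain adds
  dead space (zone-1-like overdistension of the baby lung).

Consolidation is irreversible by construction — the model has no healing —
so the consolidated fraction is non-decreasing along any ventilation
history. With the defaults, the injurious phase ends with ~30–40 % of units
consolidated; six hours of protective ventilation produce under ~5 %.

## Gas exchange and hemodynamics

Blood gases are quasi-steady, recomputed every breath from the current
aeration state:

* `PaCO2 = 863 × VCO2 / VA` (capped to 10–200 mmHg), with
  `VA = RR × VT × (1 − VD/VT)`. The physiological dead-space fraction is the
  airway dead space (1.5 mL/kg) plus terms for derecruitment, consolidation,
  overdistension (both the sigmoid factor and excess strain), lavage-induced
  surfactant dysfunction, and PEEP above 15 cmH2O (compression of alveolar
  vessels), capped at 0.92. The PEEP and overdistension terms reproduce the
  clinically familiar hypercapnia at high PEEP; the lavage term reproduces
  the persistent hypercapnia of the injured cohorts despite RR 35.
* pH follows Henderson–Hasselbalch with bicarbonate fixed at 24 mmol/L — no
  metabolic compensation over the 8-h experiment, which makes the
  controller's acidosis pathway a deterministic function of PaCO2.
* Oxygenation: alveolar PO2 from the alveolar gas equation, the Severinghaus
  dissociation curve for saturations (accurate at both asymptotes, no Bohr
  correction), and Berggren venous admixture solved exactly for arterial
  PO2: the mixing balance gives `CaO2 = CcO2 − shunt/(1−shunt) × VO2/(10 CO)`
  (mixed-venous content via Fick at fixed VO2 = 3.5 mL/kg/min), inverted
  through the content curve by a monotone root find (tolerance well below
  0.1 mmHg; floored at PaO2 = 3 mmHg). Effective shunt is the
  hypoxic-vasoconstriction-attenuated (factor 0.6) perfusion to
  non-participating units: never-opened units count fully, cyclically open
  units at 0.8 (they exchange during part of the breath), consolidated units
  at 0.5 (vascular destruction and chronic diversion reduce their perfusion
  below that of acutely collapsed tissue).
* Cardiac output falls linearly with PEEP above 5 cmH2O (1.5 %/cmH2O,
  floored at 30 % of baseline), so CO and oxygen delivery recover
  monotonically during a decremental trial. This is deliberately crude — no
  pulmonary-artery pressures or fluid responsiveness are modelled.

Death: PaO2 below 30 mmHg sustained for 10 simulated minutes sets
`alive = FALSE` and truncates the protocol into a partial log. The rule is a
placeholder — the experiment it emulates reported deaths without stating a
criterion — and with default calibration the cohorts survive.

## The closed-loop controller

The protective arm is ventilated by `make_controller()` /
`controller_step()`:

* **Oxygenation**: SpO2 target band 88–95 %, evaluated every 30 s; out-of-band
  readings move one row along the ARDSNet "higher PEEP / lower FiO2" table
  (shipped as editable config rows in the YAML, not hard-coded), with a
  5-min dwell between moves to prevent oscillation. Emitted (FiO2, PEEP) is
  always an exact table row.
* **Tidal volume**: the setpoint steps down 6 → 5 → 4 mL/kg when observed PIP
  strictly exceeds 30 cmH2O, judged on the same 30-s cadence so that
  single-breath transients during recruitment do not trigger an irreversible
  reduction. There is no automatic re-escalation — a conservative reading of
  a protocol that describes only reductions. On the calibrated (stiff) lungs
  this rule is genuinely active: phases often settle at 4–5 mL/kg, which is
  the rule doing its job rather than an artifact.
* **Respiratory rate**: arterial pH, entered once every 30 min, moves RR by
  ±5/min outside 7.30–7.45, capped at 35/min with a floor of 10/min (the
  floor is a design choice; only the cap is protocol-specified).

Controllers are deterministic given their input sequence; their decisions
are logged as an events table.

## The protocol engine

`run_full_experiment()` executes: 60-min baseline (PCV-VG, VT 6 mL/kg,
PEEP 7, RR servo-adjusted every 5 min to hold PaCO2 in 37–45 mmHg) → lavage
to criterion → three blocks of {recruitment maneuver → volume-history
standardization → decremental PEEP trial} bracketing ventilation phase 1
(3 h protective or injurious) and phase 2 (3 h protective in both arms).

* **Recruitment maneuver**: PEEP ladder 12 → 16 → 20 → 24 at ΔP 20 (5 breaths
  per rung — the protocol allows 2–4 cmH2O rungs; 4 is used and
  configurable), 5 cycles at PIP 50 / PEEP 24, then 5 min at PEEP 15 /
  VT 6 mL/kg with the standardized assessment (blood gas, Crs, M_P, CO)
  taken at minute 5. Maximum commanded PIP is exactly 50 cmH2O.
* **Volume history**: 10 cycles at VT 10 mL/kg / PEEP 0 / RR 10 / I:E 1:1,
  then a 5-s disconnection at airway pressure 0, collapsing every unit with
  positive closing pressure — each trial starts from the same volume
  history.
* **PEEP trial**: ascent 12 → 24 by 4 (5 cycles per step), descent
  24, 22, …, 6 at constant ΔP 14 / RR 20 / FiO2 1.0 with 10 simulated
  minutes (200 breaths) per step; measurements at the end of each descent
  step only (whether ascent steps were "measurements" is ambiguous in the
  source protocol; they are not treated as such here). The descent stops at
  the 6 cmH2O floor or as soon as a recorded P/F falls below 80 mmHg.
  Trial FiO2 is taken as 1.0 — implied by the P/F < 80 stopping rule and
  the post-lavage context, though not stated outright.

Time is kept in seconds with one breath = 60/RR s; a 10-min trial step is
exactly 200 breaths at RR 20. Re-running with the same pig and seed
reproduces the experiment log byte-for-byte.

## Analysis

`best_peep()` takes the argmax of a criterion (dynamic compliance, PaO2, or
DO2) over the measured descent steps, with ties broken toward the lower PEEP
(less exposure for equal benefit; the calibrated group curves have unique
maxima, so the rule is a safeguard). `group_best_peep()` first averages the
per-animal curves at each PEEP level measured in *all* animals (early
hypoxemic termination truncates individual descents) and then takes the
argmax; per-animal best PEEPs are carried alongside.
`relative_treatment_effect()` computes the mid-rank-based RTE descriptive
(size-weighted mean exactly 0.5); `rank_sum_test()` is a Mann–Whitney U with
full enumeration for combined n ≤ 12 (exact under ties) and a tie- and
continuity-corrected normal approximation otherwise. The longitudinal
ANOVA-type inferential statistic of the original analysis is intentionally
out of scope.

## Calibration, and what passing tests show

Free parameters were calibrated by simulation against the study conditions
the source experiment prints — post-lavage PaO2 ≈ 80 mmHg and hypercapnia,
PIP ≈ 50 at VT 17 mL/kg, recruitable-arm best-compliance/best-oxygenation
PEEP of 12/16 cmH2O, injured-arm best-compliance PEEP 16 cmH2O,
post-RM P/F above vs below 300 mmHg, phase mechanical power near the printed
group means — and then frozen; the defaults in the YAML are those frozen
values. The calibrated behavior is stable across cohort seeds.

The generator emulates threshold recruitment, hysteresis, shunt-driven
hypoxemia, dead-space-driven hypercapnia, and the dose–response of
atelectrauma and volutrauma. It does not emulate intra-breath flow dynamics,
gravitational/regional structure, edema or inflammation biology, pulmonary
vascular pressures, fluid and drug effects, or spontaneous breathing —
passing tests therefore demonstrate internal consistency with the modelled
mechanisms and the protocol logic, not predictive validity for real animals.
Known quantitative gaps: recruited-state compliance runs ~30 % below the
real animals' (so protective phases trip the VT-reduction rule more often
than the real controller did), phase-level mechanical power is
correspondingly lower, and the injured arm's best-oxygenation PEEP sits at
16–18 rather than 20–22 cmH2O.

## Problem sizes and numerical choices

The shipped study conditions are 6 pigs per arm at 500 units per pig; a full
8-h virtual experiment is ~15,000–20,000 breaths and runs in under 15 s, the
whole two-arm study in a few minutes. Unit tests run the protocol on
shortened schedules (the `protocol` block of the YAML); the acceptance suite
runs the full-length study once. Numerical details: the shunt inversion uses
`uniroot` at tolerance 1e-4 on a bracket guaranteed by monotonicity;
PaCO2 is clamped to 10–200 mmHg and VD/VT to ≤ 0.92; the VG driving pressure
is clamped to [1, pip_limit − PEEP]; consolidation draws consume RNG only
for candidate units, so trajectories are reproducible under a fixed seed
regardless of injury incidence.
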