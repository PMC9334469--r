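# Default calibration for the two-hit porcine lung-injury simulator.
# All pressures cmH2O, volumes mL, times seconds unless noted.
lung:
  n_units: 500
  opening_mean: 3.0        # healthy opening pressure, Normal(mean, sd), clipped >= opening_min
  opening_sd: 2.0
  opening_min: 0.5
  gap_min: 1.0             # closing = opening - Uniform(gap_min, gap_max)
  gap_max: 3.0
  compliance_per_kg: 0.65  # mL/cmH2O per kg at full aeration
  stiff_compliance: 4.0    # mL/cmH2O floor when fully derecruited
  od_p50: 27.5             # overdistension sigmoid: PIP at half effect
  od_width: 1.5            # sigmoid width, cmH2O (healthy lung)
  od_width_consol_gain: 5.0 # width multiplier per unit consolidated fraction (heterogeneity)
  od_width_consol_cap: 0.3  # consolidated fraction beyond which heterogeneity saturates
  od_min: 0.55             # compliance multiplier floor at very high PIP
  capacity_cmh2o: 30.0     # aerated capacity = compliance_scale * capacity_cmh2o (mL)
  dp_rate_limit: 2.0       # max change of the VG driving pressure per breath
injury:
  lavage_shift_mean: 13.0        # opening-pressure shift per hit unit per lavage cycle
  lavage_shift_sd: 3.5
  lavage_hit_prob: 0.4           # fraction of units surfactant-depleted per cycle
  lavage_closing_frac: 0.35      # mean closing shift as fraction of the opening shift
  lavage_closing_sd: 1.5         # sd of the per-cycle closing shift
  lavage_compliance_loss: 0.08   # fractional loss of compliance_scale per cycle
  lavage_deadspace_gain: 0.06    # added alveolar dead-space fraction per cycle
  cyclic_consolidation_prob: 1.35e-4
  overdistension_strain_threshold: 1.0
  overdistension_consolidation_prob: 0.6e-4
  cyclic_pressure_creep: 0.0015   # cmH2O added to closing pressure per cyclic event
  cyclic_creep_opening_frac: 0.5 # fraction of the creep applied to opening pressure
  cyclic_creep_ceiling: 15.8     # closing-pressure saturation of atelectrauma creep
  shunt_hpv_factor: 0.6          # hypoxic vasoconstriction attenuation of shunt
  cyclic_shunt_weight: 0.8       # shunt weight of units open only during inspiration
  consolidated_shunt_weight: 0.5  # perfusion weight of consolidated units (vascular diversion)
gas:
  hb: 10.0                 # g/dL
  hco3: 24.0               # mmol/L, fixed (no metabolic compensation)
  rq: 0.8
  pb: 760.0                # barometric pressure, mmHg
  ph2o: 47.0               # water vapor pressure, mmHg
  vo2_per_kg: 3.5          # mL O2/min/kg
  vd_aw_per_kg: 1.5        # airway (series) dead space, mL/kg
  deadspace_gain_aeration: 0.2       # VD/VT gain per unit (1 - end-expiratory aeration)
  deadspace_gain_consolidation: 0.3   # VD/VT gain per unit consolidated fraction
  deadspace_gain_overdistension: 0.05 # VD/VT gain per unit (1 - overdistension factor)
  deadspace_gain_strain: 0.4          # VD/VT gain per unit tidal strain above threshold
  deadspace_gain_peep: 0.02           # VD/VT gain per cmH2O PEEP above the onset (vascular compression)
  deadspace_peep_onset: 15.0
hemo:
  co_base: 4.0             # L/min at PEEP <= 5
  co_peep_slope: 0.015     # fractional CO loss per cmH2O PEEP above 5
controller:
  spo2_low: 0.88
  spo2_high: 0.95
  ph_low: 7.30
  ph_high: 7.45
  rr_step: 5
  rr_max: 35
  rr_min: 10
  pip_threshold: 30.0      # strict: VT step down when PIP exceeds this
  dwell_s: 300             # minimum time between PEEP/FiO2 table moves
  oxy_eval_s: 30           # SpO2 evaluation cadence
  ph_interval_s: 1800      # pH input cadence
  pip_limit: 60.0          # absolute PIP cap of the volume-guarantee mode
  # ARDSNet "higher PEEP / lower FiO2" table (fio2 fraction, peep cmH2O)
  table:
    fio2: [0.3, 0.3, 0.3, 0.3, 0.3, 0.4, 0.4, 0.5, 0.5, 0.5, 0.6, 0.7, 0.8, 0.8, 0.9, 1.0, 1.0]
    peep: [5, 8, 10, 12, 14, 14, 16, 16, 18, 20, 20, 20, 20, 22, 22, 22, 24]
death:
  pao2_threshold: 30.0     # mmHg
  sustain_s: 600           # sustained hypoxemia window before death
protocol:
  baseline_min: 60
  phase_hours: 3
  trial_step_breaths: 200  # 10 min at RR 20
  trial_dwell_ascent: 5
  rm_rung_breaths: 5
  rm_hold_min: 5
  lavage_max_cycles: 20
  lavage_window_min: 10
  lavage_settle_min: 3
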