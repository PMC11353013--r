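# Example analysis configuration: assay constants, exposures, regimens.
seed: 1
assay:
  serum: "10%FBS"
  fu_media_a: 0.034        # belvarafenib, fraction unbound in media
  fu_media_b: 0.196        # cobimetinib
  fu_plasma_a: 0.00258
  fu_plasma_b: 0.052
  mw_a: 478.93             # g/mol
  mw_b: 531.3
  doubling_time_in_vitro: 60   # h
  treatment_hours: 120
  doubling_time_in_vivo: 18    # days
  in_vitro_to_in_vivo_free: 1
exposure:                  # measured mouse free plasma concentrations, nM
  belva_15mgkg: 8
  belva_30mgkg: 20
  cobi_5mgkg: 3
prediction:
  initial_volume_mm3: 240
  horizon_days: 21
regimens:
  - {drug: belvarafenib, dose_mg: 100, schedule: BID, duration_days: 30}
  - {drug: cobimetinib, dose_mg: 40, schedule: QD, duration_days: 30}
pk_models:
  belvarafenib: {ka: 0.5, cl_f: 5, v_f: 100, omega_ka: 0.5,
                 omega_cl: 0.3, omega_v: 0.3}
  cobimetinib: {ka: 0.5, cl_f: 13, v_f: 800, omega_ka: 0.5,
                omega_cl: 0.3, omega_v: 0.3}
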