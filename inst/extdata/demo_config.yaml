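# Demo configuration for the end-to-end retrieval-analysis pipeline.
# Sections map to the package's simulation and statistics modules;
# any omitted key falls back to the package default.

simulate:
  seed: 1
  cohort:
    n_liners: 120
  linescan:
    thickness_um: 4000
    step_um: 100
    oi_peak_heights: [2.0, 1.2]
    oi_plateau: 0.5
    noise_sd: 0.0005
  indent:
    target_modulus_MPa: 900
    target_hardness_MPa: 60
    max_load_mN: 500
    hold_time_s: 6

stats:
  group_by: sterilization
  value_col: OI(max,UW)
  method: welch_t
  filter: "OI(max,UW) <= 4"
  columns:
    - OI(max,UW)
    - OI(ave,UW)
    - CI(max,UW)
    - CI(ave,UW)
    - HV(ave,UW)
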