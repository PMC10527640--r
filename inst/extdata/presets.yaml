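# Ground-truth presets for the emulated experimental groups.
#
# tau_decay_ms and wave_rates are the printed group means for WT sham,
# 2-month-alcohol WT and 2-month-alcohol JNK2dn mouse atria. The JNK2dn
# decay constant was reported only as "normalized" relative to controls, so
# the sham value is used. Everything else (amplitude, rise time, baseline
# counts, wave shape, leak/load magnitudes) is a representative default for
# Rhod-2 / Fluo-4 cardiac line scans, not a measured value.
wt_sham:
  kinetics:
    amplitude_dff0: 0.8
    rise_ms: 2.0
    tau_decay_ms: 30.03
    f0_counts: 500
    diastolic_dff0: 0.0
  wave_shape:
    velocity_mm_s: 2.0
    amplitude_dff0: 0.5
    extent_um: 120.0
    duration_ms: 20.0
    rise_ms: 3.0
    decay_ms: 12.0
  wave_rates:
    hz8: 1.99
    hz10: 4.84
    hz20: 7.59
  leak_dff0: 0.10
  load_dff0: 1.5
wt_alc:
  kinetics:
    amplitude_dff0: 0.8
    rise_ms: 2.0
    tau_decay_ms: 55.9
    f0_counts: 500
    diastolic_dff0: 0.05
  wave_shape:
    velocity_mm_s: 2.0
    amplitude_dff0: 0.5
    extent_um: 120.0
    duration_ms: 20.0
    rise_ms: 3.0
    decay_ms: 12.0
  wave_rates:
    hz8: 10.20
    hz10: 15.38
    hz20: 24.05
  leak_dff0: 0.25
  load_dff0: 2.0
jnk2dn_alc:
  kinetics:
    amplitude_dff0: 0.8
    rise_ms: 2.0
    tau_decay_ms: 30.03
    f0_counts: 500
    diastolic_dff0: 0.0
  wave_shape:
    velocity_mm_s: 2.0
    amplitude_dff0: 0.5
    extent_um: 120.0
    duration_ms: 20.0
    rise_ms: 3.0
    decay_ms: 12.0
  wave_rates:
    hz8: 2.71
    hz10: 3.11
    hz20: 7.34
  leak_dff0: 0.10
  load_dff0: 1.5
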