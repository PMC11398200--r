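# Scenario presets for the five therapeutic-exercise classes.
# Fields are arguments of exercise_scenario(); class motion mapping:
# LSA one scatterer; BSA two in-phase scatterers (both arms); SFU/SFD a
# receding/approaching linear drift superposed on the oscillation; BS two
# superposed oscillation frequencies (circular stroke).
#
# "easy": distinct oscillation frequency, scatterer count and pulse width
# per class at high SNR (constructed to be separable in descriptor space).
# "hard": shared pulse width, overlapping kinematics, strong noise.

easy:
  LSA:
    class_label: 1
    center_range_cm: 195
    osc_amplitude_cm: 12
    osc_freq_hz: 0.50
    pulse_width_bins: 1.0
    noise_sd: 50
  BSA:
    class_label: 2
    n_scatterers: 2
    center_range_cm: 191
    osc_amplitude_cm: 10
    osc_freq_hz: 0.65
    phase_offsets: [0.6, 0.6]
    scatterer_sep_cm: 4
    pulse_width_bins: 1.0
    noise_sd: 50
  SFU:
    class_label: 3
    center_range_cm: 190
    osc_amplitude_cm: 12
    osc_freq_hz: 0.45
    drift_cm_per_s: 1.2
    return_amplitude: 9500
    pulse_width_bins: 2.0
    noise_sd: 50
  SFD:
    class_label: 4
    center_range_cm: 197
    osc_amplitude_cm: 13
    osc_freq_hz: 0.55
    drift_cm_per_s: -1.2
    return_amplitude: 13000
    pulse_width_bins: 3.0
    noise_sd: 50
  BS:
    class_label: 5
    center_range_cm: 193
    osc_amplitude_cm: 8
    osc_freq_hz: 0.50
    osc_freq2_hz: 1.30
    osc_amplitude2_cm: 4
    return_amplitude: 7000
    pulse_width_bins: 1.5
    noise_sd: 50

hard:
  LSA:
    class_label: 1
    center_range_cm: 193
    osc_amplitude_cm: 12
    osc_freq_hz: 0.55
    pulse_width_bins: 1.2
    noise_sd: 500
    return_amplitude: 6000
  BSA:
    class_label: 2
    n_scatterers: 2
    center_range_cm: 190
    osc_amplitude_cm: 12
    osc_freq_hz: 0.55
    phase_offsets: [0.6, 0.6]
    scatterer_sep_cm: 5
    pulse_width_bins: 1.5
    noise_sd: 500
    return_amplitude: 6000
  SFU:
    class_label: 3
    center_range_cm: 191
    osc_amplitude_cm: 12
    osc_freq_hz: 0.55
    drift_cm_per_s: 0.8
    pulse_width_bins: 1.5
    noise_sd: 500
    return_amplitude: 6500
  SFD:
    class_label: 4
    center_range_cm: 196
    osc_amplitude_cm: 12
    osc_freq_hz: 0.55
    drift_cm_per_s: -0.8
    pulse_width_bins: 1.9
    noise_sd: 500
    return_amplitude: 7000
  BS:
    class_label: 5
    center_range_cm: 193
    osc_amplitude_cm: 9
    osc_freq_hz: 0.50
    osc_freq2_hz: 1.10
    osc_amplitude2_cm: 4
    pulse_width_bins: 1.5
    noise_sd: 500
    return_amplitude: 6000
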