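# Circadian extension: the core network of db_params.yaml plus an SCN cell
# group with an inherent 24-hour drive (high during the 12-hour light phase
# starting 06:00), 5-HT/ACh feedback from the sleep-wake network, and
# GABAergic feed-forward projections onto LC, DR, VLPO and R. Calibrated so
# that wake dominates the dark phase and NREM/REM the light phase.
# Provenance: sleepda in-house calibration v1; all values overridable.
version: 1
variant: fbfd
scn:
  F_max: 8.0
  alpha: 0.5
  beta: 0.5
  tau_F: 25
  gamma: 4.0
  tau_C: 25
  circ_amplitude: 1.0   # sinusoidal circadian drive, mean = circ_offset
  circ_offset: 0.0
  g_feedback: 0.2       # weight of (C_S + total ACh) input to the SCN
  g_scn_LC: -0.9        # GABAergic feed-forward projections
  g_scn_DR: -0.9
  g_scn_VLPO: -0.05
  g_scn_R: -0.5
  period_h: 24
  light_onset_h: 6      # light phase 06:00-18:00
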