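# Default parameter set for the 12-variable sleep-wake regulatory network
# (wake-active LC/DR, sleep-active VLPO, REM-active R, wake/REM-active WR,
# their transmitters, homeostatic drive h and thalamic input delta).
# Calibrated by the package authors to reproduce rat-like ultradian
# sleep-wake architecture: wake bouts of several minutes, NREM bouts of
# 1-4 minutes, REM bouts of about a minute terminated by brief arousals,
# and noise-driven brief awakenings. Provenance: sleepda in-house
# calibration v1 (see the methods vignette); all values overridable.
version: 1
variant: db
groups:
  lc:                 # noradrenergic locus coeruleus, wake-active
    F_max: 6.5        # Hz
    alpha: 0.7
    beta: 0.2
    tau_F: 25         # s
    gamma: 4.0        # NE release scale
    tau_C: 25         # s, NE clearance
  dr:                 # serotonergic dorsal raphe, wake-active
    F_max: 6.0
    alpha: 0.7
    beta: 0.2
    tau_F: 20
    gamma: 4.5
    tau_C: 20
  vlpo:               # GABAergic VLPO, NREM-active; threshold shifts with h
    F_max: 5.0
    alpha: 0.35
    beta: 0.8         # midpoint at h = 0; effective midpoint is beta - k*h
    k: 2.6
    tau_F: 10
    gamma: 4.0
    tau_C: 10
  r:                  # cholinergic LDT/PPT, REM-active
    F_max: 5.0
    alpha: 0.2
    beta: -0.45
    tau_F: 1
    gamma: 2.5
    tau_C: 10
  wr:                 # cholinergic LDT/PPT, wake/REM-active
    F_max: 5.0
    alpha: 0.25
    beta: -0.3
    tau_F: 10
    gamma: 2.5
    tau_C: 10
coupling:             # signed weights; transmitter_TARGET; D = thalamic input
  A_LC: 1.0
  G_LC: -1.2
  D_LC: 2.0
  A_DR: 0.85
  G_DR: -1.2
  D_DR: 2.0
  N_VLPO: -1.0
  S_VLPO: -1.0
  A_R: 0.8
  N_R: -2.0
  S_R: -2.0
  G_R: -0.3
  A_WR: 1.0
  G_WR: -2.0
homeostatic:
  h_max: 1.0
  theta: 2.0          # Hz, wake-activity threshold on F_LC
  tau_acc: 240        # s, accumulation during wake
  tau_diss: 400       # s, dissipation during sleep
noise:
  rate: 0.003         # Hz, Poisson impulse rate of thalamocortical input
  tau_delta: 10       # s, leaky-integrator decay
  impulse_amplitude: 1.0
a_scn: 0.0            # quasi-static additive drive (circadian-free filter use)
sov:
  rem_frac: 0.3       # REM when F_R >= rem_frac * F_max(R)
  wake_frac: 0.5      # else Wake when F_LC >= wake_frac * F_max(LC)
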