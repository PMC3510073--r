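---
title: "Methods: data assimilation for sleep-wake network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data assimilation for sleep-wake network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepda)
```

## The models

`sleepda` simulates a firing-rate model of the mammalian (rat-like)
sleep-wake regulatory network. Five neuronal populations interact through
the transmitters they release:

* **LC** (noradrenergic locus coeruleus) and **DR** (serotonergic dorsal
  raphe) — wake-active; their monoamines inhibit the sleep- and REM-active
  populations.
* **VLPO** (GABAergic ventrolateral preoptic nucleus) — NREM-active; its
  GABA inhibits everything wake- and REM-active. Mutual inhibition between
  VLPO and LC/DR forms the flip-flop switch that produces sharp sleep-wake
  transitions.
* **R** and **WR** (cholinergic LDT/PPT) — REM-active and wake/REM-active;
  both release ACh, and every ACh target sees the *sum* of the two pools,
  which is the main source of the REM group's poor observability (its
  output is symmetric with WR's).

Each population `X` has a firing rate obeying a first-order relaxation
`dF_X/dt = (F_inf(c_X) - F_X) / tau_X` toward a sigmoidal steady state

```
F_inf(c) = (F_max / 2) * (1 + tanh((c - beta) / alpha)),
```

where `c_X` is the signed, weighted sum of its input transmitter
concentrations. Each released concentration relaxes toward `tanh(F /
gamma)`. Two slow processes shape the architecture:

* the **homeostatic drive** `h` accumulates toward `h_max` (time constant
  `tau_acc`) while `F_LC` exceeds a threshold `theta` and dissipates
  (`tau_diss`) otherwise. It moves the VLPO's firing midpoint,
  `beta_VLPO(h) = beta - k h`, so sleep pressure progressively lowers the
  sleep switch's threshold;
* the **thalamic input** `delta`, a leaky integrator (decay `tau_delta`)
  driven by Poisson impulses at 0.003 Hz, feeds excitation into LC and DR
  and produces brief awakenings.

The circadian variant adds an SCN population whose input is a 24-h
sinusoidal drive (high during the 12-h light phase beginning 06:00; its
mean over a period equals the configured offset) plus feedback from 5-HT
and total ACh. The SCN's GABA projects feed-forward onto LC, DR, VLPO and
R. Because the strongest projections land on the wake-active populations,
wake dominates the dark phase and NREM/REM the light phase, as in nocturnal
rodents.

State of vigilance is scored by rank order with the REM-active rate
dominating: REM whenever `F_R >= 0.3 F_max(R)`; otherwise Wake when
`F_LC >= 0.5 F_max(LC)`, else NREM. The fractions are configurable
(`params$sov`); every analysis in the package scores truth and
reconstruction with the same rule, so results are self-consistent under any
reasonable choice.

### Parameter provenance and calibration

The shipped parameter files (`inst/extdata/*.yaml`) are an in-house
calibration, versioned and fully overridable. The circuit topology and
signs, the tanh sigmoid forms, the Poisson rate, and the integration scheme
are fixed by the model family; the numeric constants were chosen once so
that the simulator reproduces rat-like architecture: wake bouts of several
minutes, NREM bouts of one to a few minutes, REM bouts of about a minute
that end with a brief arousal (rising ACh re-excites LC, whose
norepinephrine shuts the REM group off), noise-driven brief awakenings, and
roughly 55/30/15 Wake/NREM/REM fractions. Identical-twin analyses are
parameter-set-agnostic by design: truth and filter share whatever set is
supplied.

One structural choice deserves a note: the VLPO midpoint is
`beta - k h` with a positive constant `beta`, not a pure `-k h`. With a
zero intercept the VLPO is half-active at zero input and zero sleep
pressure, so the switch can never disengage at low `h`; the positive
intercept makes wake the low-pressure attractor and gives clean bistable
cycling.

### Integration

Classical fixed-step RK4 at `dt = 0.5` s integrates the deterministic
vector field; Poisson impulse counts are drawn per step from R's RNG and
added to `delta` *between* RK4 steps, so the deterministic integrator keeps
its 4th order (verified empirically: measured convergence order > 3.7 on
switch-free arcs; the Heaviside in the `h` equation caps local accuracy in
the step containing a threshold crossing, which is why the order test runs
on a smooth stretch). Identical seed and configuration give bitwise
identical trajectories.

## The unscented Kalman filter

The filter propagates the symmetric 2n-point sigma set `x ± columns of
sqrt(n P)` with equal weights `1/(2n)` — no central point and no extra
scaling parameters, matching the unweighted forecast mean used throughout.
The square root is a Cholesky factor with escalating diagonal jitter
(1e-12 up to 1e-6) if the covariance has drifted off the SPD cone; the
covariance is re-symmetrized every step.

Each cycle: (i) propagate the sigma points one step through the
*deterministic* filter model (inside the filter `delta` decays without
impulses; its uncertainty comes entirely from its inflation entry);
(ii) forecast mean = point average, forecast covariance = point covariance
plus the diagonal inflation `Q`; (iii) correct with gain
`K = P_xy (P_yy + R)^-1`, where the observed-subspace covariances are taken
from the *inflated* forecast covariance. The last choice makes the
recursion collapse exactly to the classical Kalman filter on linear
dynamics (the package tests this to 1e-8 over 1000 steps) and makes the
inflation's gain-raising effect immediate as well as propagated; the
qualitative behavior — larger `Q_ii` biases the correction toward the
measurements — is unchanged.

Default inflation is `Q_ii = 1e-4 * var_i`, with `var_i` the variance of
variable `i` over a reference simulation of the same model. The multiplier
is exposed (`default_q(multiplier = )`); 1e-4 keeps the filter trusting its
model except where the tuning procedure below says otherwise. A flat
`delta` reference (noise switched off) gets an impulse-amplitude-squared
floor so its entry stays usable.

Initial conditions are deliberately arbitrary (`default_init()`), so every
reconstruction has a transient during which it is poor; all metrics discard
a transient (1 h by default) before scoring.

## Observability: NMSE and the EOC

Reconstruction fidelity of variable `i` is the normalized mean square error
`NMSE_i = mean((rec_i - truth_i)^2) / var(truth_i)` — 0 when perfect, near
1 when the reconstruction is no better than the truth's mean. For ranking
we use the bounded, regularized inverse

```
EOC = 1 / (1 + NMSE)  in (0, 1],  1 = perfect.
```

This form has every property required of a fidelity score (1 at zero
error, bounded, strictly decreasing in error); any strictly monotone
regularization would produce the same rankings, which is all the tuning
procedure consumes.

`eoc_matrix()` runs one identical-twin assimilation per candidate measured
variable — truth generated from the filter model itself, 4% variance
observation noise, 12 h scored after a 1-h transient — and tabulates
`EOC[i, j]` = fidelity of `i` when `j` is measured. By default the
thalamic noise process is switched off (truth deterministic, `delta`
dropped from the table) so the structural patterns are not washed out by
the one variable that is purely noise-driven; `include_delta = TRUE`
restores the full table.

### Inflation tuning

`optimize_q()` uses the ranked partial observability as a search guide:
compute the EOC matrix; find the variable with the lowest *off-diagonal*
mean row or column (the diagonal's self-reconstruction would mask poor
columns); a poor column means "measuring this variable tells us little" —
raise its inflation entry so measurements are favored; a poor row means
"this variable is poorly reconstructed from others" — lower its entry so
the model forecast is favored. The selected entry is swept over `{0} ∪`
a log grid (7 points per decade, 5 decades) capped at the square of the
variable's full range, scoring each candidate by the mean EOC of the
designated measurement column, and the best value is kept only if that mean
improves. With the thalamic process active the first variable selected is
`delta` with direction "increase" — its dynamics receive no input from the
network, so only measurement trust can recover it.

## Multiple-shooting parameter estimation

Estimation alternates between state reconstruction and parameter update.
Over each window (default 1800 s, longer than a sleep-wake cycle; 80%
overlap, i.e. 360-s updates) the reconstruction is re-anchored every 120 s
and the deterministic model is integrated forward from each anchor with a
candidate parameter value; the cost is the window-averaged squared
divergence from the reconstruction, restricted to the measured variables
and weighted by `1/sd` of each measured variable over the window. The
estimate moves to the grid argmin, capped at 10% relative change per
window. The candidate grid spans ±30% of the current estimate and is
refined (×0.5, floor 2%) when the argmin is interior on consecutive
windows; grids and caps use an absolute scale floor (`min_scale`, default
0.05) so estimates passing through zero keep a usable search range. When
*tracking* a drifting parameter, set `min_scale` to the expected magnitude
of the parameter's swing: the step cap is `max_step_frac * scale` per
window, so a floor far below the swing rate-limits the tracker and lags
fast transitions asymmetrically (the reproduction script uses 0.5 for the
SCN drive, whose swing is about one concentration unit). The
first `burn_in_s` (default 1800 s) of assimilation is excluded from
estimation because the filter's own convergence transient would otherwise
bias the cost. Convergence is declared after five consecutive windows with
relative change below 1e-3.

`track_parameter()` is the same loop without a convergence stop: one
estimate per overlapping window, anchored at the window center,
inherently smoothed at the half-hour scale. Its flagship use is
assimilating circadian (FBFD) truth with the circadian-free core filter
while tracking a single additive drive `a_scn` injected into the LC, DR,
VLPO and R inputs — the four sites the SCN's GABA reaches in the full
model. The tracked series follows the mean feed-forward input and its
dominant period recovers the 24-h cycle, even though the filter model
contains no circadian machinery.

`dominant_period()` is a least-squares periodogram (sinusoid regression on
a fine period grid after linear detrending) rather than a raw FFT
periodogram: a two-day tracking run minus a half-day transient spans only
~1.5 circadian cycles, where the FFT peak is badly biased by leakage but
the least-squares peak is not.

## Hypnogram assimilation

A hypnogram (Wake/NREM/REM at the filter step) is translated into
pseudo-observations by a state-conditioned map built from a scored
simulation of the filter model: within each state, the state-conditioned
*median* of each mapped variable (default `F_LC`, `F_VLPO`, `F_R` — the
three rates that define the scoring) is the "observation" and the
state-conditioned variance the measurement noise, so `R` is time-varying
and changes exactly at the hypnogram's transitions. Medians are used
because the conditional distributions are strongly skewed; variances are
floored at 1e-6 times the squared range to avoid singular corrections when
a conditional distribution is nearly degenerate. The map is built from one
long seeded run (metadata records duration and seed); rebuilding from a
different seed moves the medians by less than the conditional spread.

The UKF then reconstructs the full state, including never-observed
variables such as `h`. Details the scoring cannot resolve — brief
awakenings, individual NREM transitions — are not recovered, and no such
guarantee is claimed; the package's reference comparison is the *median
map itself* used as a reconstruction, which the filter must beat for
unobserved variables.

## What the generator does and does not emulate

All validation is by identical-twin design: the same model family
generates truth and filters it. This validates the machinery —
reconstruction, ranking, tuning, estimation — under exactly known truth.
It does not validate the biology: there is no EEG synthesis, no real
polysomnographic staging, no sensor model, and observation noise is
i.i.d. Gaussian at a fixed fraction (4%) of signal variance. Passing tests
therefore demonstrate that hidden-variable recovery and parameter
estimation work when the model is (approximately) right, including the
deliberately misspecified circadian-free filter; they say nothing about
fitting real recordings.

## Numerical choices and problem sizes

* Cholesky jitter 1e-12 → 1e-6 (×100 steps); covariance symmetrization
  every filter step; innovation solves via dense `solve` with an explicit
  singularity error.
* Observations containing `NA` trigger predict-only steps; non-finite
  simulator states abort with the step index.
* Test-suite problem sizes: model properties on 30-min to 48-h runs;
  filter checks on 1-h twins; observability on 1.5-h (unit) and 12-h
  (end-to-end) records; estimation on 4-8-h records; tracking on 48-h
  records in the reproduction script. These lengths were chosen as the
  shortest records on which each behavior is stable.
* All randomness flows through R's RNG under explicit seeds; compiled code
  is purely deterministic.

## Limitations

* The parameter set is a calibrated representative of the model family,
  not a fit to any animal; quantitative bout statistics should not be
  read as predictions.
* Single-parameter estimation only; sequential loops can handle several
  parameters but no joint optimization is attempted, and identifiability
  is not characterized — non-convergence is reported rather than guessed.
* The filter assumes additive Gaussian observation noise and a diagonal
  inflation; no square-root or smoothing variants are provided.
* Augmented-state (dual) estimation is deliberately absent: for this
  model family the windowed shooting approach is the stable alternative.
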