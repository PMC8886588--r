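---
title: "Methods: the sleep-circadian model, its fitting, and light-intervention design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sleep-circadian model, its fitting, and light-intervention design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circalight)
```

## The scientific problem

Sleep timing is the joint product of three interacting processes: a
homeostatic pressure that builds during wake and dissipates during
sleep, a circadian pacemaker that gates when wake is easy or hard to
sustain, and the light exposure pattern that entrains the pacemaker to
the 24-h day.  When multi-week actigraphy shows sleep that is long,
irregular, or drifting later each day, the cause could be intrinsic
(an unusually long circadian period, a reduced drive for wakefulness)
or environmental (too little daytime light, too much evening light).
These explanations call for different interventions, and they cannot be
separated by descriptive statistics alone.  `circalight` separates them
by fitting a physiological model to each person's own recorded light
and sleep timing, and then uses the fitted model as a sandbox in which
candidate light environments can be tried before being recommended.

## The model

The simulation core couples three well-established components.

**Sleep-wake switch.**  Two neuronal populations inhibit each other: a
sleep-active population with mean voltage $V_v$ and a wake-active
population with mean voltage $V_m$, each firing at
$Q_i = Q_{\max} / (1 + \exp(-(V_i - \theta)/\sigma))$:

$$\tau_v \dot V_v = \nu_{vm} Q_m + D_v - V_v, \qquad
  \tau_m \dot V_m = \nu_{mv} Q_v + A_m - V_m,$$

with the drive to the sleep-active population

$$D_v = A_v - \Delta_D + \nu_{vh} H + \nu_{vc} C(x, x_c).$$

The mutual inhibition makes the pair bistable: the system is either
firmly awake or firmly asleep, and transitions are fast flips.  Wake is
read out directly from the flip-flop ($Q_m > Q_v$, equivalently
$V_m > V_v$); the bistability itself provides hysteresis, so no extra
threshold parameter exists.  $\Delta_D$ is the *wake-drive deviation*,
one of the two fitted parameters: positive values mean more drive for
wakefulness and shorter sleep, negative values longer sleep.  It is
subtracted inside $D_v$ so that its sign convention reads naturally at
the behavioral level.

**Homeostat.**  $\chi \dot H = \mu Q_m - H$: pressure charges while the
wake population fires and decays otherwise.

**Pacemaker and light.**  A van der Pol-type limit cycle $(x, x_c)$
with intrinsic period $\tau_c$ (the second fitted parameter) receives a
photic drive $B = G\,\alpha(I)\,(1-n)(1-bx)(1-bx_c)$ produced by a
saturating phototransduction pool $n$,
$\dot n = 60[\alpha(I)(1-n) - \beta n]$ with
$\alpha(I) = \alpha_0 (I/I_0)^p$.  Crucially, $I$ is the light at the
eye: the available environmental light when the model is awake, and 0
when it is asleep (eyes closed).  This self-selection of light is what
couples behavior back onto the clock and makes reduced light exposure
able to produce non-24-h rhythms in a person with an ordinary
circadian period.

The circadian drive entering the switch is
$C = \tfrac12\!\left(1 + x\cos\phi - x_c\sin\phi\right)$ with
$\phi = \phi_C \pi/12$.  Published variants of this model family differ
in how $(x, x_c)$ maps to the drive; the form above was chosen because
it is the simplest one with an explicit phase degree of freedom.  Its
per-cycle minimum is the *circadian wake-propensity minimum* (CWPM),
the model's phase marker, which falls in the late biological night.

### Fixed parameters and their calibration

The fixed neuronal constants ($Q_{\max} = 100\,\mathrm{s^{-1}}$,
$\theta = 10$ mV, $\sigma = 3$ mV, $\tau_v = \tau_m = 10$ s,
$\nu_{vm} = -2.1$, $\nu_{mv} = -1.8$ mV s, $\nu_{vh} = 1$, $\chi = 45$ h,
$\mu = 4.4$, $A_m = 1.3$ mV, $\nu_{vc} = -2.9$ mV) and photic constants
($\alpha_0 = 0.05$, $\beta = 0.0075$ min$^{-1}$, $I_0 = 9500$ lux,
$p = 0.5$, $G = 33.75$, $k = 0.55$, $b = 0.4$, $q = 1/3$,
$\mu_p = 0.13$) are standard values for this model family.  Three
quantities were calibrated once, by construction, against the model's
own defining invariants, and are not data-fitted:

* $A_v = -11$ mV sets the operating point so that the default
  physiology ($\Delta_D = 0$) under a regular bright routine sleeps
  once per day for about 8 h;
* $\phi_C = 2$ h places that default sleep episode at a realistic
  clock position (onset near 23:00, offset near 07:15) under the bright
  reference routine;
* $f = 0.99737$ is the period-correction factor defined by the
  requirement that the *free-running* limit-cycle period in darkness
  equals $\tau_c$ exactly; it was measured on long dark simulations and
  holds to better than 0.006 h across the physiological range of
  $\tau_c$.  (The widely quoted value 0.99669 belongs to a slightly
  different van der Pol variant; with our drive coupling and solver the
  definitional calibration lands at 0.99737.)

### Numerical integration

Light is piecewise-constant per recording epoch (120 s by default) and
gated by the wake state, so the integrator restarts at every epoch
boundary and never steps across a light change.  Within an epoch an
embedded Cash-Karp Runge-Kutta 4(5) pair with adaptive step control
(`rtol = 1e-6`, `atol = 1e-8`) integrates the system; the flip-flop
transitions are the only stiff phases and the error controller shrinks
the step to well below a second there, while cruising at tens of
seconds elsewhere.  Wake-sleep transition times are located by linear
interpolation of $V_m - V_v$ inside the accepted step, which the small
step size at transitions makes accurate to below a second.  Halving the
tolerances moves episode onsets by less than a minute (tested).  A
compiled core makes a 42-day simulation take on the order of 100 ms,
which is what renders grid-based fitting and entrainment maps
practical.

All simulations start from one canonical initial state: the entrained
steady state of the default physiology under the bright reference
routine, computed once per session and cached.  A post-transient window
(14 days by default) absorbs the adjustment to other parameter values;
entrainment classification uses a longer transient (the final 28 days
of a 70-day simulation) because phase convergence near the entrainment
boundary is slow.

## Rhythm metrics

**Folding.**  The dominant period of a recording channel is found by
folding the data at candidate periods spaced one epoch apart (2 min)
and computing, at each candidate, the pooled within-phase-bin sum of
squares divided by the total sum of squares.  This *residual variance*
is a unit-free fraction in $[0,1]$, invariant under affine transforms
of the signal, so the argmin does not depend on whether counts are raw
or rescaled.  Ties resolve to the smallest period.  The default scan
range 20-28 h covers every free-running period the fitting stage can
produce.  A `depth` diagnostic (minimum over median residual variance)
distinguishes a real rhythm (depth well below 1) from the flat scan of
noise.

**Circular statistics.**  Sleep onset, offset and mid-sleep are clock
times; for irregular sleepers they spread around the full clock face,
so means and variances are computed on the circle (mean resultant
vector; circular SD $(24/2\pi)\sqrt{-2\ln R}$).  A zero resultant
yields a flagged, not an error, result.

**Light metrics.**  Per calendar day: hours with lux strictly above
500, mean lux, and mean $\log(\mathrm{lux}+1)$; the median across days
of each is reported.  Days with under 90% usable epochs are dropped;
masked epochs are excluded rather than zero-filled because zero lux is
meaningful darkness.  The mean-within-day / median-across-days reading
was chosen for all three measures so they share one structure.

## Fitting the two individual parameters

For each participant the model is driven by their own recorded lux
series (*imposed* mode; observed light is still zeroed while the
*model* sleeps, since a sleeping person's eyes are closed whatever the
meter recorded; missing epochs are imputed by the mean lux at the same
clock time on other days).  The objective is

$$J(\tau_c, \Delta_D) = d_{\mathrm{circ}}\big(\overline{\mathrm{mid}}_{\mathrm{model}},
 \overline{\mathrm{mid}}_{\mathrm{obs}}\big)^2 +
 \big(\bar d_{\mathrm{model}} - \bar d_{\mathrm{obs}}\big)^2$$

— squared circular distance between circular-mean mid-sleep times plus
squared difference of mean durations, both in hours with equal weights,
evaluated over the same post-transient window for model and data.
Mid-sleep plus duration carries the same information as onset and
offset means but is better conditioned on the circle.

The optimizer is deterministic: a coarse grid (0.25 h in $\tau_c$
$\times$ 1.0 drive units), a finer local grid (0.1 $\times$ 0.25)
around each promising coarse region, then Nelder-Mead polish.  A single
fit evaluates the objective a few hundred times and takes roughly
10-20 s.

**Aliasing and its resolution.**  For a drifting (non-24-h) record the
circular mean mid-sleep over a finite window is a many-to-one function
of the drift rate: intrinsic periods about 1.7 h apart can park the
mean at the same clock position, so the objective can have two deep
basins and noise can make the wrong one marginally deeper.  The mean
discards exactly one quantity that separates the basins: the drift rate
itself.  The fit therefore clusters near-optimal coarse-grid points
into basins along $\tau_c$, polishes each, and among basins whose
objective is within a tolerance of the best selects the one whose
simulated sleep-onset period is closest to the observed onset period
(slope of onset time on episode index).  More than one near-optimal
basin raises a `multimodal` flag; estimates at the search-box edge
raise `boundary`.  On 20 synthetic participants with default noise this
recovers $\tau_c$ within 6 min and $\Delta_D$ within 0.2 for at least
90% (tested).

**Acrophase validation.**  The melatonin (aMT6s) acrophase is predicted
as CWPM + 0.5 h; the offset was calibrated once so the mean residual on
synthetic records is zero, and `calibrateAcrophaseOffset()` can
recalibrate it.  Acrophase is deliberately *never* part of the fitting
objective — it stays an out-of-sample check
(`validateAcrophase()`: Fisher-Lee circular correlation, RMSE, slope).

## Intervention design

An `AvailableLightProfile` is a raised cosine on an evening floor:
light climbs from `LEve` at 07:00 to `LDay` at 13:00 and returns to
`LEve` by 21:00 (all five numbers configurable; the cosine segments
already fix the transition smoothness, so no separate smoothness
parameter exists).  `classifyEntrainment()` simulates self-selected
exposure and calls the physiology entrained when the sleep-onset period
over the final 28 days is within 2 min of 24 h; the mean sleep offset
is reported only where entrained, because a drifting offset has no
meaningful mean.  `entrainmentMap()` evaluates a (day, evening)
intensity grid — the default 67 x 67 log-spaced grid over
[10, 2000] x [0.5, 100] lux makes about 4500 simulations; tests and the
examples use coarser grids.  `designIntervention()` filters a map to
the entrained points whose mean offset is within tolerance of a target
wake time, sorted by total light change from the habitual profile.
Typically the solution set straddles qualitatively different
strategies (brighten the day vs. dim the evening) that produce the same
sleep timing, which is what allows the choice to follow personal
preference.

## The synthetic cohort generator

No public dataset accompanies this problem, so the generator is a
first-class module: it produces complete participant datasets with
known ground truth, and every pipeline stage is validated against it.

Defaults emulate a six-week two-group study: 20 cases with reduced wake
drive (mean $-1.82$, SD 1.62) in a dim environment (peak 160 lux,
30 lux evenings) and 21 controls (drive mean 0.66, SD 0.62) in a bright
one (peak 800 lux, 10 lux evenings); intrinsic periods come from nearly
identical distributions in both groups (24:14 $\pm$ 0:12 vs.
24:13 $\pm$ 0:10 h:m, truncated to [23.6, 25.4] h).  Group contrasts in
the generated phenotypes therefore arise from drive and light, never
from the period distribution — which is precisely the contrast the
analysis pipeline is meant to detect.

Observation noise, chosen as plausible magnitudes and all configurable:
per-day behavioral shift of the whole light profile (SD 0.5 h), diary
reporting jitter (SD 15 min per onset/offset), multiplicative
log-normal lux noise ($\sigma = 0.3$) over the light the model actually
received, a 0.1 lux sensor floor during sleep, negative-binomial
activity counts (means 250 awake / 10 asleep, dispersion 1.5), and
weekly acrophases built as CWPM + 0.5 h + Gaussian noise (SD 0.5 h)
inside 48-h collection windows.  The first 14 simulated days are
discarded so recordings begin in steady state.  All draws descend
deterministically from the seed; equal seeds give bit-identical
datasets.

What the generator does *not* emulate: device artifacts (off-wrist
gaps, spectral response), naps and fragmented sleep beyond what the
flip-flop produces, day-to-day variability of the physiology itself
(variability enters only through light and reporting noise), and
raw melatonin concentration curves (acrophase times only).  Passing
tests on synthetic data therefore demonstrate internal consistency of
model, generator and estimators — parameter recovery, seasonal
light-only contrasts, group phenotypes — not external validity on real
recordings.

## Problem sizes used in tests and the acceptance script

Simulations are sized to keep the full suite within a desktop-scale
budget: recovery studies use 20 participants x 42 days (the
acceptance script uses 8), entrainment maps 15 x 15 or smaller grids at
70 days per point, free-running checks 60-day dark runs.  These sizes
were chosen so that each check's sampling error is comfortably below
the tolerance it asserts.

## Known limitations

* The two fitted parameters absorb whatever the fixed physiology cannot
  represent; fits are conditional on the literature-standard constants.
* The entrainment classification near the boundary depends on the
  transient allowed; very slowly converging points close to the
  boundary can classify either way within the 2-min tolerance.
* Sleep architecture (REM/NREM), napping, and acute alerting effects of
  light are outside the model's scope.
* All times are naive local times on a DST-free calendar; civil-time
  discontinuities must be resolved upstream.
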