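---
title: "Metabolic power from GPS kinematics: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic power from GPS kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metpowr)
```

## The model

Team-sport locomotion is dominated by accelerations and decelerations, which
speed-based load metrics cannot price. The equivalent-slope framework maps
accelerated level running onto uphill running: at forward acceleration $a$,
the runner behaves as if climbing a gradient $ES = a/g$ while supporting an
apparent body mass inflated by $EM = \sqrt{ES^2 + 1}$. Instantaneous
metabolic power per kilogram is then

$$P = C(ES)\; EM \; v,$$

where $C$ is the energy cost of running at that gradient (J kg⁻¹ m⁻¹) and
$v$ the speed. `metpowr` ships two cost models:

* **new** (default): a quartic in $ES$ with flat-running constant
  4.66 J kg⁻¹ m⁻¹, measured on elite soccer players running on natural
  grass in soccer shoes. The quartic form removes the negative dip that the
  classical quintic develops beyond about −45 % gradient, so hard
  decelerations always cost positive energy. No terrain factor is applied:
  the constant was measured on grass directly.
* **original**: the classical quintic treadmill model (flat constant
  3.6 J kg⁻¹ m⁻¹) multiplied by a terrain factor $K_T = 1.29$ for grass.

At zero slope the two differ by under 0.5 % (4.66 vs 4.644); they diverge
with $|ES|$. The gradient argument is the dimensionless fraction (0.45, not
45): only on that scale do the printed coefficients produce physiological
costs. Both polynomials were fitted over $ES \in [-0.45, 0.45]$; outside
that range the package extrapolates the polynomial as-is but flags the
samples (`es_extrapolated`), and treats $|ES| > 4$ as sensor artefacts.
$g$ is fixed at 9.81 m s⁻².

## GPS processing

The processing chain follows field practice for 10 Hz receivers: the trace
is synchronised at the first sample moving above 0 m s⁻¹ (to align with
breath-by-breath output), fix-quality filtered (HDOP ≤ 2, ≥ 6 satellites;
isolated bad runs under 0.5 s are linearly interpolated, longer runs are
dropped and left as flagged gaps — never fabricated), smoothed, and
differentiated.

Smoothing defaults to a *non-overlapping pairwise mean*, reducing 10 Hz to
5 Hz. This reads the recommended "reduction of the speed data at 5 Hz" as a
rate reduction; it conserves displacement exactly under the rectangle rule.
A sliding 3-sample mean that keeps the 10 Hz grid is available via
`smooth_speed(method = "rolling")`.

Acceleration is a central finite difference over a nominal window of 0.3 s
(0.2 s is the common alternative), rounded to a symmetric whole number of
sample intervals — an off-centre difference phase-shifts the acceleration
against the speed it multiplies, which biases power at transitions. On the
5 Hz grid the effective window is therefore 0.4 s.

Heading comes from position bearings on the smoothed grid (undefined and
flagged when the displacement is below 0.2 m); Doppler course is used only
when positions are absent.

## Direct calorimetry

The reference ("gold standard") side converts gas exchange into energy with
a fixed equivalent of 20.9 J per mL O₂ (non-protein RER 0.96; no
RER-dependent adjustment is attempted because the protocol fixes it).
Breath data are averaged over 1-min bins; steady state is the mean of the
last 3 min of a constant-speed run; the linear cost is
$C_r = \dot{V}O_{2,net}/v$.

Session energy above rest is partitioned as
$EE = Aer + AnAl + AnL$:

* $Aer$: trapezoidal integral of net V̇O₂ over exercise (per-sample
  negative net values clipped at zero);
* $AnAl$: the fast (phosphocreatine) oxygen debt from the first 6 min of
  recovery. The estimator subtracts a slow-component baseline — the
  time-weighted mean of net V̇O₂ over the 4th–6th minute, times 6 min —
  from the total 0–6 min net integral, floored at zero. The window is read
  as the 4th, 5th and 6th minutes, i.e. 180–360 s of recovery. A
  mono-exponential fit ($A e^{-t/\tau}$, debt $A\tau$) is available as
  `alactic_debt(method = "exponential")`; neither estimator is canonical,
  so both are exposed.
* $AnL$: net blood-lactate accumulation × 3 mL O₂ kg⁻¹ mM⁻¹ × 20.9 J mL⁻¹.

Then $C = EE/d$ and $P_{\dot VO_2} = C \cdot d / t$. Resting V̇O₂ uses the
measured pre-exercise value when present, else 3.5 mL kg⁻¹ min⁻¹. Absolute
(mL min⁻¹) readings require an explicit body mass; units are never guessed.

## Method comparison

Calibration of the GPS estimate against the direct measure uses ordinary
least products (geometric-mean) regression: slope
$\mathrm{sign}(r)\,s_y/s_x$ (proportional bias), intercept
$\bar y - b\bar x$ (fixed bias). Confidence intervals are percentile
bootstrap over pair resamples (2000 resamples, seeded — the variant is a
package choice; the method family only prescribes "bootstrapping").
Prediction intervals adapt the classical OLS form to OLP residuals with
$n-2$ degrees of freedom:
$\hat y \pm t_{0.975,\,n-2}\, s\sqrt{1 + 1/n + (x_0-\bar x)^2/SS_x}$.
Heteroscedasticity is summarised by a Breusch–Pagan-type statistic
($n R^2$ of squared residuals on $x$), reported but never gating.
The repeated-measures ANOVA applies Greenhouse–Geisser correction when
Mauchly's test rejects sphericity, with Bonferroni-adjusted paired t-tests
post hoc.

One caution established by Monte-Carlo work during development: the OLP
slope estimates $\sqrt{\beta^2 + \sigma^2/\sigma_x^2}$, so it is inflated
when the reference spread $\sigma_x$ is small relative to the residual
noise. The parameter-recovery tests therefore use a generator with
$x \sim N(15.5, 6^2)$ W kg⁻¹ — the spread of per-bout metabolic power
across players and bouts — and noise sd 0.7 W kg⁻¹, for which the
inflation is within the stated tolerances. The bootstrap-coverage test
targets the *population OLP functional* of that generator
($\sqrt{\beta^2\sigma_x^2 + \sigma^2}/\sigma_x$), not the nominal $\beta$.

## The circuit simulator

`simulate_circuit()` emulates a soccer-specific intermittent protocol: four
phases per ~1-min lap — a maximal 21.2 m sprint triangle with two >60°
direction changes, 40 m of linear striding, a 28 m slalom, and a 20 + 20 m
shuttle — repeated for 8 mirrored laps, with ~25 s of recovery per lap
fractioned into breaks shorter than 10 s. The nominal phase intensities
(14.4 and 10.1 km h⁻¹) are *phase-average* speeds (marked distance over
nominal time, from a standing start to a full stop), so the cruise portions
run faster (4.8, 3.3 and 5.4 m s⁻¹); this is what makes the phases fit
their nominal ~10 s slots.

Trajectory dynamics are generated by a point-mass integrator:
acceleration is limited by the speed-dependent maximum
$a_{max}(v) = 5.91 - 0.18\,v\;[\mathrm{km\,h^{-1}}]$ m s⁻², braking
magnitude scales with the speed at braking onset (0.6 v, clamped to
1–4 m s⁻²: nobody brakes at 4 m s⁻² out of a walk), targets are approached
with an exponential ease-in, and all acceleration changes are jerk-limited
(8 m s⁻³) — force application is continuous in real running, and an
infinitely crisp profile would be unmeasurable by any finite-window
processing. The resulting speed profile is additionally low-passed over
0.31 s before it becomes ground truth. Corners sharper than 150° force a
stop; gentler turns are taken at a reduced corner speed. Short
repositioning walks (7 + 6 + 7 m per lap at 1.4 m s⁻¹) inside the recovery
breaks carry the player between phase start points; they reproduce the
distance a GPS actually accrues between marked phases (total ≈ 1190 m per
session, against ~1030 m of marked activity alone).

The GPS view adds independent Gaussian speed noise (default sd
0.1 m s⁻¹) and realistic fix-quality fields (HDOP ≈ 1.0 ± 0.1, ~9
satellites); no autocorrelated error model is attempted, which is the main
respect in which the synthetic noise is kinder than real multipath error.
Ground truth stays noise-free.

### Oxygen-uptake response

V̇O₂ relaxes toward a target with first-order kinetics (τ_on = 25 s up,
τ_off = 30 s down). The target is demand plus a repayment drive: demand not
met aerobically accrues as oxygen deficit in two pools. A fraction of the
demand above V̇O₂max (0.003 mM per J kg⁻¹ via the lactate equivalents)
accrues as *lactic* energy — measured afterwards as blood lactate, repaid
only slowly. The remainder accrues as *fast (phosphocreatine) debt*, which
drives extra uptake at `debt·60/τ_PCr` (τ_PCr = 100 s) during the
low-intensity breaks — this is why the simulated exercise V̇O₂ settles
near 70–73 % of V̇O₂max, as observed for this kind of protocol, rather
than at the much lower capped-demand average.

Recovery is constructed to be exactly consistent with the bookkeeping: a
fast exponential whose time constant is *derived* from the outstanding
fast debt and the end-exercise amplitude (so repayment is exact and uptake
continuous), riding on a small near-constant slow component tied to the
lactic pool (τ_slow = 1800 s) — precisely the background the
4th–6th-minute baseline estimator is designed to remove. Energy is
conserved by construction: demand energy = aerobic supply + deficit, and
deficit = alactic + lactic.

Default physiology (mass 76.5 kg, V̇O₂max 61.1 mL kg⁻¹ min⁻¹, rest
3.5 mL kg⁻¹ min⁻¹) matches the population that performs this protocol.
With these defaults the simulator lands on a mean circuit power of
~14.8 W kg⁻¹ over ~1190 m in ~490 s, a session cost of ~6.1 J kg⁻¹ m⁻¹
(~30–38 % above the flat 4.66), exercise V̇O₂ ≈ 69 % of maximum and a net
lactate rise of ~5 mM.

### What passing tests do and do not show

The round-trip tests show that the estimators are mutually consistent with
the simulator's energy accounting at the stated sampling rates — not that
the model is unbiased on real athletes. In particular: the simulator's
lactate is a deterministic function of supra-maximal demand (real lactate
kinetics include production below V̇O₂max and clearance during exercise);
the GPS noise is white; and the jerk-limited trajectories are smoother
than the most violent real decelerations, for which any 5 Hz pipeline
underestimates power. The noise-free recovery property (indirect mean
power within 2 % of ground truth) quantifies the smoothing/differencing
loss of the default pipeline on resolvable movement; the residual −1.5 %
is a genuine, known bias of finite-window processing, not an error in the
cost model.

## Numerical choices and degenerate inputs

* Simulation integrates at 10 ms; the breath model at 100 ms (explicit
  Euler; time constants ≥ 25 s make this stable and accurate).
* Polynomials are evaluated by Horner's scheme.
* The acceleration window is rounded to a symmetric number of sample
  intervals; edges use one-sided differences.
* All-zero-speed traces, empty phases, exercise shorter than 4 min,
  recovery shorter than 6 min, zero variance in either calibration arm and
  unbalanced ANOVA cells are hard errors, never silently repaired.
* Bout counting requires ≥ 0.6 s (three 5 Hz samples) above threshold, to
  suppress single-sample noise. Direction-change detection accumulates
  wrapped heading change within a 0.5 s window, gated at 1 m s⁻¹, with
  events separated by at least one window; the thresholds make noise-free
  geometric fixtures exact and are configurable.
* The "endurance speed" band for the `v > ES` time fraction has no
  standard definition; the package uses a configurable 16 km h⁻¹ default
  and labels it as an assumption.
* Seeds: every stochastic routine (simulator noise, bootstrap) takes an
  explicit seed; seeded runs are byte-identical.

## Problem sizes

The test suite runs one cached noise-free circuit simulation (~490 s of
simulated exercise, integrated at 10 ms), one noisy session, 500-replicate
Monte-Carlo parameter recovery (n = 20 pairs each) and a 500-replicate
bootstrap-coverage study (2000 resamples each); the whole suite completes
in well under a minute on one core.

## Known limitations

* The cost polynomial is applied per sample with no memory: the metabolic
  cost of a change of direction beyond its acceleration content, impacts
  and non-locomotor work are not priced (a known limitation of the whole
  framework, and the reason direct power slightly exceeds GPS power on
  protocols with many turns).
* Walking receives the running cost model; a dedicated walking-cost branch
  is deliberately out of scope.
* The equivalent-slope update for very steep equivalent gradients and
  accelerometer-based "muscle power" extensions are out of scope.
* Positional (lat/lon) noise is optional and independent of speed noise;
  no Kalman fusion is attempted.
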