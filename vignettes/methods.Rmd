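---
title: "Time-compensated celestial compass models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-compensated celestial compass models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(suncompass)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, the numerical choices,
and the places where the design was genuinely open and a decision had to
be made. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The problem and the models

A sun compass gives an egocentric bearing to the sun. To use it as a
geocentric compass, the animal must subtract the sun's current azimuth —
which changes nonlinearly over the day and with season and latitude. The
package implements three compensation schemes, all expressed as the signal
carried by a pair of clock neurons (`DN1pB`) that multiplicatively gate
the compass pathway:

* **No compensation** — the ring neurons receive the sun encoding
  directly; the decoded heading drifts with the sun.
* **Hour-angle model** — the clock encodes
  $\omega(t) = (t_z - T_L/2)\cdot 15^\circ/\mathrm{h}$, the earth's
  rotation recentred on solar noon. Variants: clockwise (northern
  hemisphere), counter-clockwise (southern; north component negated), and
  equatorial (north component zero).
* **Complete model** — adds an annual oscillation for the solar
  declination and a latitude estimate from the geomagnetic inclination:
  $\alpha_E = \delta_Q\,\omega_E$,
  $\alpha_N = \phi_Q\,\delta_N + \phi_N\,\delta_Q\,\omega_N$. The sign of
  $\phi_N$ alone flips the predicted rotation across the equator.

Assumptions inherited from the modelled biology: the sunrise time is known
exactly (zeitgeber reset), the sun's azimuth is available as a perfect
angular observation before noise is added (no polarisation optics are
modelled), and the magnetic inclination follows an ideal dipole,
$\mu = \arctan(-2\tan\phi)$, whose inversion
$\phi = -\arctan(\tfrac12\tan\mu)$ is exact on $(-89^\circ, 89^\circ)$.

The compass circuit is the trigonometric identity
$\sin\alpha\sin(\alpha'-\phi^n) + \cos\alpha\cos(\alpha'-\phi^n)
= \cos(\alpha-\alpha'+\phi^n)$ realised by three populations (MeTu2a/b
sinusoids over a 16-neuron ring of preferred angles $n\cdot22.5^\circ$,
TuBu1a/b multiplicative gating, ER4m summation). The test suite verifies
the identity end-to-end to $10^{-12}$ over $10^4$ random configurations,
and verifies that a homogeneous phase offset applied jointly to the
spatial sinusoids and the clock phase leaves the ring output unchanged —
which licenses the fixed readout convention described in §4.

The central complex is reduced to complex vectors: EPG (unit heading
estimate), PFN ($z_{EPG} v$), memory ($\tau_M\,\dot z_M = z_{PFN}$,
$\tau_M = 40$ km), FC2 (normalised $z_G - z_M$), and the PFL3 steering
pair whose magnitude difference, divided by four, is the turn rate.
Direct evaluation shows the steering readout is zero at zero error *and*
at $180^\circ$ error (an unstable symmetric fixed point), with its
maximum at an intermediate angle — noise breaks the $180^\circ$ tie in
closed loop.

## 2. Parameters

| parameter | units | default | why |
|---|---|---|---|
| ring size | neurons | 16 | printed preferred-angle grid $n\cdot22.5^\circ$; any size works (config) |
| $\tau_M$ | m | 40 000 | memory charge constant; goal and memory stored in units of m/$\tau_M$ so they stay commensurate |
| $\eta$ | fraction | 0.2 | default noise on every channel: per-neuron sun encoding, clock components, inclination ($\pm\eta\cdot90^\circ$), ring decode, EPG normalisation, steering branches |
| $T_L(0)$ | h | 7 | day-length estimate initial condition |
| fit start $(\tau_L, a, \beta)$ | (h, –, h) | (100, 10, 7) | optimiser initial guess; recovery tests pin correctness |
| foraging speed | m/s | 0.5 | walking insect; control step 1 s (0.5 m) |
| migration speed | m/s | 2.5 | monarch flight speed; travel step $dt$ = 50 min |
| `n_sub` | steps | 50 | control sub-steps per travel step; acceptance runs use 10 (coarse) to fit the time budget |
| daily travel cap | h | 8 | between sunrise and sunset, 1 h stop per hour of travel |
| departure jitter | – | $\pm5^\circ$, $\pm72$ h | uniform, drawn once per run |
| turning point | – | $>120^\circ$ over 25 m, 50 m refractory | printed search-pattern detector |
| irradiance proxy | – | $I_0\max(0,\sin e)^\gamma$, $I_0{=}1,\gamma{=}1$ | stands in for a ray-traced sky model; see §3 |

## 3. Synthetic data: what it emulates and what it does not

`make_irradiance_year()` evaluates the clear-sky proxy on the hourly grid
of a year (8 784 slots in 2024). The proxy is *not* a radiative-transfer
model: it has no atmosphere, clouds, or spectral content. It preserves
the two properties the day-length estimator actually consumes — zero at
night and a daily integral that grows with day length — and the
estimator's gain and offset are refit against it, exactly as they would
be refit for any other light regime. A green day-length test therefore
establishes that the leaky-integrator mechanism tracks day length from a
plausible light signal; it does not establish radiometric realism.

`make_exposure_schedule()` masks hourly slots by independent Bernoulli
draws with probability $T_F/12$, emulating a forager that is outside for
$T_F$ hours per day *on average*, at random times. Real foragers have
temporally structured exposure; the generator deliberately does not.

The behavioural "ground truth" (solar position, sunrise/sunset,
inclination) is computed from the embedded NOAA-style ephemeris and the
dipole formula; the test suite pins the ephemeris against an
independently implemented oracle (frozen values) to well under the 0.5°
contract.

## 4. Numerical choices

* **Time base** — hours since Jan 1 00:00 UTC of the simulation year; no
  civil time zones or daylight saving. Sunrise/sunset use the geometric
  horizon (no refraction); the internal declination model keeps its
  printed 365-day period even in leap years, while the NOAA ephemeris
  uses the true day count.
* **Euler integration** — the day-length estimator steps at 1 h (a linear
  recursion evaluated with `stats::filter`); memory integrates per
  control step; migration applies the steering output once per control
  sub-step ($dt/n_{sub}$), since a 50-minute literal step would make
  0.2-rad turns physically implausible.
* **Fitting** — `fit_day_length_params()` minimises the sum of squared
  errors of the simulated trajectory on the log-parameter scale
  (positivity) with Nelder–Mead from the fixed start; deterministic, and
  parameter recovery on self-generated data is tested to 1%.
* **Decode convention** — the population vector of a cosine bump
  $\cos(\psi+\phi^n)$ is $\tfrac12 e^{-i\psi}$; the EPG readout applies
  one fixed conjugation-and-half-turn ($-\overline{z}$) so that a perfect
  clock yields $e^{i\theta}$ with $\theta$ the true heading. The ring's
  offset invariance makes this a pure convention.
* **Degenerate inputs** — a zero-magnitude ring vector holds the previous
  heading estimate; at the memory goal, FC2 holds the last valid
  direction and the noisy steering loop produces the search behaviour;
  the inclination inverse clamps at $\pm(90^\circ-10^{-9})$.
* **Von Mises sampling** — Best–Fisher rejection; the route generator
  smooths turns with first-order exponential smoothing (factor 0.1, an
  otherwise unconstrained choice), rescales affinely to end exactly
  100 m east, and resamples at 0.5 m spacing.

## 5. Open design decisions

* **Noise sharing** — the clock components receive *independent* uniform
  draws per component per step (a shared-draw flag exists). The printed
  equations reuse one symbol; independence matches the statistical intent
  of a noise fraction.
* **Migration daily cadence** — "stop every hour for 1 h" is read as a
  one-hour stop after each accumulated hour of travel. The alternative
  (rest after every 50-min step) caps daily range at ~45 km and makes the
  printed monarch route infeasible within its printed season.
* **Consecutive turning points** — foraging trips end at four turning
  points whose successive detections are at most 100 m of path apart
  (twice the printed refractory); without the gap rule the single U-turn
  at trip start chains with the search turns and biases the centroid.
* **Teleports between foraging phases** — after homing the agent restarts
  at the exact nest with memory zero (exactly consistent); after a
  foraging trip the homing leg continues from the trip's true end
  position with the continuously integrated memory, so homing always
  unwinds a path integrated minutes earlier.
* **Migration search reporting** — the bounded steering readout caps the
  turn rate far below 120° per 25 m at flight speed, so the printed
  turning-point rule cannot fire during migration; runs end without an
  expressed search pattern and report the closest approach, flagged. The
  run additionally reports when the vector memory first reached the goal
  and the mean position over the following day (`search_center`), which
  measures the systematic overshoot described in §6.
* **Sensitivity baseline** — the swept sensing channel varies alone
  (other sensing channels silent) on top of the constant 20% processing
  noise; the reported error is the expressed-goal distance where the
  memory goal was reached, else the closest approach.
* **Estimated day length** — supported for the foraging site (the
  estimator is precomputed over the site's year); migration would need
  per-location light histories and uses the true day length.

## 6. Known limitations

* **Constant-bearing geometry.** Migrating on a fixed memory goal
  $G=\rho e^{i\theta_0}$ holds the *initial* great-circle bearing — a
  rhumb-like path. For long mid-latitude routes this geometry alone ends
  hundreds of kilometres from the destination even with a perfect
  noiseless compass (the noise-free monarch test quantifies this); for
  short or near-equatorial routes the effect is small.
* **Memory-goal overshoot under noise.** The EPG estimate decorrelates
  from the true heading by the injected noise, so memory increments
  shrink by $\kappa = E[\cos\varepsilon] < 1$ and the memory reaches
  $|G|$ only after $\sim 1/\kappa$ of the true distance: the post-arrival
  search centre sits systematically beyond the destination, by a fraction
  of route length that grows with the noise level. This is intrinsic to
  the printed equations; the `search_center` diagnostic exposes it.
* The compass front end is idealised (no polarisation pattern, no
  elevation dependence of azimuth observability); the geomagnetic field
  is a perfect dipole; there is no wind, terrain or energetics; the
  ring-attractor dynamics of the heading circuit are abstracted to a
  single complex number.
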