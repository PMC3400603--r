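---
title: "From individual Weber-law trail following to collective path choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From individual Weber-law trail following to collective path choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stigmergy)
```

This vignette documents the models implemented by `stigmergy`, the
assumptions behind them, the parameters that matter, and the numerical
choices the package makes where a choice had to be made. It is the
package's methods reference; the empirical claims in it are exactly the
ones the test suite and `scripts/acceptance.R` compute.

## The scientific problem

Foraging and exploring ants coordinate through stigmergy: each ant
deposits trail pheromone as it walks and steers by the pheromone it
encounters, so the environment itself stores the colony's collective
memory. Two bodies of evidence have long sat uneasily together:

* **Collective assays** (double-bridge experiments) are well described by
  a *disproportional* choice function — the Deneubourg form
  $P_L = (h+L)^a / ((h+L)^a + (h+R)^a)$ with $a \approx 2$ — implying a
  strongly nonlinear response to pheromone.
* **Perception research** suggests insects follow **Weber's law**: the
  response to a pair of stimuli scales with the *Michelson contrast*
  (difference over sum), a proportional — linear in the difference —
  rule.

The package implements the full chain that reconciles the two: a
proportional individual turning rule, measured from trajectories against
a passage-count pheromone field, *plus directional noise integrated over
the approach to a branching point*, yields a sigmoidal (error-function)
collective choice and a pitchfork bifurcation — the same phenomenology as
the nonlinear classical model.

## The pheromone field proxy

Pheromone is invisible, so its concentration at a cell $i$ and time $t$
is proxied by accumulated occupancy:

$$Q_t(i) \;=\; \sum_{s \le t} \delta q \,\cdot\, \mathbf{1}[\text{cell } i
\text{ covered by} \ge 1 \text{ ant at } s] \cdot 2^{-(t-s)/\eta},$$

with half-life $\eta = \infty$ (no evaporation) or finite (30 min is the
experimentally motivated lower bound; both scenarios are supported and
give similar inference because the Weber response is scale invariant).
Choices:

* **Grid.** 1 cell = 1 mm², matching the calibration "one ant marks one
  mm² with one unit of pheromone per second". The per-sample increment is
  `frame interval / footprint cells`, so each ant deposits exactly 1
  unit-equivalent per second regardless of footprint discretisation.
* **Footprint.** A disc of radius 1 mm around the tracked point
  (trajectory input carries no silhouette); configurable.
* **Occupancy is an indicator.** A cell covered by several ants in one
  frame is incremented once; under (rare) overlap the first ant in id
  order contributes its increment.
* **Evaporation is closed-form**, never a per-frame decay loop: deposits
  are stored with amplitude $2^{t/\eta}$ and queries scaled by
  $2^{-T/\eta}$, so advancing time is exact and order-independent. (This
  amplitude bookkeeping overflows only for half-lives far below any
  physically motivated value; the supported regime is minutes and up.)
* **Replay, not snapshots.** `field_replayer()` reproduces the field at
  any query time by replaying the deposit stream, so the "field as it was
  16 s ago" used below is exact rather than interpolated from cached
  snapshots.

## Tracking events and annotation

The unit of analysis is a *tracking event*: every 20 frames at 25 Hz
(0.8 s) an ant's position is marked, followed for 10 frames, marked,
followed for 10 more, marked again — two 0.4-s segments and the turning
angle $\Delta\alpha$ between their chord headings (degrees,
anticlockwise positive: left turns positive). Events with either segment
displacement under 4 mm are discarded (headings are unreliable when the
ant barely moves). Each event is annotated with the total pheromone
$C_L$, $C_R$ in 90° front-left/front-right circular sectors of radius
1 cm around the middle mark, oriented by the pre-segment heading, and
evaluated on the field *16 s before* the event so that an ant is never
correlated with its own just-deposited mark.

Numerical conventions worth knowing:

* Sector membership is by cell centre; a centre exactly on the heading
  ray belongs to the left sector (deterministic, and irrelevant for
  generic float positions).
* Sectors extending beyond the grid contribute zero, which is why the
  inference below restricts itself to an interior analysis window.
* The event anchor is the middle mark (the junction of the two
  segments), and the annotation heading is the pre-segment heading.
* One documented source-cadence ambiguity exists (0.8 s vs 0.4 s between
  event starts); the package uses cadence 20 frames = 0.8 s with 10-frame
  segments, consistent with 0.4-s speed intervals.

## The Weber inference

Three estimators, from weakest to strongest assumptions:

1. **Per-band slopes** (`band_slope_fit`): within bands of total
   pheromone $\Sigma C = C_L + C_R$, OLS of $\Delta\alpha$ on
   $C_L - C_R$ *through the origin* (the no-intercept form is forced by
   left/right symmetry: mirror-reflected data must give the same fit).
   Six log-spaced bands between the detection threshold and the 99th
   percentile of $\Sigma C$ by default; bands under 200 events are
   flagged undefined. Confidence intervals are nonparametric bootstrap
   percentiles over events (1000 resamples; the level is adjustable so
   that family-wise checks can Bonferroni-correct).
2. **Power law across bands** (`powerlaw_fit`): unweighted least squares
   of $\log k$ on $\log \Sigma C$ at the geometric band midpoints,
   restricted to $\Sigma C \ge 50$ units because the slope-concentration
   curve bends down below the detection threshold. Exponent $\nu = -1$
   is Weber's law: $k = A/\Sigma C$, i.e.
   $\Delta\alpha = A \,(C_L - C_R)/(C_L + C_R)$.
3. **Direct Weber fit** (`direct_weber_fit`): least squares of
   $\Delta\alpha$ on the contrast over events with
   $\Sigma C \ge C_0$; $A$ has a closed form. $C_0$ defaults to 50 units
   (fixed), or can be profiled over a grid with the residual sum of
   squares computed over *all* events (below-threshold events predicted
   to turn 0 on average) — profiling on the above-threshold subset alone
   would be ill-posed because shrinking the subset shrinks its RSS.

The fit is exactly invariant under rescaling every concentration (and
the threshold) by a common factor — the substantive reason the
passage-count proxy works at all: the deposition calibration and
(approximately uniform) evaporation cancel out of the contrast.

**The interior analysis window.** Estimation should use events away from
the arena walls (`clip_events`, 25 mm margin by default, the analogue of
the experiment's interior camera field of view). The reason is a
selection effect we measured explicitly on null data: near a wall, which
turning angles an ant can *complete* depends on the wall's orientation,
and wall orientation correlates with the local trail geometry; turns
that would exit are redirected. On pheromone-*independent* synthetic
ants this inflates the fitted amplitude from $\approx 0$ (interior) to
$\approx 8°$ (all events). The margin removes every event whose segments
can interact with the wall.

Auxiliary analyses: the **pixel-pair correlation map**
(`correlation_map`) correlates observed turning angles with the angle
predicted from a single probe pixel and its mirror image across the
heading axis, over a lattice of ant-frame offsets — the mirror pairing
preserves the left/right contrast logic while indexing the map by one
offset. Events whose pixel pair holds no pheromone are skipped per
offset; offsets with under 50 valid events are undefined, and an
optional permutation band (95% quantile of the permuted maximum $|\rho|$,
a family-wise band, so "everywhere inside the band" is a calibrated
statement) quantifies the no-response null. **Speed vs pheromone**
(`speed_vs_pheromone`) gives per-band box statistics with 1.5 IQR
whiskers. **Turning autocorrelation** (`turning_autocorrelation`) pools
per-ant lagged Pearson correlations of $\Delta\alpha$ at multiples of
the 0.8-s cadence.

## The agent-based model

Off-lattice agents on a patch grid: 1 patch = 1 mm, one step = 0.1 s,
speed 2 patches/step (the observed ~2 cm/s), direction updates every 4
steps (0.4 s, the analysis cadence). At an update the agent sums
pheromone in two 45°-wide sectors of radius 20 patches centred 45° left
and right of its heading and turns by

$$\Delta\alpha = A\,\frac{L - R}{L + R} + \varepsilon_1
\quad (L + R \ge \text{threshold}), \qquad
\Delta\alpha = \varepsilon_2 \quad \text{otherwise},$$

with $\varepsilon_1 \sim N(0, \sigma_1)$,
$\varepsilon_2 \sim N(0, \sigma_2)$. Each move deposits 0.1 units at the
current patch. 1000 ants enter at probability 1/1000 per step.
Parameter notes:

* $A = 35°$ — the measured response amplitude.
* $\sigma_1 = 15°$, $\sigma_2 = 35°$ per 0.4-s update. These two SDs are
  a package calibration (35° is the observed overall scale of direction
  changes; the smaller on-trail noise keeps trails stable while the
  larger below-threshold noise gives near-isotropic exploration). Which
  noise applies when is itself an assumption: the package attaches the
  small noise to the pheromone response above threshold and the large
  noise to undirected exploration below it.
* Detection threshold 50 units — consistent with the inference default;
  sensible because the simulator's deposition (0.1 units per 0.1 s =
  1 unit/s per ant) matches the field calibration.
* No evaporation by default; a half-life is supported.
* No ant–ant interactions of any kind; agents update in fixed id order
  from a single seeded RNG (R's RNG, so `set.seed()` makes whole runs
  bit-reproducible).

**Geometries.** The open arena is a circle of diameter 1000 patches with
the nest at the centre; agents acquire a back-to-nest label at rate 1
per 10 min, and labelled agents within 2 cm of the nest head straight in
and leave the world (rejoining the entry pool). An agent heading into
the wall aligns with the tangent closest to its current heading (exact
head-on ties break to the left tangent). The binary bridge is 440
patches end to end: nest disc (radius 20), proximal stem, a diamond of
four 45° branch capsules (half-width 10, side vertices 100 patches
off-axis), distal stem, food disc; reaching the food assigns the label,
and wall contact aligns the agent with its corridor's axis pointing away
from the last visited end. Branch-angle, widths and region radii beyond
the stated total length are fixed package constants
(`bridge_geometry()`, version 1).

**Outputs.** The bridge run records per-second branch counts (an agent
counts as "on a branch" inside a branch capsule clear of the central
stem column) summarised as percentages over 3-minute windows; the
plateau statistic is the mean majority share over the final five
windows. The arena run records the spatial Gini coefficient of the
in-circle field at 5-minute checkpoints and per-checkpoint summed
occupancy images (300 one-second snapshots each), the simulation
analogue of long-exposure arena photographs.

**Observed behaviour at the defaults.** Sixty-minute bridge runs give a
majority-branch plateau averaging close to 70% across seeds, with wide
per-seed spread (mid-fifties to high eighties): symmetry breaking is a
stochastic amplification, and some seeds are still deepening their
majority at the hour mark. In the arena, trails form and the field Gini
rises to ~0.77 by 60 min; one transient is worth knowing about: the Gini
at the *first* 5-minute checkpoint slightly exceeds the second, because
ants are still entering and the exploration front has not yet covered
the arena — sparse coverage looks unequal. From the second checkpoint
onward the rise is strictly monotone. The package reports the series as
measured rather than starting the clock after the transient.

## The analytic bridge model

On the approach to a branching point the ant's lateral position performs
a biased random walk: per step, drift
$V = c\,(C_L - C_R)/(C_L + C_R + K)$ (positive towards the left branch)
plus $N(0, \sigma)$ noise. After $n$ steps the position is
$N(nV, n\sigma^2)$, so the probability of arriving left of the branch
point is

$$P_L = \tfrac12\left[1 + \operatorname{erf}\!\left(
\frac{\sqrt{n}\,V}{\sqrt{2}\,\sigma}\right)\right]
= \Phi\!\left(\frac{\sqrt{n}\,V}{\sigma}\right),$$

a sigmoid in the concentration difference even though $V$ is
proportional — the resolution of the proportional-vs-disproportional
puzzle. Conventions and choices:

* Positive drift (more pheromone left) increases $P_L$; the walk oracle
  counts walkers finishing at $x > 0$ as left.
* $K \ge 0$ is an additive softening in the contrast denominator that
  captures the detection threshold (choice goes to chance when
  $C_L + C_R \ll K$); its exact placement is a package assumption. As
  $K \to \infty$, $P_L \to 1/2$ for all finite concentrations.
* The Monte-Carlo oracle (`mc_walk_oracle`) simulates the walk with
  antithetic noise pairs: unbiased, with variance at or below the
  binomial level, so its reported binomial SE is a conservative error
  bound in closed-form-vs-oracle comparisons.

The two-branch flux model couples this choice to deposition:
$\dot C_L = \Phi F_L - r C_L$ (and symmetrically), with total flux
$\Phi$ and retirement rate $r$. At stationarity $F_L + F_R = 1$ forces
$C_L + C_R = \Phi/r$, and stationary states solve a scalar root problem
(`stationary_states`: sign-change scan over a fine grid plus bisection
to $10^{-10}$ relative tolerance; the symmetric root is included
analytically). Stability comes from the eigenvalues of the $2\times2$
Jacobian (central finite differences of $F_L$), cross-checked in the
tests by `deSolve` integration from perturbed starts. Linearising at the
symmetric state gives a closed-form critical flux

$$\Phi_c = \frac{rK}{c\,\sqrt{2n/\pi}/\sigma - 1},$$

which the bisected numerical value reproduces to $10^{-6}$ — below
$\Phi_c$ one stable symmetric state, above it the symmetric state is
unstable and two stable mirror-image asymmetric states appear: a
pitchfork, as in the classical model. Defaults ($c = 0.5$, $n = 25$,
$\sigma = 1$, $K = 10$, $r = 0.1$) put $\Phi_c \approx 1.0$ with a fully
developed pitchfork within the default flux range.

## The synthetic-data generator

`gen_weber_trajectories()` is first-class, tested code, not a fixture:
agents at 25 Hz in a rectangular arena draw a turn every 0.4 s from the
truth rule ($A = 35°$, threshold 50 units, response noise SD 35°, speed
2 cm/s by default — the conditions used by the recovery tests) evaluated
on the pheromone map **as it was 16 s earlier**, the same lagged
quantity the inference annotates. This choice makes the recovery loop
exact: extraction reproduces every logged turn, and annotation
reproduces every logged $C_L, C_R$ bit-for-bit (the tests assert it), so
any recovery error is attributable to the estimators, not to a
generator/analysis mismatch. Every turn is logged with its sector sums,
threshold flag and a `wall` flag (turns whose next segment would leave
the arena are redirected towards the centre). The null generator is the
same machinery with the coupling off.

What the generator emulates — and what it does not: constant speed (the
observed speed was unaffected by pheromone; a speed-concentration
coupling is exercised at the event level in tests instead), no
camera-pixel quantisation, no ant-ant encounters (the encounter filter
in `extract_events` exists but defaults off), no thigmotaxis. Passing
recovery tests therefore demonstrate that the estimators invert the
stated generative model at realistic sizes and noise; they cannot rule
out biases that enter through what the model omits (identity-tracking
errors, marking-rate variability among real ants, wall-following).

**Problem sizes.** The recovery tests run 150 ants for 30 simulated
minutes in a 50 cm arena (~285,000 retained interior events, of which
~200,000 exceed the detection threshold), five seeds; at these sizes the
power-law exponent lands within ±0.2 of −1 and the direct amplitude
within a few percent of truth. The bridge acceptance uses five (test
suite) or ten (acceptance script) 60-minute seeds; the arena acceptance
one 60-minute run.

## Known limitations

* The passage-count proxy conflates pheromone amount with traffic; only
  contrast-based conclusions transfer, which is why every estimator is
  built (and tested) to be scale invariant.
* Near-wall events are excluded rather than modelled; thigmotaxis is not
  implemented, so bridge-plateau levels (where walls are never far) are
  more model-sensitive than the open-arena inference.
* The two simulator noise SDs are calibrated, not measured; the bridge
  plateau responds to them, to the sensing geometry and to the bridge
  proportions, and the package exposes all three.
* Band edges (six log-spaced bands) and the 25 mm interior margin are
  defaults, not estimates; both are arguments.
* The correlation map pairs mirror pixels only; fully general two-pixel
  maps would cube the computation and are out of scope.
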