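---
title: "Methods: geometry, inference and simulation of prey escape trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, inference and simulation of prey escape trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapegeom)
```

## The model

A prey animal at the origin is attacked by a predator approaching in a
straight line along the +x axis. The prey's initial orientation $\beta \in
[0^\circ, 180^\circ]$ is the angle between its body axis and the approach
path ($0^\circ$ = attacked head-on). To escape it turns by a signed angle
$\alpha$ (positive = away from the predator, negative = toward it) and then
swims straight; the escape trajectory is $ET = \alpha + \beta$, a circular
variable. Because the geometry is mirror-symmetric about the approach axis,
only the folded angle in $[0^\circ, 180^\circ]$ matters to the physics
(`fold_et()`).

The predator's capture device (its mouth) has half-width $D_{width}$ and is
approximated as an arc of radius $R_{device}$; the device edge at the
half-width lags the tip by the sagitta $D_2 = R_{device}(1 -
\cos(\arcsin(D_{width}/R_{device})))$. The attack ends with the tip
$D_{attack}$ beyond the prey's initial position. The *danger zone* is the
region this device sweeps: a lateral strip $|y| \le D_{width}$ closed off by
the end-of-attack arc. Escape rays below the corner angle
$\theta_{corner} = \mathrm{atan2}(D_{width},\, D_2 - D_{attack})$ exit
through the strip edge; steeper rays exit through the arc.

The prey is safe if its whole body crosses that boundary before the
relevant device edge arrives. The prey's arrival time splits into a
fast-start phase — duration $T_1(|\alpha|)$, covering the first $D_1$ of
displacement, which absorbs the cost of turning — and a constant-speed
phase at $U_{prey}$ over the remaining distance plus the posterior body
length $L_{prey}$. The predator arrives at a lateral crossing after
travelling $D_{initial} + D_2 - x_{cross}$ at speed $U_{pred}$, and at any
arc crossing exactly when the attack ends. The survival margin is
$T_{diff} = T_{pred} - T_{prey}$; dropping the $\alpha,\beta$-independent
constant $D_{initial}/U_{pred} + D_1/U_{prey} - L_{prey}/U_{prey}$ gives
the relative margin $T'_{diff}$ used everywhere rankings or argmaxes are
involved (`t_diff_rel()`, `et_profile()`).

Two escape routes emerge: sideways out of the strike path, or straight away
to outlast the attack. Their peaks in $T'_{diff}$ are separated by a trough
at $\theta_{corner}$ (a ray at the corner travels furthest for no gain),
which is what makes several distinct escape directions simultaneously
sensible — the core phenomenon the package models.

## Parameters and defaults

All lengths are mm, times ms, speeds mm/ms (numerically equal to m/s).
`pagrus_params()` carries the juvenile red sea bream / dummy scorpionfish
values: $D_{width} = 18$, $R_{device} = 199$, $D_1 = 15$, $U_{prey} =
1.04$, and the calibrated $D_{attack} = 34.73$, $U_{pred} = 1.54$; turn
angles are bounded by the observed range $|\alpha| \in [9^\circ,
147^\circ]$ and the ET grid step is $1^\circ$. $L_{prey} = 30$ (a ~45 mm
fish with its centre of mass at about a third of its length) and
$D_{initial} = 60$ follow the worked corner-mechanism scenario; neither
affects rankings (they cancel in $T'_{diff}$).

### The turn-time curve and how its free constants were fixed

$T_1(|\alpha|)$ is piecewise linear: flat up to a changepoint near
$44^\circ$, rising linearly beyond. The changepoint is an empirical
result; the flat level and slope, however, are not published. We fixed
them once, by requiring the model to reproduce the published worked
escape/capture scenario ($\beta = 110^\circ$, $D_{initial} = 60$,
$L_{prey} = 30$): escapes at ETs $140^\circ$ and $170^\circ$, captures at
$90^\circ$, $157^\circ$ and $190^\circ$. Writing those five sign
constraints in terms of the level $c$ and slope $m$ gives
$c \in (7.76, 12.07)$ ms and $m \in ((13.26 - c)/36, (13.26 - c)/16)$
ms/deg; `default_turn_model()` uses $c = 11.5$, $m = 0.08$, which satisfies
all five. A level near 11.5 ms for the first 15 mm of displacement implies
a mean fast-start speed of ~1.3 mm/ms, slightly above the subsequent
constant speed — plausible for a burst-and-coast escape. The companion
post-turn velocity curve `default_v0_model()` rises at 0.01 mm/ms per
degree to a plateau of 1.01 mm/ms at $46^\circ$, consistent with the
constant-phase speed.

Consequences worth knowing: quantities that depend on the *absolute* scale
of $T_1$ — most visibly the optimal-ET advantage — inherit the uncertainty
of this choice. Our curve yields a maximum advantage of ~2.7 ms; the
original analysis, with its own fitted curve, reports considerably larger
values in the same $\beta$ band. The *relative* structure (where the
advantage is large, where it is negligible, where the peaks sit) is robust
across the admissible $(c, m)$ region and is what the tests assert.

## Inference pipeline

**Turn kinematics** (`fit_changepoint()`): continuous two-segment least
squares with per-individual fixed intercept offsets (sum-to-zero coded, so
the population curve is the average fish), profiled over a $1^\circ$ grid
of changepoints; the wrong-signed segment collapses to a constant.
Model comparison (`compare_turn_models()`) uses Gaussian AIC with the
profiled changepoint counted as a parameter. Uncertainty, when requested,
comes from a cluster (by-individual) bootstrap. The original analysis used
a hierarchical Bayesian sampler with WAIC; the conclusions rest on the
curve shape, not the inference machinery, so the default backend is the
deterministic profile fit.

**Calibration** (`ranking_index()`, `optimize_params()`): for each event,
all feasible grid ETs of its orientation are ranked by decreasing
$T'_{diff}$ (both directionality branches as one list; ties share the mean
rank); the observed ET maps to the nearest feasible grid ET by circular
distance and its standardised rank in $[0, 1]$ is the ranking index. The
predator constants $(D_{attack}, U_{pred})$ minimise the cohort's mean
ranking index over a deterministic coarse-to-fine grid (9 points per axis
per stage, window shrink 1.5 cells, final resolution 0.01). Be aware the
objective has a shallow diagonal ridge in $(D_{attack}, U_{pred})$: at
$n \approx 264$ events the speed is well identified but the attack
distance can wander by more than $\pm 20\%$ between cohorts, which the
acceptance suite reports honestly.

**Stochastic choice** (`choice_dist()`, `fit_choice_sd()`,
`sample_et()`): the prey's deviation from the theoretical optimum is a
draw from a zero-mode normal with scale $SD_{choice}$ truncated to
$[0, 1]$, applied to the standardised rank; the scale is fitted by maximum
likelihood. Small scale = deterministic optimiser; large scale = protean
(unpredictable) escapes.

**Simulation and comparison** (`simulate_experiment()`,
`kuiper_two_sample()`, `gmm_modes()`, `variant_comparison()`): Monte Carlo
ET samples per orientation; two-sample Kuiper test ($V = D^+ + D^-$ of the
circular ECDFs, tie blocks pooled, rotation-invariant) with Stephens'
asymptotic p-value at $n_{eff} = n_1 n_2/(n_1+n_2)$ and a permutation
fallback below $n_{eff} = 20$; mixture-based mode counting; and the
four-variant factorial (attack endpoint × $\alpha$-dependent turn time)
with each reduced variant independently re-calibrated.

## The adjustable-path (pursuit) predator

`pursuit_params()` adds a reaction distance $D_{react}$ (the predator
travels straight, sweeping with its device, until its tip is that close to
the prey's initial position) and a minimum turning radius $R_{turn}$.
Post-reaction the predator is tracked by its tip along straight + single
arc + straight paths (Dubins CS), under a total path budget of
$D_{initial} + D_{attack}$; the adjustment arc is capped at a half-turn.
The danger zone is the union of the pre-reaction device sweep and the
post-reaction tip-reachable set; the prey's crossing point is found by
marching along its ray (2 mm steps, then bisection), and
`pursuit_t_pred()` supplies the arrival time there.

Three consequences of this construction, each a deliberate choice:

* The interiors of the two minimum-radius turning discs are unreachable —
  the safety pocket inside the predator's turning circle. This requires
  both the tip-only treatment of curved paths (the device half-width
  exceeds $R_{turn}$ here, so a device-sweeping turner would cover the
  discs) and the half-turn arc cap (an unbounded path could loop ~330°
  around the *opposite* circle into a disc).
* A second safety region lies opposite the predator's incoming direction,
  beyond the path budget: escape by outlasting the attack.
* With $R_{turn} = \infty$ the predator cannot adjust at all and the
  implementation *is* the straight-attack model, exactly — this implements
  the stated containment of the straight-attack construction in the
  adjustable-path one. For large but finite $R_{turn}$ the pointised
  post-reaction predator leaves a thin swept corridor, so the
  correspondence is implemented at the limit point itself rather than
  approached continuously.

With the frog-and-bat style parameters ($R_{turn} = 12$, $D_{react} = 70$,
$D_{attack} = 400$, $D_{initial} = 130$) the simulated ET distribution is
bimodal: a large-angle mode near 170–180° and a small-angle clump filling
the turning-disc shadow, whose angular width seen from the prey is
$2\,\mathrm{atan}(R_{turn}/D_{react}) \approx 19^\circ$. The package's
small-angle mode therefore sits within $[0^\circ, 20^\circ]$; a mode near
$30^\circ$ would require a differently anchored safe zone than anything
derivable from the material available to this implementation, and the
corresponding acceptance check is left failing rather than redefined.

## The synthetic-data generator

`synth_events()` emulates a dummy-predator escape experiment: 23
individuals, 264 events, orientations uniform on $[0^\circ, 180^\circ]$
(free positioning before the strike; an arbitrary `beta_dist` function can
be supplied), ET drawn by the truncated-normal ranking rule
($SD_{choice} = 0.33$), turn angle and directionality derived from
$ET - \beta$, turn times from the truth curve plus per-fish offsets
(sd 2 ms) and residual noise (sd 2 ms), velocities from the rise-then-flat
curve (sd 0.05 mm/ms), optional per-trial predator speeds drawn from the
slow (0.13–0.93) and fast (1.29–1.88) dummy ranges, and an optional
mirrored (left-side) recording mode for testing the pooling reader.

What it does *not* emulate: frame-by-frame kinematics; any empirical
clustering of orientations (a uniform $\beta$ washes out the small
toward-side peak near $-100^\circ$ that a head-on-heavy design produces);
predator-speed effects on choice (events are generated under a fixed
effective predator speed, which is exactly the model's assumption). A
green pipeline test therefore establishes internal consistency of model,
generator and estimators — not agreement with any particular animal.

## Numerical choices

* ET grid $1^\circ$; argmax ties break toward the smaller $|\alpha|$
  (cheaper turn); plateau local maxima collapse to their central point; a
  grid point is a local maximum only if strictly above both neighbours
  within its branch.
* An ET of exactly $0^\circ$ (straight at the predator) never exits the
  lateral strip and is marked infeasible rather than an error; under an
  infinite straight attack the same applies to exactly $180^\circ$.
* If a crossing falls inside the fast-start radius ($\lVert c\rVert <
  D_1$, possible for exotic parameter sets), the constant-phase distance is
  clamped at $L_{prey}$ so times stay non-negative.
* Truncated-normal sampling by inverse CDF; ML scale fit by
  `optimize()` on $(10^{-3}, 10)$.
* Mixture mode counting fits equal-width components by default and offers
  BIC selection, because per-component variances plus AIC overcount
  components on clean data; the AIC table is always reported.
* The Kuiper type-I calibration in the acceptance suite draws from the
  package's own simulated (grid-valued) ET distribution; mild ties make
  the asymptotic test very slightly conservative, measured ≈ 0.045 at
  nominal 0.05.
* Brute-force validation oracles (`march_crossing()`, `stepping_tdiff()`)
  are independent code paths: the crossing is found by marching the ray at
  $10^{-3}$ mm and the outcome by stepping time at $10^{-3}$ ms, in C++.

## Known limitations

* Planar geometry only; the predator neither accelerates nor re-targets
  continuously; the turn cost enters only through $T_1(|\alpha|)$.
* The absolute scale of $T_1$ (hence of the optimal-ET advantage) is fixed
  by the worked-scenario derivation above, not by a fit to the deposited
  experimental data.
* $D_{attack}$ is weakly identified from rankings alone at realistic
  sample sizes (see Calibration).
* The adjustable-path danger zone is a reconstruction; its acceptance is
  qualitative (mode locations), and the small-angle mode position is tied
  to the turning-disc shadow as described.
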