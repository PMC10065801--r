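# escapegeom

Geometric modelling of prey escape trajectories, for behavioural ecologists
studying predator evasion. When an ambush predator strikes, many prey
species do not flee in one "best" direction: their escape trajectories
(ETs) cluster around several preferred angles. `escapegeom` implements a
geometric model that explains this multimodality from two ingredients that
classical escape-angle models omit — the time the prey needs to *turn*
before accelerating away, and the *endpoint* of the predator's attack — and
ships the full inference pipeline around it, plus a synthetic-data
generator so every stage is testable without any external dataset.

## The model in brief

A prey at the origin, with initial orientation $\beta$ to the predator's
straight approach path, turns through $\alpha$ and escapes along
$ET = \alpha + \beta$. The predator's mouth (half-width $D_{width}$, arc
radius $R_{device}$) sweeps a danger zone that ends when the attack ends,
$D_{attack}$ past the prey. For every reachable ET the model evaluates the
survival margin

$$T_{diff} = T_{pred} - T_{prey},$$

the predator's arrival time at the prey's exit point of the danger zone
minus the time the prey (fast-start phase $T_1(|\alpha|)$ to displacement
$D_1$, then constant speed $U_{prey}$, body length $L_{prey}$ trailing)
needs to clear it. The optimal ET maximises $T_{diff}$; a second local
maximum — the suboptimal ET, separated from the optimum by a trough at the
danger-zone corner — is the other escape route, and prey choose between
them stochastically according to a truncated-normal distribution over the
model's ranking of all options (the "matching law" reading of escape
decisions).

The pipeline: changepoint (piecewise-linear) fits of turn kinematics
(`fit_changepoint`), rank-based calibration of the unobservable predator
constants (`optimize_params`), stochastic-choice fitting (`fit_choice_sd`),
Monte Carlo simulation (`simulate_experiment`), circular two-sample Kuiper
testing (`kuiper_two_sample`), Gaussian-mixture mode counting
(`gmm_modes`), optimal/suboptimal choice analysis (`classify_choice`,
`logistic_choice_fit`), and an adjustable-path pursuit extension
(`pursuit_profile`) in which the predator may bend its approach with a
minimum turning radius.

## Worked example

```r
library(escapegeom)

params <- pagrus_params()       # juvenile red sea bream experiment values
turn   <- default_turn_model()  # T1(|alpha|): flat 11.5 ms, break at 44 deg

# survival-margin profile for a prey attacked at 75 deg to its body axis
et_profile(75, params, turn)
#> T_diff' profile at beta = 75 deg: 278 grid ETs (277 feasible)
#>   optimal ET 119 deg; suboptimal ET 171 deg (advantage 2.56 ms)

# a synthetic cohort (23 fish, 264 escapes), then the full calibration
ev  <- synth_events(n_events = 264, n_fish = 23, seed = 1)
opt <- optimize_params(ev, params, turn)
#> D_attack = 39.77 mm, U_pred = 1.46 mm/ms, mean ranking = 0.234
ch  <- fit_choice_sd(ranking_index(ev, opt$params, turn))
#> truncated-normal choice distribution, sd_choice = 0.3063

# simulate theoretical ETs and compare with the "observed" cohort
sims <- simulate_experiment(ev$beta, opt$params, turn, ch,
                            n_reps = 100, seed = 2)
kuiper_two_sample(sims$et[sims$sim_id == 1], ev$et)
#> Two-sample Kuiper test (asymptotic): V = 0.1136, p = 0.3590 (n1 = 264, n2 = 264)
circ_modes(sims$et, bw = 50)
#>   mode     density
#> 1  123 0.007862337
#> 2  174 0.005498879
#> 3  221 0.003261676
```

Reading the numbers: at $\beta = 75°$ the best escape is at 119° (turn
sideways out of the strike path) and the second-best at 171° (outrun the
attack), the former buying 2.56 ms more margin. Calibration on the
synthetic cohort recovers the generating predator speed (truth 1.54) well
and the attack distance (truth 34.73) roughly — the ranking objective is
genuinely flat in $D_{attack}$ at this sample size. The simulated ET
distribution is statistically indistinguishable from the cohort (Kuiper
$p = 0.36$) and is multimodal, with its two main peaks at ~123° and ~174°
(the 221° mode is the mirror image of the 139° direction on the full
circle).

A command-line pipeline covering the same stages is available via
`escape_cli()`; see `?escape_cli`.

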