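---
title: "A prospective-error primitive model of trial-by-trial motor learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A prospective-error primitive model of trial-by-trial motor learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemotor)
```

## The model

`pemotor` simulates trial-by-trial sensorimotor adaptation with a population
of motor primitives whose recruitment is driven by the *prospective error*
(PE): the movement error the learner predicts for the upcoming trial. On
trial $t$ the motor command is the weighted sum of primitive activities,

$$x_t = \mathbf{W}_t \mathbf{A}^\top(\hat e_t), \qquad
A_i(\hat e) = \exp\!\left(-\frac{(\hat e - \mu_i)^2}{2\sigma^2}\right),$$

where $\mu_i$ is the $i$-th primitive's preferred PE (an even grid over
$(-180^\circ, 180^\circ)$ by default) and $\sigma$ a shared tuning width.
After the movement, the observed error $e_t$ (on a normal trial
$e_t = p_t - x_t + \xi_t$ for perturbation $p_t$ and feedback blur $\xi_t$)
drives two updates:

$$\mathbf{W}_{t+1} = \lambda\, \mathbf{W}_t + \eta\, e_t\, \mathbf{A}(\hat e_t),
\qquad
\hat e_{t+1} = \hat e_t + \alpha\,(e_t - \hat e_t).$$

Learning is credited to whichever primitives were active, i.e. to those
tuned near the current PE; primitives tuned elsewhere keep their memory,
eroded only by the forgetting factor $\lambda$ (which applies to every
weight on every trial). The linear PE update is the steady-state Kalman
predictor for a random-walk error observed in noise
(`pe_kalman_gain()` returns the gain for given drift and observation-noise
magnitudes).

Three trial modes are supported: `normal`; force-`channel` (the executed
movement is constrained straight, so the command is forcibly 0 and
$e_t = p_t + \xi_t$, while the corrective force the learner would have
produced is still recorded as `x_plan`); and `error_clamp`
($e_t \equiv 0$, under which the PE relaxes geometrically at rate
$1 - \alpha$).

### Why the PE, in one equation

Multiplying the weight update by $\mathbf{A}^\top(\hat e_{t+1})$ gives the
reduced recursion

$$x_{t+1} \approx \lambda\, x_t +
\eta\, e_t \exp\!\left(-\frac{(\hat e_{t+1} - \hat e_t)^2}{4\sigma^2}\right)
\cdot c_0,$$

so the effective learning rate is modulated by how much the PE moves
between trials. A predictable environment (small PE jumps) learns fast; an
unpredictable or blurred one learns slowly; and if perturbations are
i.i.d. with zero mean while recruitment is decoupled from them, the
ensemble-average weights converge to zero — memory can only form when the
activities carry information about the perturbation. These three
consequences are what the structural-learning, uncertainty and
memory-nulling checks in the test suite assert.

### Activity normalization and the primitive count

The number of primitives is not a scientific quantity, so activities used
in simulation are divided by $Z = \sigma\sqrt{2\pi\,\rho\,\rho_0}$, where
$\rho$ is the actual primitive density and $\rho_0 = 100/360$ per degree a
fixed reference density. This is classic sum-normalized Gaussian population
coding anchored at 100 primitives per full circle, written with the
large-$N$ value of the normalizing sum so that every simulated quantity is
invariant to `n_primitives` (the suite checks < 2% change between 1,000 and
4,000 primitives). With this convention the effective single-trial
error-to-command gain at zero PE change is
$\eta\, c_0 = \eta / (2\sqrt{\pi}\,\sigma\rho_0) \approx 0.148$ at the
default parameters — a stable, smoothly converging learner. The raw
per-operation formulas (`tuning_activities()`, `motor_command()`,
`update_weights()`) are unnormalized; `step_trial()` applies $Z$.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `lambda` | forgetting rate | 0.9586 | per trial |
| `eta` | learning rate | 2.3913 | unitless |
| `alpha` | PE update rate | 0.8 | per trial |
| `sigma` | tuning width | $0.2868 \cdot 360/2\pi \approx 16.43$ | degrees |
| `n_primitives` | population size | 1000 | — |
| `mu_low`, `mu_high` | preferred-PE range | $\pm 180$ | degrees |

The defaults are the best-fit values for adaptation to a $30^\circ$
visuomotor rotation; all phenomenon reproductions use this single set. Only
the ratio $\sigma/\alpha \approx 20.54^\circ$ is identified by single-trial
error corrections (see below), which is why `sigma` is stored tied to the
printed ratio. Preferred PEs sit on a deterministic grid by default (an
option samples them uniformly); the grid removes one noise source and is
what the tests exercise, since all reported quantities are ensemble
averages anyway. Tuning is a plain Gaussian on the real line — no angular
wrap-around — because the PEs visited in all protocols stay well inside
$\pm 90^\circ$, and the PE itself is never clipped.

## Protocols and phenomena

Schedules are data frames of `(p, mode, phase)` built from
`constant_schedule()`, `block_random_schedule()` (perturbations constant
within blocks of length $k$, drawn i.i.d. from the rotation set
$(-45, \dots, 45)$ by $15^\circ$) and `concat_phases()`. `run_schedule()`
iterates the model; `run_ensemble()` repeats it with per-run seeds derived
from a master seed by a prefix-stable scheme (growing an ensemble never
reshuffles earlier runs; re-running is bit-identical).

The packaged phenomenon experiments and their default problem sizes:

* `structural_learning()` — channel training (210 trials, blocks of
  $k \in \{1,2,3\}$), 10 washout trials, 30 test trials at $+30^\circ$;
  100 runs. Reports the exponential learning speed of the mean test curve
  and the end-of-training memory probed at a $30^\circ$ PE. Washout length
  between training and test is not pinned down by the underlying
  experiment; 10 zero-perturbation trials is the package default and is
  configurable. Consecutive random blocks may repeat a value (i.i.d.
  draws — the simplest reading of uniform sampling).
* `uncertainty_effect()` — 50 trials at $30^\circ$ under feedback blur
  $\sigma_G \in \{0, 18, 30, 36, 60\}^\circ$, 100 runs per level, fit with
  the state-space model $x_{t+1} = A x_t + B e_t$. The same master seed is
  used at every level so level comparisons are paired.
* `savings()` (30/5/30 trials) and `savings_washout_sweep()` (60-trial
  initial phase, washouts up to 200 trials, forgetting rates
  0.9586/0.9786/0.9986, normalized to each rate's maximum). The savings
  metric is the plain sum of the first-five-trial command differences —
  discrete trials, so a sum rather than an integral.
* `anterograde_interference()` — initial phases of 25/50/100 trials, then
  50 opposite trials; reports per-length curves plus a half-rise index
  (trials for the opposite-phase adaptation to reach half its final
  level), since the underlying comparison is usually shown as curves only.
* `spontaneous_recovery()` — 50/5 trials then 50 error-clamp trials
  (clamp length is a package default; the reference protocols show an
  extended clamp without printing its length). Reports both the headline
  recovery metric (max clamp command minus end-of-opposite command) and
  `max_clamp_x`. Note the former is positive even when relearning merely
  decays a deep negative state toward baseline; `max_clamp_x > 0` is the
  sharper signature of true re-expression.
* `perturbation_prediction()` — the rival model in which recruitment
  follows a predicted perturbation $\hat p$ (same linear update, driven by
  the noiseless $p$, reusing `alpha`; no separate rate is defined
  anywhere), with $\hat p$ forced to 0 or $-30^\circ$ during the clamp,
  phases mirroring the spontaneous-recovery protocol.

Ensemble-size defaults follow the reference simulations: 100 runs for
structural learning and uncertainty, 10 for savings, interference and
recovery (the latter protocols are deterministic at zero noise, so their
ensembles exist for interface uniformity).

## Fitting and statistics

**Single-trial correction (stage 1).** With zero weights and zero PE, the
correction after observing $e$ in a channel trial is
$f(e) \propto \eta\, e\, \exp(-(\alpha e)^2 / 4\sigma^2)$: odd,
non-monotonic, peaked at $\sqrt{2}\sigma/\alpha \approx 29^\circ$. Only
$\sigma/\alpha$ is identified. `fit_correction_ratio()` fits
$m f(e; r) + n$ by profiled least squares over $r$. Two practical points
discovered while validating the estimator on synthetic data:

* During continuous random training the zero-PE context is violated and
  carried-over memory correlates with the previous error, biasing the
  naive estimator upward by tens of percent. `fit_model_params()` therefore
  screens pairs for *PE quiescence* (small errors one and two trials back)
  before fitting.
* Even screened, the carried-memory term dominates the per-pair noise.
  `generate_probe_subject()` provides the clean measurement design used in
  single-trial adaptation studies: long quiet runs of zero-perturbation
  channel trials (weights decay, PE relaxes), one isolated probe, one
  read-out trial. Twelve noiseless probe subjects recover the ratio to
  well under 1%.

**Learning curve (stage 2).** `fit_learning_curve()` searches
$\alpha \in \{0.1, \dots, 1.0\}$ (with $\sigma = r\alpha$ tied to the
stage-1 ratio, $\alpha = 0$ would force a zero tuning width and is
infeasible), estimating $(\lambda, \eta)$ for each grid point by bounded
quasi-Newton least squares against the model's noiseless curve, simulated
with a 200-primitive population (results are N-invariant; the smaller
population keeps the search fast). On noiseless constant-rotation data the
generating parameters are the unique optimum. However, with
$\sigma = r\alpha$ the rate modulation equals
$\exp(-(e-\hat e)^2/4r^2)$ — free of $\alpha$ — so a smooth constant
rotation barely distinguishes neighbouring grid points. $\alpha$ is
identified where errors jump: `alpha_probe_schedule()` (initial learning
plus three reversal / error-clamp / relearning cycles) separates the grid
sharply; at behavioural noise (5° motor noise, 12-subject averages) the
generating grid point is recovered in roughly nine of ten replicates.

**Auxiliary fits.** `exp_fit()` fits $y_t = a e^{-bt} + c$ by profiling:
for fixed $b$ the model is linear in $(a, c)$, so a coarse grid plus 1-D
optimization reaches the global least-squares solution with no
nonlinear-solver failures — important inside 3,000-fold bootstraps.
Constant series are flagged ($b$ unidentifiable). `state_space_fit()` is
OLS on $x_{t+1} = A x_t + B e_t$ with the convention that $B > 0$ means
adaptation when $e = p - x$; an all-zero error series flags $B$ as
unidentifiable, and a collinear design errors. `affine_fit()` is
closed-form; zero-variance data are flagged with $R^2 = 0$.

**Resampling.** `bootstrap_learning_speed()` resamples subjects with
replacement (3,000 resamples in the standard analysis).
`randomization_test()` intermingles and re-splits the two samples; the
default statistic is the two-sided $|\bar a - \bar b|$ with the add-one
correction $p = (1 + \#\text{extreme})/(1 + n_{perm})$, which makes the
p-value label-symmetric, bounded away from 0, and uniform under the null
(checked by a KS test over 200 replications). One-sided alternatives are
available by argument. `exclude_outliers()` is the one-pass
mean $\pm 3$ SD screen; note that because the moments include the
candidate point, the within-sample z-score is bounded by
$(n-1)/\sqrt{n}$, so at $n = 12$ only values just past the fence can ever
be removed — moderate outliers are masked.

## The synthetic behavioural generator

`generate_group()` emulates a three-group rotation experiment: 12 subjects
per group (6 clockwise, 6 counter-clockwise test rotations), force-channel
training with block-random rotations (84 trials by default — 12 exposures
per set value, in blocks), 10 washout trials, 30 test trials at
$\pm 30^\circ$. Channel rows record an affine-scaled force
(`force_gain`, `force_offset`, defaults 1 and 0) with noise defaulting to
10% of the peak single-trial correction; test and washout rows record the
movement angle with 5° Gaussian motor noise (no subject-level noise model
is published for this design; 5° is a typical trial-to-trial pointing
s.d.). `normalize_sign()` folds CW subjects onto the CCW convention so
groups can be pooled; `inject_outlier()` plants a screened-data test case.

What the generator does *not* emulate: kinematic time series, movement
velocity criteria, reaction times, within-movement corrections, reward
effects, or any between-subject parameter variability. Passing tests
therefore show that the analysis pipeline recovers what this model family
generates under i.i.d. Gaussian trial noise — not that real subjects obey
the model.

## Numerical choices and degenerate inputs

* Closed forms (`inner_product_closed_form()`,
  `uncertainty_averaged_correction()`) are checked against brute-force
  sums and quadrature at relative tolerances of 1% (finite-N) and 1e-6
  (quadrature).
* All angles are degrees, counter-clockwise positive; a clockwise rotation
  is $-30^\circ$.
* Single seeded RNG: every stochastic entry point takes a seed or uses the
  R RNG explicitly; ensembles derive per-run seeds prefix-stably from the
  master seed.
* Degenerate inputs are flagged rather than guessed at: constant series in
  `exp_fit()`, zero error series in `state_space_fit()`, zero-variance
  data in `affine_fit()`; unknown trial modes, malformed tables and
  out-of-range configuration values raise located errors.
* Problem sizes in the checks (200-run nulling ensembles, 100-run
  phenomenon ensembles, 50 recovery replicates, 200 calibration
  replications) are the package's validation choices and run in a few
  minutes on a single core.

## Known limitations

* Single target, single movement direction; the bivariate extension of the
  tuning (target direction × PE) is deliberately out of scope.
* The learner's parameters are constant: no trial-by-trial Kalman
  modulation of `alpha`, no longer error history.
* The headline recovery metric conflates true re-expression with passive
  decay after full unlearning (use `max_clamp_x` alongside it).
* The stage-2 grid search inherits the flat-objective caveat above: on
  plain constant-rotation data, report $\alpha$ only with an
  identification protocol.
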