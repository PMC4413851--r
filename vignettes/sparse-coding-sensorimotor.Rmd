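---
title: "Sparse coding and sensorimotor transformation: model and methods"
author: "sparsemotor developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse coding and sensorimotor transformation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsemotor)
```

## The scientific question

Reaching for a visual target requires a *sensorimotor transformation*:
visual information (where the target is) and proprioceptive information
(how the arm is currently configured) must be combined into muscle
commands, and the mapping from muscle activity to movement itself
depends on posture.  `sparsemotor` simulates the classic visually
guided wrist-movement paradigm: a cursor must be driven onto one of
`K = 8` targets on the unit circle while the forearm is held in one of
three postures (pronation, midrange, supination).  Because each
muscle's pulling direction rotates with the forearm, the same muscle
command produces different movements in different postures — the
network must learn a genuinely posture-contingent visuomotor map.

The package's purpose is to ask what *coding sparseness* in the neural
population that feeds the muscles contributes to learning this
transformation, holding metabolic cost fixed.

## The model

### Task

- Targets: unit vectors `v_k = (cos a_k, sin a_k)`, `a_k = 2*pi*(k-1)/K`.
- Postures: unit vectors `p_k'` at angles `(-pi/4, 0, pi/4)`.
- Muscles: `N_M = 5` muscles whose pulling directions are base angles
  (evenly spaced over the circle by default) rigidly rotated with the
  posture; posture `k'` has projection matrix `P_k'` with columns
  `(cos phi_ik', sin phi_ik')`.
- A trial presents a uniformly random (target, posture) pair; the
  executed movement is `x = P_k' %*% M` and the movement error is
  `e = v - x`.

The paper-of-record for this paradigm prints neither the posture
vectors nor the pulling directions (and reports insensitivity to the
posture values); both are configurable here, with the defaults above.

### Coding layer

Each of `N = 2000` neurons receives the two input vectors through
fixed random Gaussian weights and fires through a rectified linear
unit,

    u_i = J_v[i,] . v + J_p[i,] . p - theta_i,      r_i = max(u_i, 0),

and the population vector is normalized to unit squared norm,
`A = r / ||r||`, so that the "metabolic cost" `t(A) %*% A = 1` is
identical for every input and every threshold.  The threshold `theta`
is the single knob controlling sparseness: the fraction of neurons
that are *never* active over the 24 task conditions (`N_NA / N`) grows
from 0 to 1 as `theta` sweeps the grid `seq(-3, 3.8, length.out = 18)`.
Normalization is per presented input; if no neuron responds, the input
is silent, produces no movement and (crucially) no learning update.

Saturating variants (`tanh_rectified`, `sigmoid`, `tanh_positive`) are
provided for the robustness and comparison experiments; `beta` (slope)
defaults to 1.

### Learning rule

Muscle activity is the rectified readout `M = pmax(W %*% A, 0)`.  `W`
(initialized at zero) descends the per-trial cost

    C = 0.5 * ||v - P %*% M||^2 + 0.5 * lambda * sum(M^2)

by `W <- W + eta * (t(P_plus) %*% e - lambda * M) %*% t(A)`, where
`P_plus` zeroes the columns of muscles on the wrong side of the
rectification.  Defaults: `eta = 0.4`, `lambda = 0` (the muscle-cost
term is kept for completeness but plays no role in the converged
error).

**Subgradient at the kink.** Because `W` starts at exactly zero, every
muscle drive is exactly at the rectification kink on the first trial.
Taking the subgradient 0 there would zero `P_plus` entirely and
learning could never start; the package therefore treats drive `>= 0`
as active in the learning mask (subgradient 1 at the kink).  This is
the only reading under which zero-initialized learning is possible at
all.

### Comparison networks

To separate "sparse coding helps" from "any nonlinearity helps", two
tanh networks with `theta = 0` (dense), `N = 200`, are provided in
which the sensory weights `J` adapt (alone, or together with `W`) by
the chain-rule gradient of the same cost through the activation and
the normalization.  The published initialization is `J = 0`; a
rectified tanh would then be identically silent and could never
learn, so these networks use the smooth nonnegative activation
`(1 + tanh(beta*u))/2`, which is 1/2 at zero drive.  `W` is
initialized Gaussian with sd `1/sqrt(N)` (the published sd is not
printed; this keeps the initial drive O(1)).

## Analyses

- **Threshold sweep** (`theta_sweep`): per run, one draw of `J` shared
  across the whole grid; per (run, theta) a fresh training from
  `W = 0`; converged error = mean squared error over the last 10% of
  trials; mean/sd across runs per theta, plus sparseness.
- **PCA** (`pca_contributions`): eigenvalues of the covariance of the
  24 activity columns (conditions are observations, neurons variables,
  centered over conditions).  Contributions are percentages of the
  eigenvalue sum; at most `min(N, C)` can be nonzero (tolerance
  `1e-10` x largest).  Activity does not depend on `W`, so trained and
  untrained populations have the same spectrum; only `theta` matters.
- **Generalization** (`generalization_error`): freeze `W` after
  training, evaluate mean squared error on `L = 500` novel targets
  (uniform random angles by default, evenly spaced available) crossed
  with all 3 postures.
- **Tuning and modulation** (`tuning_matrix`, `modulation_fit`,
  `modulation_census`): a neuron's K x 3 activity table is fitted by
  an additive model `f(k) + g(k')` (two-way main effects, closed-form
  least squares) and a multiplicative model `f(k) * g(k')` (best
  nonnegative rank-1 approximation by alternating least squares, 100
  iterations / 1e-10 relative convergence).

**Classifier rule.** The two models have the same number of free
parameters, so the better model is the one with the smaller residual
sum of squares; a call is definite only when the winner's residual is
at least 2x smaller, otherwise "ambiguous" (and "flat" below an
activity scale of 1e-6).  We deliberately do not use a margin on the
R-squared difference: for well-tuned neurons both models reach
R-squared near 1, and even an *exactly* additive table (additive
R-squared = 1 to machine precision) sits within 0.05 of its rank-1
fit whenever mean activity dominates the contrasts — a fixed
R-squared margin therefore sends essentially every dense-coding
neuron to "ambiguous" while the residual ratio separates the classes
cleanly.

## Numerical design choices

- **Factored training.** With fixed `J` the activity vector takes only
  `C = 24` values, so `W` always lies in the span of those columns and
  is carried exactly as `W = G %*% t(Act)` (`G` is `N_M x C`); muscle
  drive uses the Gram matrix of the activity columns.  This is not an
  approximation — the trajectory is algebraically identical to the
  direct update, and `train(..., method = "direct")` (plain R,
  `N`-dimensional) backs the equivalence tests at 1e-10.  One
  million-trial training takes seconds, so sweeps can use the full
  reference protocol rather than truncated training.
- **Determinism.** Every stochastic step (weights, thresholds,
  schedules, novel targets) is seed-controlled through an internal
  push/pop of R's RNG state; a master seed spawns child seeds, all
  below 2^31.
- **Silent trials** produce error `||v||^2 = 1` and no update.
- **Gradient validation.** Every analytic gradient (the `W` rule and
  the `J` chain rule) is checked against central finite differences
  (`h = 1e-6`) on 100+ random instances with all pre-activations and
  drives bounded 1e-3 away from rectification kinks.

## What the generator emulates — and what it does not

The synthetic world is the stated simulation protocol itself: Gaussian
sensory weights (sd 1), `N = 2000`, `K = 8` targets x 3 postures,
`eta = 0.4`, `W0 = 0`, uniform trial sampling, 18-point theta grid.
It contains no neuronal noise, no noise correlations, no trial-order
effects and no biomechanics (no force-length curves, no dynamics), so
green tests establish properties of the idealized rate model only.

A dynamical feature worth knowing about: the rectified muscle stage
can *trap*.  Once a muscle's drive goes negative for a condition its
row stops updating from that condition, and recovery relies on
activity overlap with other conditions; in sparse coding (decorrelated
activities) that overlap is weak and a small fraction of runs plateau
permanently at roughly one posture's worth of error (~0.35).  The
location of the error-minimizing theta on the grid is therefore partly
decided by how often runs trap at each theta, which in turn depends on
the (unpublished) pulling-direction geometry; with the package
defaults the across-seed argmin concentrates on 3.0-3.4 with
occasional 3.8, rather than landing exactly on 3.0 every time.

## Known limitations

- The pulling-direction geometry is a stand-in (evenly spaced,
  rigidly rotated); empirical wrist-muscle pulling directions are
  neither uniform nor rigidly rotating.
- The comparison networks' activation and `W` initialization resolve
  under-specified published details; conclusions about them are
  qualitative (learnability, modulation class), not quantitative.
- `sigmoid` re-zeroes the logistic at the threshold before
  rectification, mirroring the rectified-tanh construction; it is an
  interpretation, not a published formula.
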