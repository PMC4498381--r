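---
title: "Space-by-time decomposition of muscle activity: models, solvers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-by-time decomposition of muscle activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergizer)
```

## The model

A single trial of muscle activity is a non-negative matrix $M^s \in
\mathbb{R}_+^{T \times M}$ (time steps $\times$ muscles), typically an EMG
envelope resampled to a common $T$ and normalized per muscle. The
space-by-time model factors every trial over one shared basis in time and
one in muscle space:

$$M^s \approx \tilde{W} A^s W, \qquad s = 1, \dots, S,$$

with temporal modules in the columns of $\tilde{W} \in \mathbb{R}_+^{T
\times P}$, spatial modules in the rows of $W \in \mathbb{R}_+^{N \times
M}$, and trial-specific activation coefficients $A^s \in \mathbb{R}_+^{P
\times N}$. The modules are constrained to unit sum — each column of
$\tilde{W}$ and each row of $W$ sums to 1 — so all amplitude information
lives in the coefficients. (Note the orientation: some descriptions of this
model state the normalization for rows of $\tilde W$ and columns of $W$;
the constraint systems actually solved here fix columns of $\tilde W$ and
rows of $W$, which is the orientation this package uses consistently.)

The model assumes (i) non-negativity of all factors, matching rectified
EMG; (ii) that the same temporal waveforms and muscle groupings are reused
across all trials and tasks, with only their couplings varying; and (iii)
trials of equal length, which in practice means time normalization before
fitting.

Reconstruction quality is summarized by the variance accounted for,

$$\mathrm{VAF} = 1 - E^2_{NMF} \Big/ \sum_s \lVert M^s - \bar{M}
\rVert^2_{fro},$$

where $\bar M$ is the mean trial pattern; VAF is 1 for an exact fit and can
be negative for a model worse than the mean.

## The discriminative objective

When each trial carries a task label $k \in 1..K$, the coefficients are the
task-dependent part of the model, and a useful decomposition should keep
them similar within a task and different between tasks. Following the
Fisher/LDA construction on the vectorized coefficients,

$$S_w = \sum_{k} \sum_{s \in G_k} \mathrm{vec}(A^s - \bar{A}_k)\,
\mathrm{vec}(A^s - \bar{A}_k)^\top, \qquad
S_b = \sum_{k} \mathrm{vec}(\bar{A}_k - \bar{A})\,
\mathrm{vec}(\bar{A}_k - \bar{A})^\top,$$

the discriminative fit minimizes

$$E^2 = E^2_{NMF} + \gamma\, \mathrm{tr}(S_w) - \delta\, \mathrm{tr}(S_b).$$

Two deliberate fidelity choices: $S_b$ is *unweighted* by class size (each
class mean contributes once), even though class-size weighting is more
common in the LDA literature; and $\mathrm{vec}(\cdot)$ is column-stacking,
used identically in the scatter computation, the decoders, and the solver
gradients. Traces are evaluated through the Frobenius identity
$\mathrm{tr}(S_w) = \sum_k \sum_{s \in G_k} \lVert A^s - \bar A_k
\rVert^2_{fro}$, so the $(PN)^2$ matrices are materialized only on request.

The coefficient gradients used everywhere (solvers, finite-difference
audits) are, for $s \in G_l$,

$$\partial_{A^s} \mathrm{tr}(S_w) = 2 (A^s - \bar{A}_l), \qquad
\partial_{A^s} \mathrm{tr}(S_b) = \tfrac{2}{n_l} (\bar{A}_l - \bar{A}) -
\tfrac{2}{S} \sum_k (\bar{A}_k - \bar{A}).$$

## Solvers

All solvers are best-of-restarts: factors are initialized entrywise
uniform(0,1), modules normalized to unit sum, and the initial coefficients
rescaled by the single least-squares factor that matches the initial
reconstruction to the data scale (without this, the multiplicative
iteration spends hundreds of iterations recovering scale). Restart $r$ uses
seed $\texttt{seed} + r - 1$; ties in the final cost are broken by lower
reconstruction error, then by restart index.

**Multiplicative updates (`mult`).** The module updates are the standard
NMF multiplicative rules for the two unfoldings of the data (the Fisher
terms do not involve the modules). The coefficient update splits the
gradient of $E^2$ into its positive and negative parts and multiplies
elementwise by their ratio; with $\gamma = \delta = 0$ it reduces exactly
to the reconstruction-only algorithm. A small guard
($\varepsilon = 10^{-12}$, configurable) is added to denominators; an entry
that reaches exactly zero stays zero (multiplicative absorption). One
iteration applies, in order: spatial-module update, temporal-module update,
unit-sum renormalization, coefficient update.

The placement of the renormalization matters more than one might expect.
For the reconstruction-only fit the renormalization is *compensated* — the
coefficients absorb the inverse factors — so the objective is untouched and
the error trace is provably non-increasing (the package asserts this).
For the discriminative fit the constraint is imposed without compensation,
which forfeits the descent guarantee. If that uncompensated renormalization
is instead applied *after* the coefficient update, the scheme can diverge
systematically: each iteration the module updates absorb scale, the
renormalization discards it, and the Fisher-damped coefficient update never
catches up, so the reconstruction decays without bound. Renormalizing
before the coefficient update lets the coefficient step re-absorb the
discarded scale within the same iteration; with compensation the order is
objective-neutral, so a single code path serves both cases.

**Constrained alternating least squares (`als`, `als_qp`).** Each module
update solves the equality-constrained least-squares problem (unit-sum
columns of $\tilde W$, rows of $W$) through its KKT system; a singular
system is re-solved with a small ridge and a warning. Negative entries are
then clipped to zero and the unit sums restored by renormalization. The
`als_qp` variant instead solves the non-negativity-constrained quadratic
program by projected gradient descent with exact Euclidean projection onto
the probability simplex and a backtracking step, which guarantees that
module steps never increase the module-update cost (audited in the tests).
Coefficients reuse the multiplicative rule in both variants; how (or
whether) the coefficients are re-estimated inside each ALS sweep is not
fixed by the method's description, so this is a documented package choice.

**Nonlinear programming (`nlp`).** All factors are stacked into one
non-negative variable $z = (\mathrm{vec}(\tilde W), \mathrm{vec}(A),
\mathrm{vec}(W))$ and $E^2(z)$ is minimized subject to the linear unit-sum
constraints $\phi(z) = 0$ by an augmented-Lagrangian loop over `L-BFGS-B`
(box constraints give $z \ge 0$; multiplier updates drive the constraint
violation below $10^{-6}$), with analytic gradients for every block.

**Stopping.** Each solver stops when the relative change of *its own*
objective ($E^2_{NMF}$ for the reconstruction-only fit, $E^2$ otherwise)
falls below `tol` (default $10^{-8}$) or after `max_iter` (default 500)
iterations. Both defaults are package choices; the underlying method
descriptions specify neither.

**Projection onto fixed modules.** Generalization to unlabeled trials uses
coefficient-only multiplicative updates with the modules frozen (no task
information). The fixed-point iteration converges slowly near its limit, so
the projection defaults are deliberately strict (`max_iter = 20000`,
`tol = 1e-13`); the tests require recovery of constructed coefficients to
$10^{-3}$ relative.

## Evaluation metrics

* **DEC** — leave-one-out task decoding of the vectorized coefficients by a
  Gaussian linear discriminant with pooled covariance and empirical class
  priors. The classifier is ridge-regularized only on singularity
  ($\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/d$, with a warning). A
  resubstitution variant (`lda_decode_resub()`) is exposed separately
  because "decoding on trained data" is sometimes reported; the
  cross-validated DEC is the default everywhere.
* **VDM** $= \mathrm{VAF} \times \mathrm{DEC}$, with negative VAF clamped
  to zero so $0 \le \mathrm{VDM} \le 1$; the single score used for tuning.
* **CLS** — repeated stratified subsampling: modules are fitted on training
  trials only, *all* trials are projected onto the frozen modules, a linear
  SVM (cost 1; the method description names the tool but no
  hyper-parameters, and no kernel search is done) is trained on the
  training coefficients and scored on the held-out trials.
* **J** $= \mathrm{tr}(S_w)/\mathrm{tr}(S_b)$, smaller meaning better task
  separation.
* **Module similarity** — Pearson correlation under the pairing that
  maximizes total similarity, found by exhaustive permutation (module
  counts here are at most a handful, so assignment by enumeration is
  exact). Zero-variance modules yield `NA` with a warning and contribute
  zero to the pairing objective.

## Tuning and model order

`grid_search_gamma_delta()` fits the discriminative decomposition over a
coarse grid (default $\{0, 10^{-4}, \dots, 1\}$ per weight — wide enough to
bracket optima typically reported for multi-task EMG), computes VAF, DEC
and VDM per cell, and returns the VDM-argmax; `refine_gamma_delta()` then
runs a Nelder–Mead maximization of VDM in $\log_{10}$ coordinates (zero
start components floored at $10^{-8}$), with fixed fitting seeds so the
objective is deterministic, and never returns a point scoring below its
start. Whether the grid's DEC uses cross-validation or resubstitution is
configurable; the default is leave-one-out.

`select_model_order()` picks the most compact $(P, N)$ whose DEC is within
a tolerance of the best over the searched ranges (ties: smallest $P N$,
then $P + N$, then $P$). The default tolerance is one binomial standard
error of the maximal DEC at the given $S$ — a deliberate simplification of
decoding-plateau selection procedures that are defined in prior work rather
than re-derived here.

## The synthetic-data generator

`toy_synergy_spec()` defines the benchmark simulation: $T = M = 2$, two
temporal and two spatial modules, $K = 4$ tasks $\times$ 10 trials, 40 %
noise. The generative quantities that the simulation design leaves
unspecified are fixed, documented package defaults:

* true modules: unit-sum 2-vectors (no special structure is claimed);
* task-mean coefficient matrices: four distinct non-negative patterns whose
  pairwise distances exceed five within-task standard deviations, so the
  tasks are perfectly discriminable from the true coefficients *by
  construction* — the stated premise of the simulation design;
* within-task variability: truncated-at-zero normal draws around the task
  mean with a coefficient of variation of 0.1 (truncated-normal rather than
  lognormal for symmetric small-CV behavior; configurable);
* noise law: `observed = max(0, signal·(1 + f·u) + f·s̄·v)` with `u`, `v`
  i.i.d. standard-normal fields, `f` the noise fraction and `s̄` the
  trial's mean absolute signal — one multiplicative and one additive
  component, each scaled to the stated fraction. Whether a "40 % noise"
  statement means amplitude or SD, per component or split, is genuinely
  underdetermined; this law is the package's documented reading, and the
  tests verify that the realized deviation scales linearly with `f`.

`pointing_synergy_spec()` mirrors a realistic arm-pointing experiment
(9 muscles, 50 time steps, 16 tasks = 8 directions × 2 speeds × 40 trials,
3 temporal modules — two single-burst and one double-burst Gaussian
waveform, echoing the triphasic pattern — and 4 sparse muscle groupings,
with fast-speed task means scaled 1.8× above normal-speed ones).

What the generator does *not* emulate: biomechanics (no forward model, no
kinematic consistency), muscle-specific noise spectra, trial-length
variability, electrode crosstalk, or nonstationarity across the session.
Passing the recovery tests therefore shows the algorithms work when the
model family is correct and noise is unstructured; it does not certify
performance on real recordings.

A note on the benchmark's geometry: with $T = M = 2$ each trial has exactly
$P N = 4$ observations, so the reconstruction-only fit can absorb nearly
all measurement noise into the coefficients (VAF close to 1) at the cost of
noisy, poorly separable coefficients. This makes the benchmark a sharp test
of the discriminative objective: only the Fisher penalty can recover the
task structure of the coefficients.

**Tuning in the simulation study.** For the 20-seed simulation audit the
within-task weight is tuned by maximizing LOO decoding over the small log
grid $\gamma \in \{1, 3, 10\}$ (ties to the smallest value) at
$\delta = 0.01$. VDM-argmax tuning on this toy lands in a regime where
decoding is high but not perfect; the simulation study's claim is about the
discrimination-dominant regime (perfect categorization at visibly lower
VAF), and decoding-targeted tuning is the procedure that matches that
claim. On real-scale data, where the reconstruction term involves hundreds
of observations per trial, VDM-based tuning is the recommended default.

## Numerical choices and degenerate inputs

* All-zero module during normalization: replaced by a uniform module
  ($1/T$ or $1/M$ entries) with a warning; under compensation its
  coefficient slice is zeroed, so reconstructions are unchanged.
* VAF with identical trials (zero total scatter) is an explicit error, not
  a silent `NaN`; `j_ratio()` with $\mathrm{tr}(S_b) = 0$ likewise.
* Fits are deterministic given `(data, options)`: per-restart seeds are
  derived from the master seed by a counter, and the compiled engine is
  free of its own randomness.
* Problem sizes used by the test suite: the 40-trial benchmark for the
  solver and tuning audits (100 restarts × 20 seeds for the simulation
  study; 3×3 grid × 10 restarts for the tuning direction check), random
  6-trial instances for descent and gradient audits, and one noise-free
  640-trial pointing-scale fit.

## Limitations

* Discrete task labels only; continuous task parameters are out of scope.
* No sparsity or smoothness penalties on modules.
* The multiplicative discriminative iteration has no global descent
  guarantee (a property of imposing the unit-sum constraint without
  compensation); the `als_qp` and `nlp` solvers exist precisely to check
  its solutions, and the tests assert cross-solver agreement.
* In-sample tuning of $(\gamma, \delta)$ by design: the tuning objective
  uses the same trials that were fitted. CLS on held-out trials is the
  guard against over-optimistic conclusions.
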