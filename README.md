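# synergizer

Space-by-time decomposition of muscle activity, with an optional
task-discrimination objective.

## The problem

Surface EMG recorded during repeated motor tasks is high-dimensional and
noisy, yet motor control appears to reuse a small repertoire of building
blocks — *muscle synergies*. The space-by-time model expresses every trial
`s` of muscle activity (a `T × M` matrix `Mˢ`: time steps × muscles) as

```
Mˢ ≈ W̃ Aˢ W
```

where the columns of `W̃` (`T × P`) are **temporal modules** (activation
waveforms over normalized movement time), the rows of `W` (`N × M`) are
**spatial modules** (weightings across muscles), both shared by all trials,
and `Aˢ` (`P × N`) holds the non-negative **activation coefficients** that
couple them in that trial. All factors are non-negative; each temporal
module (column of `W̃`) and each spatial module (row of `W`) sums to 1.

The reconstruction-only decomposition (**sNM3F**) minimizes

```
E²_NMF = Σₛ ‖Mˢ − W̃ Aˢ W‖²_fro .
```

When the task performed in each trial is known, the coefficients — the only
task-dependent part of the model — should also *separate* the tasks. The
discriminative extension (**DsNM3F**) adds a Fisher scatter penalty on the
vectorized coefficients,

```
E² = E²_NMF + γ·tr(S_w) − δ·tr(S_b),
```

with `S_w` the within-task and `S_b` the between-task scatter matrix, so the
fit balances data approximation against task discriminability. The package
provides three interchangeable solvers (multiplicative updates, constrained
alternating least squares with an optional strict-descent QP variant, and a
joint nonlinear program), the evaluation stack (VAF, leave-one-out LDA
decoding, the VDM trade-off score `VAF × DEC`, linear-SVM generalization on
held-out trials, Fisher ratio `J = tr(S_w)/tr(S_b)`, module similarity),
tuning of `(γ, δ)` and model order `(P, N)`, EMG preprocessing (envelope
extraction, time and amplitude normalization), plain-text I/O, and a
ground-truthed synthetic EMG generator for testing every claim without
recordings.

Audience: motor-control and biomechanics researchers decomposing
trial-structured EMG, and methodologists working on supervised non-negative
matrix factorization.

## Worked example

Simulate the benchmark dataset (4 tasks × 10 trials, 2 true temporal and 2
true spatial modules, 40 % additive-plus-multiplicative noise), then fit the
reconstruction-only and the discriminative decomposition and compare them:

```r
library(synergizer)

sim <- generate_emg(toy_synergy_spec(seed = 42))
sim$dataset
#> <emg_dataset> 40 trials, 2 time steps x 2 muscles
#>   tasks: 4 (1, 2, 3, 4)

opts <- fit_options(n_restarts = 20, seed = 1)
base <- fit_snm3f(sim$dataset, P = 2, N = 2, opts)
disc <- fit_dsnm3f(sim$dataset, P = 2, N = 2, gamma = 3, delta = 0.01,
                   options = opts)

compare_models(sim$dataset, base, disc, names = c("sNM3F", "DsNM3F"))$metrics
#> # A tibble: 2 × 7
#>   model    vaf   dec   vdm tr_sw tr_sb j_ratio
#>   <chr>  <dbl> <dbl> <dbl> <dbl> <dbl>   <dbl>
#> 1 sNM3F  1.000 0.575 0.575 54.5   2.63   20.8
#> 2 DsNM3F 0.621 1     0.621  3.32  2.57    1.29
```

Reading the numbers: on this tiny 2 × 2 design every trial has exactly as
many observations as coefficients, so the reconstruction-only fit absorbs
the measurement noise into the coefficients — near-perfect VAF but only
57.5 % of trials decodable from the coefficients (`dec`), and a large
within-task scatter (`tr_sw`). The discriminative fit trades VAF (0.62) for
perfect decoding (`dec = 1`), a 16-fold smaller within-task scatter, and a
much lower Fisher ratio `j_ratio` (smaller = better task separation). The
overall trade-off score `vdm = max(vaf, 0) × dec` still favors it. Both fits
recover the true generating modules exactly (pairing correlation `r = 1`,
see `recovery_score()`).

Results are tibbles throughout, so the usual verbs apply; `tidy()`,
`glance()` and `autoplot()` methods are provided for fits, tuning grids and
datasets. A thin command-line wrapper with `simulate | preprocess | fit |
select | decode | compare` subcommands is installed at
`inst/cli/emgsynergy.R`.

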