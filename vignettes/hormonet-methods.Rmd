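---
title: "Surrogate modelling and genetic optimization of tissue-culture hormone combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modelling and genetic optimization of tissue-culture hormone combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormonet)
library(dplyr)
```

## The problem

Micro-propagation of *Prunus* rootstocks (here the almond × peach hybrid
G × N15, "Garnem") hinges on the cytokinin–auxin balance of the culture
medium. Five growth regulators are screened in factorial combinations —
the cytokinins BAP, KIN and TDZ at 0–2 mg/l against the auxins IBA and
NAA at 0–0.15 mg/l — and four responses are scored after four weeks:
number of micro-shoots per explant (NS, also called the proliferation
rate), micro-shoot length (LS, cm), callus weight (CW, g; undesired) and
an ordinal plantlet quality index (QI, 0–5).

Factorial screens sample the dose–response surface coarsely. The approach
implemented here fits a neural-network surrogate to the screen, searches
the fitted surface with a genetic algorithm for the best hormone
combination (which generally falls *between* the tested doses), and ranks
the hormones by how much the model degrades when each is withheld.

## Data

`media_tables()` ships the five factorial tables (85 media in total:
20 + 20 + 15 + 15 + 15) with the per-medium mean, standard error and
replicate count for each trait — six replicates per medium in the two
BAP experiments, five elsewhere, each replicate a four-explant culture
unit. `validation_experiment()` ships the follow-up wet-lab experiment
that re-tested the optimized combinations; it is a comparison fixture
only and nothing in the package recomputes it.

One bookkeeping note: the narrative summary accompanying the second
factorial table calls the hormone-free control "the highest LS
(2.13 cm)" while the printed control row reads 2.67 (2.13 belongs to the
next row). The fixtures follow the printed table; the discrepancy is
recorded here and left unresolved.

## Regenerating replicate-level data

The original analysis used 465 replicate-level "data lines" (279 for
training, 186 for testing), which were never deposited; only the
per-medium mean ± SE survives. `expand_replicates()` therefore re-expands
each medium into its `n` replicates by sampling a truncated normal:

* scale: `se * sqrt(n)`, the replicate-level standard deviation implied
  by the standard error of the mean;
* truncation: each trait's physical range (NS, LS, CW ≥ 0; QI in [0, 5]);
* location: solved per cell (closed-form truncated-normal mean, root
  found by `uniroot()`) so that the truncated distribution's mean equals
  the printed mean exactly. Plain truncation would bias cells printed
  near a boundary with a large SE (a CW of 0.07 ± 0.12 would drift to
  roughly 0.24 g);
* NS quantization: each replicate is the mean count over four explants,
  so NS observations are rounded to the nearest 0.25 (`quantize_ns`,
  default on).

Normality is the minimal distributional assumption consistent with the
reported mean ± SE summaries and the original t-tests; it reproduces the
first two moments and nothing more. What the generator does *not*
emulate: between-replicate correlation within a culture vessel, batch
effects between experiments, and the discreteness of QI scoring. Tests
passing on these replicates therefore validate the pipeline's machinery
and its behaviour under the published noise levels — not biological
conclusions about real explants.

`split_dataset()` assigns `round(0.6 * n)` records to training by a
seeded uniform permutation; 465 records split exactly 279/186
(279/465 = 0.6). How the original 279/186 split was made is not stated;
a global shuffle is the default and a per-medium stratified option is
provided. All randomness is seed-controlled and reproducible.

```{r split}
ds <- media_tables() |>
  expand_replicates(seed = 1) |>
  split_dataset(seed = 2)
table(ds$.split)
```

## The surrogate network

Each trait gets its own single-hidden-layer feed-forward network: five
inputs (hormone concentrations, mg/l), a hyperbolic-tangent hidden layer,
one linear output unit,

$$\hat{y} = b_2 + \sum_j w_{2j} \tanh\!\Big(b_{1j} + \sum_i W_{1ji} x_i\Big).$$

Inputs and output are min–max normalized to $[-1, 1]$ on the training
rows only (a constant column maps to 0 and is flagged). Training is
damped Gauss–Newton (Levenberg–Marquardt) on the normalized scale with an
analytic Jacobian: a step is accepted only if it lowers the fit-set MSE,
the damping factor shrinks tenfold on acceptance and grows tenfold on
rejection, and training ends at a normalized MSE of 0.01, at 800 epochs,
or when the damping factor exceeds $10^{10}$ without an acceptable step.
Weights start from a seeded uniform draw on $[-0.5, 0.5]$.

Two protocol details deserve their rationale:

* **Hidden-layer size.** Not stated in the source protocol; the default
  is 10 units (71 parameters for 5 inputs), a conventional middle ground
  for a few hundred training rows, exposed as `n_hidden`.
* **Validation early stopping.** 15% of the training rows are held out;
  training keeps the weights from the epoch with the lowest validation
  MSE and stops after 50 epochs without improvement. Without this guard
  a fully converged unregularized network reproduces the design-point
  responses well but oscillates wildly *between* design points — the
  fitted NS surface can spike to hundreds of shoots per explant at
  off-grid hormone combinations, which destroys the optimization step
  even though test statistics at the design points look unremarkable.
  Early stopping against a held-out subset is the standard remedy in
  this network family. The patience is 50 rather than the customary 6
  because accepted Levenberg–Marquardt steps are few and large, so a
  short plateau fires long before the validation minimum; with patience
  50 stopping is governed by the minimum itself. `val_fraction = 0`
  restores plain full-convergence training.

Model adequacy is reported the way the original analysis reports it:
$R^2$ is the squared product-moment correlation between observed and
predicted values (so it is affine-invariant and identical on raw and
normalized scales), RMSE is the root mean square error in trait units,
and a two-sided paired t-test compares observed and predicted means.
Whether the original adequacy table lists t statistics or p-values is
ambiguous; `evaluate_surrogate()` reports both.

```{r train}
fit <- train_surrogate(ds, "ns", seed = 1)
evaluate_surrogate(fit, ds)
```

### What accuracy is attainable here?

The replicate noise implied by the printed standard errors puts a hard
ceiling on replicate-level test $R^2$: no model can explain the
within-medium scatter. A second, subtler cap comes from the tables
themselves: eleven hormone points recur across experiments with
*conflicting* printed means (the same (BAP 0, IBA 0.1, others 0) medium
is printed as NS 1.67 in the BAP × IBA table but 1.00 in the KIN × IBA
and TDZ × IBA tables — different experimental batches). A surrogate is a
single function of the hormone vector and must average such conflicts,
so its test accuracy on regenerated replicates sits slightly below the
per-row noise ceiling. Consequently the package's seeded runs land close
to, but not reliably above, the originally reported test accuracies
(NS 0.81, LS 0.87); the acceptance suite states those published values
as thresholds and records honestly whether a given seed reaches them.

## Genetic search over the surrogate

`ga_optimize()` is a real-coded generational GA: fitness-proportional
(roulette-wheel) parent selection on fitness shifted by
`f - min(f) + eps` (`eps = 1e-9 * (max - min + 1)` keeps the wheel
defined for negative and tied fitness), per-gene blend crossover at rate
0.85, per-gene uniform-reset mutation at rate 0.1, clipping to the
design bounds, one elite copied unchanged, 50 individuals, 500
generations — the published search settings. The chromosome holds only
the hormones of the subspace being optimized (`active`); all others are
pinned to 0, mirroring the five screened cytokinin–auxin combinations.
Callus weight is minimized (fitness negated internally); the other
traits are maximized. With elitism the best-so-far trajectory is
monotone, which every run asserts internally via its recorded history.

A dense grid search (`grid_optimize()`) over the same surrogate serves
as the deterministic reference optimizer in the tests.

Note that one row of the published optimization table is labelled
"KIN + IBA" while its nonzero columns are KIN and NAA; the package's
subspace masks follow the columns (`default_subspaces()`), and the label
is treated as a typo. Likewise the concluding section's "1.2 mg/l BAP"
disagrees with the abstract's 1.02 mg/l; the abstract value is taken as
authoritative.

## Hormone importance (VSE/VSR)

For each trait, `variable_sensitivity()` reports the variable
sensitivity error — the model's test RMSE when one input is unavailable —
and the variable sensitivity ratio VSR = VSE / (full-model test RMSE).
"Unavailable" defaults to retraining without the column, the most literal
reading; a cheaper fix-at-training-mean mode is available. Because a
single fit depends noticeably on its initialization, baseline and VSE are
averaged over seeded restarts (default 5), and the meaningful output is
the *rank order*, not the VSR magnitudes: those depend on the original
fitted weights and are not reproducible from summaries. Ranks are
assigned by descending VSR with alphabetical tie-break. Whether the
original VSE was computed on training, testing or pooled rows is not
stated; the test split is used here, matching how model adequacy is
judged.

## The pipeline

`run_pipeline()` chains the stages — expand, split, train each trait
(best of `n_restarts` seeded fits by test $R^2$; 3 by default to keep a
full run inside a few minutes on one core), evaluate, rank sensitivities,
optimize every trait × subspace — and writes tidy CSVs plus a JSON run
manifest. Everything is deterministic given the master seed. Failures
abort with a stage-named error and remove partial outputs.

Predicted responses *reported by the pipeline* are clamped to each
trait's physical scale (counts and weights at 0, QI at [0, 5]): the
network output is an unbounded linear unit, but a reported optimum lives
on the measurement scale, and the published QI optima print the 5.0
ceiling. Raw `predict()` output is never clamped.

The problem sizes used throughout the shipped tests — the full 465-row
dataset for acceptance checks, smaller generated sets for unit tests,
and reduced GA budgets for property checks — are chosen so the whole
suite completes in about a minute while still exercising the published
protocol at full scale where it matters.

## Numerical choices and degenerate inputs

* Damping schedule $\lambda_0 = 10^{-3}$, ×10 / ÷10, cap $10^{10}$ —
  conventional values; the protocol source gives none.
* Ties in `best_medium()` break toward the lowest experiment then media
  id; ties in sensitivity ranks break alphabetically — both purely for
  determinism.
* A constant trait column is an error (no model, no sensitivity); a
  constant *input* column normalizes to 0, is flagged degenerate, and
  contributes nothing to the fit.
* `r_squared()` refuses constant vectors, `paired_t_pvalue()` refuses
  zero-variance differences — both undefined.
* The published RMSE formula omits the radical sign as printed; the
  name and units of the reported values require the square root, which
  is applied.
* Serialization (`write_surrogate()`/`read_surrogate()`) stores weights
  at full precision in versioned JSON; restored models predict
  identically.

## Known limitations

* The surrogate interpolates a 5-D surface from observations lying on
  five 2-D coordinate slices; predictions for combinations of three or
  more simultaneous nonzero hormones are extrapolations with no data
  support.
* The generator cannot restore information the summaries destroyed:
  replicate-level correlations, batch effects, and any non-normality.
* VSR magnitudes are initialization-noisy even after restart averaging;
  only ranks should be interpreted.
* GA results on a freshly trained surrogate inherit the surrogate's
  seed-to-seed variability; the shipped protocol reports the median over
  a GA seed ensemble on a fixed surrogate.
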