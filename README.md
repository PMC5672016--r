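# hormonet

Neural-network surrogate modelling and genetic-algorithm optimization of
cytokinin–auxin combinations for *in vitro* proliferation of the
G × N15 (*Prunus*) rootstock.

Plant tissue-culture screens test hormone combinations on a coarse
factorial grid. `hormonet` is for researchers who want to squeeze more
out of such a screen: it fits a feed-forward neural network to the
dose–response tables, searches the fitted surface with a genetic
algorithm for the optimal hormone combination (usually *between* the
tested doses), and ranks the hormones by importance. The five shipped
factorial tables cover the cytokinins BAP, KIN and TDZ (0–2 mg/l)
crossed with the auxins IBA and NAA (0–0.15 mg/l), scored for four
responses: micro-shoots per explant (NS), shoot length (LS, cm), callus
weight (CW, g) and a 0–5 plantlet quality index (QI).

## The method

Each trait is modelled by a single-hidden-layer network with tanh hidden
units and a linear output,

    ŷ = b₂ + Σⱼ w₂ⱼ · tanh(b₁ⱼ + Σᵢ W₁ⱼᵢ xᵢ),

with inputs and output min–max normalized to [−1, 1] on the training
rows. Training is Levenberg–Marquardt (damped Gauss–Newton with analytic
Jacobian; steps accepted only if the fit MSE drops) to a normalized MSE
goal of 0.01 or 800 epochs, with validation-based early stopping.
Replicate-level data are regenerated from the published mean ± SE
summaries by a moment-matched truncated normal (465 records, split
279/186 train/test). Model adequacy is reported as R² (squared
product-moment correlation), RMSE and a paired t-test.

The fitted surrogate becomes the fitness function of a real-coded GA
(population 50, 500 generations, roulette-wheel selection, blend
crossover at 0.85, per-gene uniform-reset mutation at 0.1, one elite),
restricted to one cytokinin–auxin subspace with the other hormones
pinned to 0. Hormone importance is ranked by the variable sensitivity
ratio VSR = VSE / baseline error, where VSE is the test RMSE after
retraining without that hormone.

## Worked example

```r
library(hormonet)

# best observed medium for shoot number in the BAP x IBA experiment
best_medium(media_tables(experiment = 1), "ns")[, c("media_id", "bap", "iba", "value")]
#> # A tibble: 1 × 4
#>   media_id   bap   iba value
#>      <dbl> <dbl> <dbl> <dbl>
#> 1       11     1   0.1  10.7

# regenerate the 465 replicate records and split 279/186
ds <- media_tables() |> expand_replicates(seed = 1) |> split_dataset(seed = 2)

# train the shoot-number surrogate and evaluate both splits
fit <- train_surrogate(ds, "ns", seed = 4)
evaluate_surrogate(fit, ds)
#> # A tibble: 2 × 7
#>   trait split     n r_squared  rmse  t_stat t_p_value
#>   <chr> <chr> <int>     <dbl> <dbl>   <dbl>     <dbl>
#> 1 ns    train   279     0.837 0.944  0.0276     0.978
#> 2 ns    test    186     0.758 1.30  -0.760      0.448

# search the BAP + IBA subspace for the optimal combination
opt <- ga_optimize(fit, active = c("bap", "iba"), seed = 11)
opt
#> <ga_result> maximize bap+iba -> 10.98 at bap=1.14, iba=0.0996 (500 generations)

# rank hormone importance for shoot number
variable_sensitivity(ds, "ns", n_restarts = 3, seed = 1)
#> <sensitivity_report> trait=ns baseline RMSE=1.431 (3 restarts, retrain)
#> # A tibble: 5 × 4
#>   hormone   vse   vsr  rank
#>   <chr>   <dbl> <dbl> <int>
#> 1 bap      2.45 1.71      1
#> 2 kin      2.03 1.41      2
#> 3 tdz      1.57 1.10      3
#> 4 iba      1.42 0.992     5
#> 5 naa      1.54 1.07      4
```

Reading the output: the screen's best observed NS medium is 1 mg/l BAP +
0.1 mg/l IBA at 10.67 shoots/explant; the surrogate reaches a test-set
R² of 0.76 against replicate-level noise; the genetic search places the
optimum just off-grid at 1.14 mg/l BAP + 0.10 mg/l IBA with a predicted
11.0 shoots/explant; and BAP, then KIN, matter most for shoot number.
`run_pipeline()` chains all of this for every trait and subspace and
writes tidy CSV reports; `autoplot()` methods draw observed-vs-predicted,
GA-history and importance figures. See the methods vignette
(`vignettes/hormonet-methods.Rmd`) for the model, its assumptions and
its limitations.

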