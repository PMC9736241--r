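# barncast

Short-horizon forecasting of air humidity in intensive livestock barns from
multivariate environmental sensor series (temperature, CO₂, particulates,
light, noise, NH₃, H₂S — sampled every 10 minutes).

Humidity in closed winter barns drives mold and parasite load, so herd
managers want it predicted 10–90 minutes ahead. The series are nonlinear
and strongly coupled, and only a few thousand records are typically
available, which favours a compact hybrid over deep networks. `barncast`
implements that hybrid end to end:

1. **GOSS feature screening** — gradient-boosted shallow regression trees
   with gradient-based one-side sampling: each round keeps all
   large-gradient samples and a random `p` fraction of the rest,
   re-weighted by `(1 − o)/p` inside the split gain
   `Ṽ_m(d) = (1/n)·[(Σ_left w h)²/n_left + (Σ_right w h)²/n_right]`.
   Summed chosen gains rank the sensors; the top-k (default 4) become the
   model inputs.
2. **Chaotic grey wolf optimisation (CGWO)** — a bound-constrained
   minimiser where candidate solutions move toward the three best pack
   members. The chaotic variant replaces the random attraction coefficient
   `C = 2·r₂` with deterministic iteration schedules `C₁, C₂, C₃`
   (exponential ramps plus a `1.4·sin(n)/30` perturbation), giving a
   reproducible exploration/exploitation sweep.
3. **ε-SVR prediction** — RBF kernel `exp(−‖mᵢ − mⱼ‖²/g²)`; the optimizer
   tunes `(C, g, ε) ∈ [0.01, 10]³` against forward-chaining
   cross-validated RMSE on the training block, and the tuned model is
   evaluated on a chronological 70/30 hold-out with MAE, RMSE, MSE,
   NRMSE = RMSE/mean and the explained-variance-ratio R².

The SVR dual is solved by a compiled SMO solver shipped with the package
(validated against scikit-learn's `SVR` in the test suite). Because the
original barn dataset is not public, the package includes a synthetic
generator with the same schema and a coupled humidity process, so every
stage is testable offline.

## Worked example

```r
library(barncast)
report <- run_pipeline(pipeline_config(n_rows = 2000, seed = 1))
print(report)
#> humidity forecasting pipeline (horizon 1 steps)
#> selected features: air_temp, light, co2, noise
#> tuned hyperparameters: C=1.1728 g=9.8701 eps=0.0710
#> cgwo_svr      MAE 0.3978  RMSE 0.5024  MSE 0.2524  NRMSE 0.0063  R2 0.9474
#> svr_default   MAE 2.6660  RMSE 3.0171  MSE 9.1027  NRMSE 0.0377  R2 0.0231
```

The run generates a 2000-row synthetic table, repairs it, ranks the nine
non-target sensors by GOSS gain on the training block (three of the four
true humidity drivers — temperature, light, CO₂ — top the ranking), tunes
`(C, g, ε)` with 20 wolves over 20 iterations, and scores the held-out 30%
in original humidity units (%). The tuned model's RMSE of 0.50 percentage
points versus 3.02 for the untuned default `(C, g, ε) = (1, 0.1, 0.1)`
shows what the optimisation stage buys; NRMSE is RMSE relative to mean
humidity (~80%), and R² is the explained-variance ratio.

The same pipeline is scriptable:

```sh
exec/barn-cgwo generate --n-rows 2000 --seed 1 --outdir out/
exec/barn-cgwo run --horizon 30 --k-features 4 --variant cgwo --outdir out/
```

writing importance, hyperparameter, metrics, trace and prediction CSVs plus
a log into `--outdir`.

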