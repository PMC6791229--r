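# greycast

Forecasting tools for very short annual incidence series, built on grey
systems theory. The package exists for settings like national
occupational-disease surveillance, where a modeller may have a dozen annual
case counts and nothing else: too little data for ARIMA-style time-series
models or feature-hungry machine learning, but enough for grey models, which
are designed for "poor information" systems with small samples.

## The method

**Stage 1 — grey models.** Let `x0 = (x0(1), …, x0(n))` be the positive raw
counts and `x1` its cumulative sum (the accumulated generating operation,
AGO). Five GM(1,1)-family models are estimated by ordinary least squares on
their defining difference forms (`z` is the mean-generated background value,
`z(k) = (x1(k) + x1(k−1))/2`):

| model | estimation form | prediction rule |
|---|---|---|
| EGM  | `x0(k) = −a·z(k) + b` | whitening solution `x1̂(k) = (x0(1) − b/a)e^(−a(k−1)) + b/a` |
| EDGM | same `(a, b)` as EGM | recursion `x1̂(k) = ((1 − a/2)x1̂(k−1) + b)/(1 + a/2)` |
| ODGM | `x0(k) = −a·x1(k) + b` | recursion `x1̂(k) = (x1̂(k−1) + b)/(1 + a)` |
| DGM  | `x1(k) = β1·x1(k−1) + β2` | the same linear recursion from `x1̂(1) = x0(1)` |
| Verhulst | `diff(x)(k) = −a·z(k) + b·z(k)²` on the raw series | logistic response `x̂(k) = a·x(1)/(b·x(1) + (a − b·x(1))e^(a(k−1)))` |

The first four restore predictions to the original scale by inverse
accumulation (first differencing); the Verhulst model treats the raw series
itself as the S-curve state and reports its logistic response directly. All
five preserve the first observation exactly. ODGM, EDGM and DGM reproduce
homogeneous exponential sequences `q·r^(k−1)` exactly — a property the test
suite exercises.

**Stage 2 — hybrid models.** The five grey models' fitted values (training
years) and forecasts (held-out years) form a 5-column feature matrix with
the actual counts as labels. Second-stage regressors — k-nearest neighbours,
support vector regression (four kernels), random forest, gradient boosting
and a single-hidden-layer neural network — are trained on the training rows
and compared on the held-out years by MAPE and RMSE (errors signed as
`actual − forecast`).

## Worked example

The bundled series is the annual number of newly reported occupational
diseases in China, 2005–2017, with the number of reporting provinces per
year:

```r
library(greycast)
series <- china_occupational()
split  <- split_series(series)          # 10 training years, 3 testing years
fits   <- fit_all_grey(split$train)
grey_table(fits, series)
#>    year actual   EGM  EDGM  ODGM   DGM Verhulst
#> 1  2005  12212 12212 12212 12212 12212    12212
#> 2  2006  11805 14255 14268 14136 14415    14677
#> ...
#> 13 2017  25114 44366 44452 44851 44009    33649
```

Rows 2005–2014 are in-sample fitted values; 2015–2017 are out-of-sample
forecasts. The four exponential-type models all extrapolate the 2005–2014
growth and overshoot the flat 2015–2017 counts badly, the saturating
Verhulst model less so, which the accuracy table quantifies:

```r
accuracy_table(fits, split)
#>                label    model    group        ME     RMSE      MAE    MPE  MAPE  n
#> 1       EGM_training      EGM training   -194.98  3301.76  2721.90  -4.14 13.02 10
#> 2        EGM_testing      EGM  testing -12710.28 13539.22 12710.28 -47.51 47.51  3
#> ...
#> 10  Verhulst_testing Verhulst  testing  -5730.92  6113.09  5730.92 -21.53 21.53  3
```

Negative ME/MPE means over-prediction. The hybrid stage then trains the
second-stage regressors on the grey features:

```r
hd <- build_features(fits, split)
train_predict(regressor_spec("knn", k = 2, weighting = "inverse"), hd)
#> Hybrid result knn (k=2, inverse) on features {EGM, EDGM, ODGM, DGM, Verhulst}
#>   training MAPE 0.00%, RMSE 0.00 | testing MAPE 7.49%, RMSE 2189.49
```

(The zero training error is structural: each training point is its own
zero-distance neighbour, whose inverse-distance weight dominates.) The full
nine-configuration comparison, subset search over all 31 grey-feature
subsets, and selection by testing MAPE/RMSE:

```r
ex <- run_hybrid_experiment(series)
ex$best
#> Hybrid result rf on features {EGM, EDGM, ODGM, DGM, Verhulst}
#>   training MAPE 6.21%, RMSE 1473.21 | testing MAPE 6.87%, RMSE 2060.99
subset_search(fits, split, regressor_spec("knn"))$ranking[1:3, ]
#>          subset size test_MAPE test_RMSE train_MAPE
#> 1      Verhulst    1  7.469565  2216.892          0
#> 2 ODGM+Verhulst    2  7.479900  2188.588          0
#> 3  EGM+Verhulst    2  7.480202  2188.881          0
```

Even the best hybrid roughly halves the held-out MAPE of the best single
grey model (Verhulst, 21.5%) — the core argument for the two-stage scheme.
Note that the selected family and the neural network's held-out error are
restart- and seed-sensitive on 10 training points; the methods vignette
discusses this instability in detail.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/greycast`:

```sh
Rscript inst/scripts/greycast fit-gm --fixture china --out results/
Rscript inst/scripts/greycast fit-hybrid --families knn,ann --seed 7 --out results/
Rscript inst/scripts/greycast synth --kind logistic --n 30 --capacity 100 --out s.csv
```

## Unstated-parameter conventions

The support-vector constants (`cost = 1`, `epsilon = 0.1`, `degree = 3`,
`coef0 = 0`, kernel `gamma = 1/p`) and the neural network's scaling
(min-max to `[0, 1]`, logistic output, best-of-50 restarts by training RMSE)
are documented package conventions where the underlying analysis left
details unstated; see the methods vignette.

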