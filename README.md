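# driftcor

Short-term spike-count noise correlations, estimated unbiasedly under
arbitrary baseline drift.

## The problem

Noise correlations — correlations of the trial-to-trial fluctuations of
two neurons' spike counts around their mean stimulus response — shape the
coding capacity of neural populations, but their measurement is
confounded by nonstationarity. A slowly drifting baseline makes two
neurons' counts co-vary across a session even when their within-trial
noises are independent, so the conventional Pearson coefficient mixes a
*short-term* (simultaneous) component with a spurious *long-term*
(co-drift) component. driftcor is for electrophysiologists and
statisticians who need the short-term component alone, with calibrated
significance tests, from nothing more than a pair of trial-ordered count
series.

## The estimator

For per-trial activities $x_t, y_t$ modelled as Gaussian with constant
noise covariance $\Sigma$ and an arbitrary, unknown baseline drift that
is (approximately) equal on consecutive trials, the semiparametric
estimating-equation solution is local pairwise detrending: with
within-pair differences $\Delta x_t = x_{2t-1} - x_{2t}$ over pairs
$\{1,2\},\{3,4\},\dots$,

$$\hat\Sigma_{11} = \tfrac{1}{N}\sum_t \Delta x_t^2,\quad
  \hat\Sigma_{12} = \tfrac{1}{N}\sum_t \Delta x_t \Delta y_t,\quad
  \hat\rho = \frac{\hat\Sigma_{12}}{\sqrt{\hat\Sigma_{11}\hat\Sigma_{22}}}.$$

$\hat\rho$ is unbiased for the noise correlation whatever the drift, and
the per-pair covariance statistic attains the minimum-variance bound
$\Sigma_{11}\Sigma_{22} + \Sigma_{12}\Sigma_{21}$ among drift-robust
estimators. Significance comes from a Monte-Carlo null distribution of
$\hat\rho$ under white Gaussian noise (exact by location/scale
invariance), a serial-correlation test on block-averaged series flags
nonstationary neurons, and comparator implementations (trial-shifted
Pearson correlograms, moving-average residuals, a maximum-likelihood
Kalman state-space detrender) reproduce the benchmark orderings. A
session simulator (40 blocks x 16 stimuli, 1.0–1.7 s trials) and
linear-discriminant decoding schemes dissociate the impacts of
short-term and long-term correlations on stimulus decoding.

## Worked example

Two neurons whose baselines wander independently as integrated ARIMA
processes, with a genuine simultaneous noise correlation of 0.3:

```r
library(driftcor)

trend_x <- simulate_trend(trend_spec("arima021", n = 100), seed = 8)
trend_y <- simulate_trend(trend_spec("arima021", n = 100), seed = 9)
pair <- simulate_pair(trend_x, trend_y, noise_spec(rho = 0.3), seed = 10)

pearson_correlation(pair$x, pair$y)
#> [1] 0.7372
short_term_correlation(pair$x, pair$y)
#> [1] 0.2939

null <- build_null_distribution(100, reps = 1e5, seed = 11)
short_term_test(pair$x, pair$y, null, alpha = 0.01)
#> <test_result> short_term_mc: statistic=0.2939 p=0.03532 significant=FALSE
```

The conventional coefficient (0.74) is dominated by the co-wandering
baselines; the local estimator recovers the planted 0.3. The Monte-Carlo
test refers the estimate to its exact finite-sample null — here a single
100-trial realization gives p = 0.035, genuine but not significant at
the strict 0.01 level, which is the honest reading of one short series.
The trial-shifted correlogram localizes the correlation at the origin:

```r
cross_correlogram(pair$x, pair$y, 4, "proposed")
#> <correlogram> method=proposed, lags -4..4
#>      -4      -2       0       2       4
#>  0.2644  0.0768  0.2939 -0.1943 -0.0389
```

A command-line front end over the same functions lives at
`inst/cli/driftcor.R` (subcommands `simulate`, `estimate`, `correlogram`,
`test`, `nonstationarity`, `benchmark`, `decode`).

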