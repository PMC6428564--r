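Package: driftcor
Title: Short-Term Spike-Count Noise Correlations Under Baseline Drift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of short-term (within-trial) spike-count noise
    correlations between simultaneously recorded neurons that is unbiased
    under arbitrary slow baseline drift. Implements the local pairwise
    detrending covariance estimator for the semiparametric Gaussian model
    with a nuisance drift distribution, a Monte-Carlo significance test
    with an empirical null distribution, a lag-one serial-correlation
    nonstationarity test with block averaging, conventional comparator
    methods (trial-shifted Pearson correlograms, moving-average residual
    correlations, a scalar-latent Kalman state-space residual method fitted
    by maximum likelihood), simulators for drifting-baseline benchmark data
    and full stimulus-structured sessions, and linear-discriminant decoding
    analyses that dissociate the impacts of short-term and long-term
    correlated variability.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
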