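# buildtail

Fitting and evaluation of a two-parameter empirical model of megavoltage
photon percent-depth-dose (PDD) curves, and of the collimator-scatter-factor
(S_c) models built on its parameters — a toolkit for beam-commissioning QA
and independent monitor-unit double-checks in radiotherapy physics.

## The model

A central-axis PDD scan is described as the product of a quadratic *buildup*
term and an exponential *tail*:

```
PDD(d) ∝ d / (d² + n) · exp(−μ d)
```

where `d` is depth in water (cm), `n` is a beam-hardening parameter (larger
for harder beams: less surface dose, deeper dose maximum) and `μ` (1/cm) is
an effective linear attenuation coefficient governing the tail slope. The
curve peaks at the unique positive root of `μd³ + d² + μnd − n = 0`
(exactly `√n` when `μ = 0`). Two derived S_c parameterizations are provided:

- a square-field power law `S_c(FS) = n_E · FS^(0.63 μ_E)` calibrated
  per energy to a measured S_c table, optionally constrained so
  `S_c(10) = 1` at the reference field;
- an asymmetric-jaw law `S_c = A · (U^w_u · L^w_l)^p` whose unequal jaw
  weights reproduce the collimator exchange effect (swapping upper and
  lower jaw settings changes the output).

The package covers model evaluation and depth-of-maximum location,
deterministic nonlinear least-squares fitting to measured scans,
measured/modeled comparison reports with percent-error columns, S_c
calibration and prediction, a synthetic-scan generator with known ground
truth for validation, packaged reference tables from published
commissioning data, and a command-line interface.

## Worked example

```r
library(buildtail)

p6 <- load_fixture("table2")$`6MV`     # published 6 MV parameters
p6
#> Buildup-tail beam parameters: n = 0.208, mu = 0.0515 /cm, amplitude = 1

d_max(p6)
#> [1] 0.4457187                        # depth of maximum, cm

as.data.frame(evaluate_pdd(p6, c(0.5, 1.5, 5, 10, 20)))
#>   depth_cm pdd_percent
#> 1      0.5   99.326829
#> 2      1.5   52.735766
#> 3      5.0   14.313502
#> 4     10.0    5.566485
#> 5     20.0    1.665582

# calibrate the square-field power law to the measured 6 MV Sc table
fit <- sc_square_fit(load_fixture("table3_6MV"))
fit$model
#> Sc square-field power law: n_E = 0.92685, mu_E = 0.0517971, k = 0.63
fit$max_abs_dev_pct
#> [1] 0.5302308                        # worst deviation, percent

# collimator exchange effect from the measured jaw matrix
exchange_effect(load_fixture("table4"), 15, 10)
#> [1] 0.0055
```

The depth-dose values are the model normalized to 100 % at its own maximum;
the calibrated power law reproduces every measured 6 MV S_c value (field
sizes 4–40 cm) to within 0.53 %, and the positive exchange effect shows the
upper jaw dominating the head-scatter response.

A `fit_pdd()` call on a measured scan returns fitted `(n, μ, amplitude)`,
a depth-by-depth comparison table and summary error statistics; with the
packaged synthetic generator (`gen_scan()`) the fitter recovers known
parameters to well under 2 % at realistic scan noise.

## Command line

A thin wrapper is installed at `inst/cli/buildtail`:

```sh
Rscript inst/cli/buildtail predict-sc --upper 15 --lower 10
Rscript inst/cli/buildtail simulate --n 0.208 --mu 0.0515 --noise-sd 0.2 --seed 1 --output scan.csv
Rscript inst/cli/buildtail fit-pdd --input scan.csv --output fit.json --report report.tsv
```

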