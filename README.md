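# indirectRI

Indirect reference-interval (RI) estimation from mixed hospital laboratory
data, for clinical-chemistry and laboratory-medicine informatics work.

A reference interval is the central 95% range (2.5th–97.5th percentile) of
an analyte in a healthy population. Direct establishment needs a recruited
healthy cohort; *indirect* methods instead estimate the healthy component
from the mixed healthy/diseased results already stored in a laboratory
information system (LIS). This package implements three such estimators
behind one shared model — a **Box-Cox-Gaussian** healthy component
(transform `y = (x^λ − 1)/λ`, Gaussian `(μ, σ)` on the transformed scale),
whose reference limits are the closed-form percentiles
`inv_boxcox(μ ± 1.959964·σ, λ)`:

* **`fit_hoffman()`** — computerised Hoffman: weighted least-squares on the
  central linear segment of the cumulative normal-probability plot,
  extrapolated to the 2.5%/97.5% normal quantiles, with a reproducible
  widest-window-at-R² segment rule in place of the traditional visual
  judgement.
* **`fit_kosmic()`** — truncated Box-Cox-Gaussian fitting: truncated-normal
  maximum likelihood over a grid of truncation windows (sample quantiles)
  and Box-Cox powers, selecting the fit with the smallest
  (inside-fraction-penalised) Kolmogorov-Smirnov distance.
* **`fit_refiner()`** — inverse modelling: principal-peak and search-region
  detection, then a multi-level grid search over `(λ, μ, σ, P)` — `P` being
  the fraction of results attributed to the non-pathological component —
  against a one-sided binned χ² cost; percentile bootstrap confidence
  intervals via **`bootstrap_ci()`** (200 replicates by convention).

Around them: `read_lis_csv()` / `write_lis_csv()` for LIS-style CSV exports
(adult 18–87 age filter by default, drop-log included), a fully specified
synthetic-data generator with known ground truth (`synthetic_spec()`,
`tsh_like_preset()`, `generate_lab_data()`), and `run_comparison()`, which
fits all three methods and tabulates them against a manufacturer (IFU)
range with per-limit deviations and verdicts. Fits come with `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(indirectRI)

spec   <- tsh_like_preset(n = 20000, seed = 42)  # 30% pathological TSH mixture
series <- generate_lab_data(spec)
series
#> <measurement_series> TSH [mIU/L]: n = 20000, decimals = 1
#>   sample quantiles 2.5/50/97.5%: 0.1 / 2.6 / 70.5
ground_truth_ri(series)
#> <reference_interval>  0.5328 - 7

fit_kosmic(series)
#> <kosmic_fit> TSH: lambda = 0.192, mu = 0.758461, sigma = 0.797566
#>   truncation 0.4 - 6 (68% of data inside), KS = 0.02398
#> <reference_interval: kosmic>  0.4172 - 6.821

report <- run_comparison(series, ifu_range("TSH", 0.38, 4.28))
as.data.frame(report)[, c("method", "lower", "upper", "verdict")]
#>    method     lower    upper          verdict
#> 1 hoffman 0.0500000 4.686418 lower-discordant
#> 2  kosmic 0.4172144 6.820958 upper-discordant
#> 3 refiner 0.2538729 6.247200  both-discordant
```

Reading the output: the mixture's healthy component implies a true interval
of 0.533–7.00 mIU/L. The truncated-KS fit recovers the upper limit within
3% despite 30% contamination; Hoffman, fitting a straight line to a
distribution whose healthy 97.5th percentile is 3.4× its median, truncates
its negative extrapolated lower limit and lands far below on the upper
limit. Against the kit-insert range 0.38–4.28 the automated methods are
flagged `upper-discordant` — their fitted healthy upper limits (6.2–6.8)
sit well above the manufacturer's 4.28, the characteristic behaviour of
automated indirect methods on skewed tertiary-care TSH data.

A thin CLI wraps the same functions:

```sh
exec/indirect-ri simulate --out data.csv
exec/indirect-ri fit --method all --input data.csv --analyte TSH --out result.json
exec/indirect-ri compare --input data.csv --analyte TSH \
    --ifu-lower 0.38 --ifu-upper 4.28 --out report.csv
```

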