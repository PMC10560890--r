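# ctcstab

Statistical evaluation of vaccine stability under real-time cold-chain
storage (RT, 2–8 °C) and extended controlled temperature conditions
(ECTC, 40 °C), culminating in a **minimum release potency (MRP)** — the
content a lot must have at release so that, after the labelled
shelf-life plus a permitted out-of-cold-chain excursion and after a
statistical uncertainty allowance, it still meets the lower limit LL.

The package is aimed at biostatisticians and CMC/regulatory scientists
preparing a controlled-temperature-chain (CTC) label claim: it covers
the study-design containers and CSV I/O, a calibrated synthetic
stability-data generator, the log-scale regression-assumption
diagnostics (mean–range transform selection, Shapiro–Wilk,
Breusch–Pagan, White, Durbin–Watson, influence measures, partial-residual
linearity), ICH Q1E batch-poolability F-tests at α = 0.25, stability
evaluation via the 95 % confidence band of the mean regression line, and
the MRP calculation.

## The model

Antigen content decays log-linearly. With slopes per month on the
natural-log scale, the release specification for `t` months at 2–8 °C
followed by `d` days at 40 °C is

```
MRP = exp[ log(LL) − ( t·b_2–8 + (d/30)·b_ECTC − U ) ]
U   = k · sqrt( (t·se_2–8)² + ((d/30)·se_ECTC)² + s² )
```

where `U` is the combined uncertainty: coverage factor `k` (1.645,
one-sided 95 % normal) times the root sum of squares of the
slope-estimation terms and a residual-variability term `s²` (by default
the average of the RT and pooled-ECTC residual variances). Positive
(improving) slopes are conservatively clamped to zero; estimated
negative slopes are used as they are.

## Worked example

```r
library(ctcstab)

# one synthetic study from the calibrated mock preset
ds <- simulateDataset(mockSimParams(seed = 1))
ds
#> StabilityDataset: 357 assay results of antigen content (LEU)
#>   lots: 24 | RT results: 123 | ECTC results: 234
#>   lower limit: 800 LEU

fitStability(ds, "RT")
#> RegressionFit (reduced2): slope -0.004215 (SE 0.000282) per month,
#>   residual SD 0.0238, n = 123, df = 121

testPoolability(ds, "RT")
#> PoolabilityResult: p(slope) = 0.9480, p(intercept) = 0.6657
#>   -> one_line (reduced2 model)

evaluateStability(fitStability(ds, "RT"), lowerLimit = 800)
#> StabilityEvaluation over [0, 24]: PASS (LL = 800, 95% band)

# the MRP for 24 months cold chain + 14 days at 40 C, using the
# reference pooled-model coefficients
computeMRP(mrpScenario(t28 = 24, tEctcDays = 14, lowerLimit = 800),
           b28 = -0.003723, bEctc = -0.117480, U = 0.0462)
#> MRPResult [scenario]: 24 months RT + 14 days ECTC, LL = 800
#>   -> MRP = 967.8 (U = 0.0462)
```

Reading: the generated study's RT slope (−0.0042/month) is recovered
close to the preset truth (−0.003723); lots pool into one line (both
poolability p-values far above 0.25); the 95 % lower confidence bound
stays above 800 LEU through month 24, so a 24-month shelf-life is
supported; and a lot released at ≈ 968 LEU still meets 800 LEU after the
full shelf-life plus a 14-day excursion, uncertainty included.

`runFullAnalysis(ds, analysisConfig())` chains every stage and returns a
deterministic report bundle, including the 10-row MRP scenario grid
(pooled and conditioning-month subsets × 3/14 days);
`writeReport(bundle, "report.json")` serialises it.

## Command line

```sh
Rscript inst/cli/ctcstab.R simulate --seed 7 --out data.csv
Rscript inst/cli/ctcstab.R diagnose data.csv --condition RT --report diag.json
Rscript inst/cli/ctcstab.R pool data.csv --condition RT --out pool.json
Rscript inst/cli/ctcstab.R evaluate data.csv --condition RT --ll 800 --out eval.json
Rscript inst/cli/ctcstab.R mrp data.csv --ll 800 --days 3,14 --out mrp.csv
Rscript inst/cli/ctcstab.R report data.csv --out report.json
```

See `vignettes/stability-mrp.Rmd` for the full account of the model,
the generator's calibration, the uncertainty-policy reconstruction and
the package's design choices.
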