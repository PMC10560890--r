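---
title: "Evaluating vaccine stability and deriving a minimum release potency"
author: "ctcstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating vaccine stability and deriving a minimum release potency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcstab)
```

## The problem

Most vaccines are licensed for storage at 2–8 °C. A controlled temperature
chain (CTC) label allows a single excursion outside the cold chain — here a
stay at 40 °C of up to 14 days, the "extended controlled temperature
conditions" (ECTC) — immediately before administration. Supporting such a
label requires showing two things from stability data:

1. the stability-indicating parameter (here antigen content, in assay
   units "LEU") stays above its lower limit LL over the labelled storage
   plus excursion, and
2. a **minimum release potency (MRP)**: the content a lot must have at
   release so that, after decaying through the full shelf-life and the
   excursion *and* after subtracting a statistical uncertainty allowance,
   it still meets LL.

`ctcstab` implements the full statistical pipeline: study containers and
CSV I/O, a calibrated data generator, regression-assumption diagnostics,
ICH Q1E batch-poolability testing, confidence-band stability evaluation,
and the MRP calculation.

## The decay model

All modelling is on the natural-log scale, where exponential decay is
linear. For lot $i$:

$$\log Y_{ij} = \mu + a_i + b_{2\text{–}8}\, t_{ij} + \varepsilon_{ij}$$

under cold-chain (RT) storage, with $t$ in months, and

$$\log Y = \mu + a_i + b_{2\text{–}8}\, m + b_{ECTC}\, d/30 + \varepsilon$$

for a lot conditioned $m$ months at 2–8 °C and then held $d$ days at
40 °C. Slopes are per month; ECTC days are converted with a fixed 30-day
month. The lot effect $a_i \sim N(0, \sigma_a^2)$ captures release-level
variability; residuals are iid Gaussian per assay result with separate
SDs per temperature. The log transform is selected empirically by the
mean–range criterion (`meanRangeTable()`): the transform whose
per-timepoint range is least related to the per-timepoint mean. Assay
noise that scales with the mean (the usual behaviour of content assays)
selects the log; purely additive noise would select the identity.

## The study design and the synthetic generator

The built-in design (`mockStudyDesign()`) follows the reference mock
study: 24 lots assayed at months 0/3/6/9/12/18/24 with 24, 12, 24, 12,
24, 12 and 15 lots per timepoint (123 RT results), and ECTC series at
days 0/3/7/10/12/14 for 12 lots exposed after 0, 6 and 12 months of
conditioning plus 3 lots exposed after 24 months (234 results). Lots are
assigned to cells in roster order, which reproduces the marginal counts;
the true lot-to-cell allocation of the reference study is not recorded.

`simulateDataset()` draws studies from the decay model above. The
`mockSimParams()` preset uses the reference study's fitted pooled
coefficients as generative truth — RT slope $-0.003723$/month with
residual SD $0.0271$, ECTC slope $-0.117480$/month with residual SD
$0.0250$ — because the underlying raw data are not available and the
fitted values are the best estimate of the generating process. Two
quantities are not reported anywhere and were fixed once:

* **mean log release content** $\mu = \log(1000)$, placing trajectories
  comfortably above LL $= 800$ as in the reference study's summary
  figures;
* **lot intercept SD** $\sigma_a = 0.005$ (≈0.5 % CV). The reference
  study found its lots poolable (one line) and its pooled-model
  residuals free of autocorrelation; a large lot effect would contradict
  both, because lot-level shifts masquerade as within-lot residual
  correlation (Durbin–Watson $d \approx 2(1-\rho)$ with
  $\rho = \sigma_a^2/(\sigma_a^2+\sigma_e^2)$). The chosen value keeps
  $\rho \approx 0.03$.

The ECTC starting level of a lot is its *noise-free* RT trajectory at
the conditioning month, so the two decay phases compose exactly as the
MRP formula assumes. There is no replicate-level variance component
beyond the residual (none is estimable from the reference outputs), and
no Arrhenius-type link between the two temperatures.

What the generator does *not* emulate: assay-run batch effects, outliers
and transcription errors, non-linear (e.g. initial-drop) decay shapes,
and censoring at the assay's limits. Passing tests on generated data
therefore validate the statistical machinery under the stated model, not
the behaviour of any real product.

## Assumption diagnostics

`runDiagnostics()` applies the standard battery to a log-scale fit:

* **Shapiro–Wilk** (`normalityTest()`) on residuals, 3–5000 observations.
* **Breusch–Pagan** (`breuschPagan()`), studentized (Koenker) form by
  default, and **White** (`whiteTest()`), which augments the auxiliary
  regression with the squared time term. Both need ≥ 2 residual df, and
  White needs ≥ 3 distinct times (with 2, $t^2$ is collinear with $t$).
* **Durbin–Watson** (`durbinWatson()`): $d = \sum(e_t - e_{t-1})^2 /
  \sum e_t^2$, with observations ordered within lot by time and lots
  concatenated in ID order — stability data are a panel and no single
  ordering is canonical, so the ordering is an explicit argument. The
  verdict uses the familiar $1.5 < d < 2.5$ rule; an optional
  normal-approximation p-value ($d \sim N(2, 4/n)$) is available.
* **Influence** (`influenceDiagnostics()`): studentized residuals,
  leverages, Cook's D and DFFITS with the conventional cutoffs
  ($|r| > 3$, $h > 2p/n$, $D > 4/n$, $|DFFITS| > 2\sqrt{p/n}$).
  Flagged observations are *reported, never removed*.
* **Linearity** (`linearityCheck()`): a loess smooth (span 0.75, tricube
  weights, degree 1) through the partial residuals is compared with the
  least-squares line; the maximum absolute gap over the observed range
  summarises curvature.

Because each test honestly holds its ~5 % level on well-behaved data,
requiring *all* of them to be simultaneously non-significant succeeds in
roughly $0.95^3 \approx 86\%$ of replicate studies, not more — a joint
rate worth remembering when a battery is used as a gate.

## Batch poolability

`testPoolability()` fits three nested OLS models on the same
observations — per-lot lines (full), common slope with per-lot
intercepts (reduced 1), one line (reduced 2) — and applies sequential
partial F-tests at $\alpha = 0.25$: slope equality (full vs reduced 1)
first; only if non-significant, intercept equality (reduced 1 vs
reduced 2). The decision follows the standard matrix: `not_parallel`,
`parallel` or `one_line`, with the boundary $p = 0.25$ counted as
significant. The intercept contrast is deliberately the sequential one
(after imposing a common slope) rather than a within-full-model test;
the sequential scheme matches the model-reduction flow the decision
feeds. Mixed (random-effects) pooling is out of scope — the framework is
fixed-effects OLS throughout.

For ECTC data, poolability is run on the pooled day 0–14 set and on each
conditioning-month subset, mirroring the structure of the reference
coefficient table.

## Stability evaluation

`evaluateStability()` forms the mean regression line and its two-sided
$t$-based band on the log scale, exponentiates, and passes iff the lower
bound stays at or above LL over the whole evaluated range. The band is
for the **mean response** — the shelf-life convention — with a
prediction-band option for single-future-assay questions. The default
grid is the observed timepoints plus a 101-point dense grid; a crossing
is localised by bisection to $10^{-6}$ grid units. Grids extending
beyond ~25 % past the observed range, and claims outside the evaluated
grid, are refused: no silent extrapolation.

When the final model keeps per-lot terms, the evaluation reports the
conservative envelope across lots (pointwise worst mean and lower
bound). Each lot contributes only over its own observed time range: in
the built-in design nine of the 24 lots are scheduled no further than
month 12, and extrapolating their individual lines to month 24 would
manufacture meaninglessly wide bands — the same no-extrapolation rule,
applied per lot.

## Minimum release potency and combined uncertainty

The release specification is

$$MRP = \exp\!\left[\log(LL) - \left(t_{2\text{–}8}\, b_{2\text{–}8} +
t_{ECTC}\, b_{ECTC} - U\right)\right]$$

with $t_{ECTC}$ in months ($d/30$) and $U \ge 0$ the combined
uncertainty. Slopes pass through a clamp first: the default zeroes
*positive* (improving) slopes so an apparent potency gain can never pull
the release requirement below LL, and uses estimated negative slopes as
they are — the behaviour that reproduces the reference worked example.
The opposite reading (zeroing negative slopes) is selectable.

$U$ is reconstructed as a coverage factor $k$ (default 1.645, one-sided
95 % normal) times the root sum of squares of the slope-estimation
terms and a residual term:

$$U = k\sqrt{(t_{2\text{–}8}\, se_{2\text{–}8})^2 +
(t_{ECTC}\, se_{ECTC})^2 + s^2}.$$

The residual policy is configurable. The default (`"pooled"`) averages
the RT residual variance with the residual variance of the *pooled*
ECTC fit for every combined scenario, on the argument that residual
scatter is assay-level noise best estimated from the full ECTC set even
when the slope comes from a conditioning-month subset. Against the
reference table this reproduces the RT uncertainty within 0.3 % and
eight of the ten ECTC values within 0.6 %. The two 12-month-conditioning
rows of the reference table cannot be reproduced within 1 % by *any*
single policy: backing the residual term out of the printed values gives
≈ 0.0271 (the RT residual SD) for those two rows but ≈ 0.0262 for all
others, an internal inconsistency of the reference values themselves.
Per-scenario (`"average"`), RT-only and ECTC-only policies are also
available, and every configured choice is echoed into the report header.

`scenarioGrid()` evaluates one MRP per (ECTC subset, excursion length)
pair with the RT duration fixed at the shelf-life — the release
specification must cover a full shelf-life followed by the excursion —
and `runFullAnalysis()` assembles the whole pipeline into a
deterministic report bundle. When lots are not poolable, the MRP stage
computes every lot-slope combination and keeps the largest MRP, the
conservative release rule.

```{r example}
ds <- simulateDataset(mockSimParams(seed = 1))
bundle <- runFullAnalysis(ds, analysisConfig())
bundle$verdicts
head(bundle$mrp[, c("subset", "days", "U", "mrp_rounded")])
```

## Numerical choices and degenerate inputs

* OLS is delegated to `stats::lm`; coefficient SEs are the unscaled
  covariance times the residual variance, and `residualSD =
  sqrt(SSE/df)`.
* Exact fits (numerically zero residual variance) are rejected by the
  normality and heteroscedasticity tests rather than returning
  meaningless statistics; observations with leverage 1 get an
  `exact_leverage` flag instead of an undefined studentized residual.
* Nested-model checks tolerate SSE inversions up to a $10^{-8}$
  relative slack before declaring models non-nested; a saturated full
  model (SSE = 0) yields $F = \infty$ unless the reduced model is also
  exact.
* The poolability boundary $p = \alpha$ takes the non-pooled branch.
* All randomness lives in the generator; a simulation seed fully
  determines the dataset, and the session RNG state is restored
  afterwards.

## Problem sizes used by the test suite

The suite validates calibration properties at sizes chosen to keep a
full run around a minute: 1000 replicate studies for the
slope-equality type-I rate, 500 for slope recovery and CI coverage,
200 seeds for the diagnostics battery, 1000 replicates for
heteroscedasticity type-I rates at $n = 200$, and 20 end-to-end pipeline
runs. Monte-Carlo bands in the tests are sized to those replicate
counts.

## Limitations

* Single excursion only (RT followed by one ECTC stay); no multi-leg
  temperature histories and no kinetic extrapolation between
  temperatures.
* Fixed-effects OLS only; a product with strong lot effects would call
  for a mixed model that is out of scope here.
* The combined-uncertainty formula is a reconstruction; its coverage
  factor and residual policy are configurable precisely because the
  reference values do not pin them down uniquely.
* The reported per-test p-values of any one real study are, of course,
  not reproducible from generated data; the suite asserts distributional
  calibration instead.
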