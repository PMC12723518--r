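---
title: "Analysing paired on-farm strip trials: effect sizes, regression and break-even economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing paired on-farm strip trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striptrials)
```

## The design and the effect-size model

An on-farm strip trial (OFT) embeds an experiment in a commercial field: a
strip receives the treatment (here, a foliar humic biostimulant applied
once at a critical growth stage) and an adjacent strip is managed
identically but untreated. Each trial contributes one pair of strip-mean
yields and is treated as a single independent replicate; within-strip
sampling is not modelled, because a single unreplicated pair per site
gives no estimate of within-site variance.

The per-trial effect size is the log response ratio

$$L_i = \ln\!\left(\frac{T_i}{U_i}\right),$$

with $T_i$ and $U_i$ the treated and untreated strip yields (t/ha). The
log scale makes the statistic unit-free, symmetric between gains and
losses, and approximately normal across trials. For interpretation it is
back-transformed to a percent response, $(T_i/U_i - 1)\times 100$.

Two programme-level percent summaries are deliberately kept apart,
because they answer different questions and differ whenever yields vary
between trials:

* the **mean of per-trial responses** — the expected gain of a randomly
  chosen trial (this is what `summarize_crop()` reports as
  `response_pct`, with the back-transformed mean log effect labelled
  separately as `response_pct_log_scale`);
* the **ratio of mean yields**, $(\bar T/\bar U - 1)\times 100$ — the
  gain of the programme-wide average yield
  (`response_pct_ratio_of_means`). For the bundled soybean means this is
  13.6% while the mean per-trial response is 14.2%; both are correct,
  and conflating them is a classic reporting error.

## Bootstrap confidence intervals

The overall mean effect per crop is the unweighted arithmetic mean of the
$L_i$ (no meta-analytic variance weighting: each trial is one strip pair
with no internal variance estimate). Its confidence interval is the
bias-corrected normal-approximation bootstrap interval: with observed
mean $\bar t$, bootstrap mean $\bar t^*$ and bootstrap standard deviation
$s^*$ over `n_boot` resamples,

$$(2\bar t - \bar t^*) \mp z_{(1-\gamma)/2}\, s^*.$$

Defaults are `n_boot = 10000` resamples and `conf = 0.95`; a percentile
interval is available via `type = "perc"` but is not the default. The
resampling is vectorised (index matrix + `colMeans`, chunked to bound
memory) and seeded explicitly; a unit test checks agreement with the
`boot` package's `"norm"` interval to Monte Carlo error. On a
zero-variance sample the interval collapses to a point rather than
erroring.

**Effectiveness** is the percentage of trials whose response strictly
exceeds a threshold (0% and 10% by default). Strictness matters only for
exact ties: a trial with exactly zero response does not count as
effective.

## Response versus baseline yield

`linear_response_fit()` is ordinary least squares of percent response on
untreated yield, with the usual two-sided t-test on the slope. The
response variable is the percent response (not the log effect), matching
how such results are plotted; a negative significant slope means the
treatment helps most where baseline yields are low.

`loess_response_fit()` is a locally weighted linear smoother written to a
pinned specification: at each of `grid_n` evenly spaced points over the
observed baseline range, the $\lceil \mathrm{span}\cdot n\rceil$ nearest
trials are weighted by the tricube kernel $(1-(d/h)^3)^3$ and a weighted
line is fitted. Degree 1, no robustness iterations, default span 0.75 —
common convention, exposed in the configuration. Numerical edge cases are
handled explicitly: a window whose radius is zero (all points coincident)
returns the local mean, as does a window with no spread in $x$. Useful
exactness properties follow: the smoother reproduces any noiseless line
to machine precision, and with `span = 1` and the `"uniform"` kernel it
degenerates to the global least-squares line — both are tested, the
latter also against `stats::loess` on smooth data as an independent
cross-check.

`crop_year_model()` fits `response_pct ~ crop + year` with both as
categorical factors, no interaction, reference levels the alphabetically
first crop and the earliest year. A single-level factor is dropped with a
warning rather than an error, so a one-crop table still yields a
year-only model. Because the source programme published no coefficients
for this model, it is property-tested (zero contrasts on homogeneous
data, recovery of a simulated between-crop contrast) rather than checked
against printed values.

## Break-even economics

Per-trial yield differences $(T_i - U_i)\times 1000$ kg/ha are sorted
ascending into a right-continuous empirical CDF,
$F(x) = \#\{d_i \le x\}/n$. The tie convention is explicit: the "chance
to exceed cost", $100(1 - F(b))$, counts *strict* exceedances, so a
trial whose gain exactly equals the break-even mass is not profitable.
The published analysis does not state its convention; right-continuity
is the standard definition of the ECDF and the one adopted here.

The break-even yield for a price $p$ (USD/t) and total treatment cost
$c$ (USD/ha) is $b = c/p \times 1000$ kg/ha, and the net return from
mean yields is $(\bar T - \bar U)\,p - c$ USD/ha — the only formula that
reproduces all five published net-return figures from the published mean
yields.

Price sensitivity uses three scenarios: *unfavorable* (mean price − 1 SD,
total cost inflated 4.5%), *normal* (mean price, actual costs),
*favorable* (mean price + 1 SD, actual costs). The 4.5% inflation applies
to the combined product + application cost, which is what reproduces the
published unfavorable cost column (24 × 1.045 = 25.08, displayed 25.1).
The bundled Uruguayan defaults store the published scenario prices
verbatim (they were printed already rounded to 0.1 USD/t; the
between-year price SD behind them is not public) and back-derive the SD
as half the favorable−unfavorable spread; user-supplied `price_cost()`
objects may instead give a mean and SD and let `scenario_table()` derive
the scenario prices. Full precision is kept everywhere in computation;
rounding (yields 3 dp, percentages 2 dp, money 1 dp) happens only when
the report CSVs are written.

## What the synthetic generator emulates — and what it does not

Raw per-trial yields of the source programme are not public, so
`simulate_crop()` generates them from a transparent model: untreated
yields from a normal distribution truncated by rejection to the observed
range (the published summaries give a mean and range but no shape, and a
truncated normal matches them without inventing skew; the default sd,
range/4, keeps most mass interior), and a per-trial log effect

$$L_i = \mu + \beta\,(U_i - \bar U) + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \sigma^2).$$

The bundled `uruguay_grain_profiles()` set, per crop: the published trial
counts (181/103/60/74/30), untreated means and ranges, mean responses
(14.22/7.56/15.73/12.71/14.29%, so $\mu = \ln(1 + r/100)$), and year
spans. Two parameters the programme never published are chosen once, as
follows:

* **Between-trial sd $\sigma$** is calibrated in closed form so that
  $P(L_i > 0) = \Phi(\mu/\sigma)$ matches each crop's reported
  effectiveness at the >0% threshold (90.2–94.6%), giving
  $\sigma \approx$ 0.10 (soybean), 0.05 (rice), 0.11 (maize), 0.07
  (wheat), 0.09 (barley). A single flat $\sigma$ cannot do this: a value
  matching soybean's dispersion would give rice four times its reported
  share of negative responses. The generic `crop_profile()` default
  (0.12) remains a reasonable uncalibrated choice, yielding roughly one
  negative trial in ten at typical effect sizes.
* **Effect–yield slopes $\beta$** (log effect per t/ha) are −0.05
  (barley), −0.02 (maize), −0.015 (wheat) and 0 (rice, soybean):
  negative exactly where the published regressions were significantly
  negative, strongest for barley where the decline was most pronounced,
  and large enough relative to their simulated standard errors that a
  500-trial OLS detects them essentially always.

Per-crop random streams are derived deterministically from one master
seed (a stable per-crop offset), so simulating a subset of crops
reproduces exactly the draws of the full run.

The generator does **not** emulate: site geography or the 53 localities
(site labels are synthetic "S001"…), year effects or the 2022–2023
droughts (years are assigned uniformly), within-trial strip replication,
yield-dependent *variance*, or rice's reported U-shaped response at the
yield extremes (the model is linear in baseline yield). Passing tests
therefore demonstrate that the *methods* are correct and well calibrated
under the programme's stated marginal conditions — not that real trial
data are free of spatial, temporal or management confounding.

## Problem sizes and numerical choices

The test suite and the acceptance script run the methods at the study's
own scale: 448 simulated trials across the five crop profiles, 10,000
bootstrap resamples, 200 replicate programmes for the CI coverage
experiment, 100 replicates per crop for slope-detection power at
n = 500, and 1,000 flat-slope fits for type-I calibration — sizes chosen
so each experiment's Monte Carlo error is small against the band it
checks while the whole analysis completes in well under a minute.
Reported checks: coverage of the 95% interval lands at 95–96%, the
type-I rate at 5–6%, slope-sign detection at 100%, and the span-1
uniform smoother agrees with OLS to ~1e-15.

Known limitations: trials are unweighted regardless of strip size or
yield level; the economics assume a single price per crop-scenario and
ignore discounting and farm-level optimization; and the break-even
"chance" is an in-sample ECDF estimate, not a predictive probability for
a new site.
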