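# striptrials

Statistical and economic analysis of **paired on-farm strip trials
(OFTs)** — experiments embedded in commercial fields where a treated and
an untreated crop strip form one replicate. The package was built around
a multi-year programme of 448 such trials of a foliar humic biostimulant
on soybean, rice, maize, wheat and barley across Uruguay's main grain
zones, and ships defaults (trial counts, yield distributions, prices,
costs) describing that programme, but every function accepts user data
in the same tidy schema.

## What it computes

For each trial *i* with treated yield *Tᵢ* and untreated yield *Uᵢ*
(t/ha), the effect size is the log response ratio

> *Lᵢ* = ln(*Tᵢ* / *Uᵢ*),  back-transformed to a percent response
> (*Tᵢ*/*Uᵢ* − 1) × 100.

On top of that:

* **Per-crop summaries** — mean effect with a bias-corrected
  normal-approximation **bootstrap CI** (10,000 resamples by default),
  percent responses on both the mean-of-ratios and ratio-of-means
  scales, and **effectiveness** (share of trials whose response exceeds
  0% / 10%).
* **Response–yield regression** — OLS of percent response on untreated
  yield, a tricube local-linear (loess-style) smoother, and a
  crop-by-year fixed-effects model.
* **Break-even economics** — the ECDF of per-trial yield differences
  (kg/ha), the break-even yield *b* = cost/price × 1000, the **chance to
  exceed cost** 100 (1 − F(b)), the net return
  (*T̄* − *Ū*) × price − cost, and a three-scenario price sensitivity
  (mean ± 1 SD prices, 4.5% cost inflation in the unfavorable case).
* **A calibrated synthetic trial generator** so the whole pipeline runs
  without the programme's raw per-site yields.

## Worked example

```r
library(striptrials)

recs <- simulate_trials(uruguay_grain_profiles(), seed = 42)   # 448 trials
s <- summarize_crops(recs, n_boot = 10000, seed = 42)
s[, c("crop", "n_ofts", "response_pct", "ci_pct_low", "ci_pct_high",
      "effectiveness_gt0", "effectiveness_gt10")]
#>      crop n_ofts response_pct ci_pct_low ci_pct_high effectiveness_gt0 effectiveness_gt10
#> 1 soybean    181       15.584     13.133      16.738             88.95              65.75
#> 2    rice    103        7.976      6.771       8.919             91.26              35.92
#> 3   maize     60       17.729     13.406      20.500             90.00              68.33
#> 4   wheat     74       12.408     10.240      14.000             95.95              59.46
#> 5  barley     30       18.907     14.126      22.634             93.33              73.33

break_even_table(recs[recs$crop == "soybean", ], uruguay_price_costs()$soybean)
#>      crop    scenario price total_cost break_even_yield chance_exceed_cost net_return
#> 1 soybean unfavorable 304.9      25.08           82.256             79.006     86.024
#> 2 soybean      normal 384.2      24.00           62.467             81.215    116.001
#> 3 soybean   favorable 463.6      24.00           51.769             81.768    144.934
```

Reading the soybean table: at the normal scenario the treatment must buy
back 62.5 kg/ha of grain to pay for itself; 81% of the simulated trials
gained more than that, and the mean yield gain is worth 116 USD/ha net
of the 24 USD/ha treatment cost. The `response_pct` column is the mean
of per-trial responses; the ratio of mean yields is reported separately
(`response_pct_ratio_of_means`) because the two differ whenever yields
vary between trials.

The same analysis runs end to end from a config:

```r
res <- run_pipeline(oft_config(simulate = TRUE, seed = 42,
                               out_dir = "report"))
# writes trials.csv, crop_summaries.csv, break_even.csv,
# crop_year_model.csv and a full-precision report.json
```

or from your own data: a CSV with header
`crop,year,site_id,untreated_yield_t_ha,treated_yield_t_ha` via
`oft_config(oft_csv = "...", economics = "...")`.

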