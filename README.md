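# hrvretest

Test–retest reliability analysis of short-term heart rate variability
(HRV) responses to submaximal exercise, for exercise physiologists and
clinical researchers who need to know whether an HRV-based protocol gives
the same answer when the same person repeats it.

The motivating design: older adults perform a 2-minute step test twice on
the same day, with HRV measured from R-R interval recordings before and
immediately after each bout. The package answers two questions per HRV
index and condition:

1. **Did anything systematically change between sessions?** The
   per-subject difference `y = session2 − session1` is modelled as
   `y ~ Normal(μ, σ)` with the skeptical prior `μ ~ Normal(0, 2.5·sd(y))`
   and a half-Student-t(3, 0, 2.5·sd(y)) prior on σ, sampled by a blocked
   Gibbs scheme. The posterior is described in the SEXIT style: median,
   95% highest-density interval, probability of direction (pd), occupancy
   of the region of practical equivalence (ROPE, ±0.1·sd(y)), and the
   Savage–Dickey Bayes factor `BF10 = p(0 | prior) / p(0 | posterior)`
   with the conventional evidence labels. Extreme outliers are removed
   first with the 3×IQR box-plot rule; convergence is gated on split
   R-hat < 1.01 and ESS > 1000.
2. **How well do the two sessions agree?** Lin's concordance correlation
   coefficient `CCC = 2·cov(x,y) / (var(x) + var(y) + (x̄ − ȳ)²)`,
   estimated Bayesianly through a bivariate-normal model with a vague
   conjugate prior and labelled on the Evans scale, plus Bland–Altman
   bias and 95% limits of agreement.

Upstream of both sits a feature extractor that turns a raw R-R series
into the nine analysed indices — mean R-R, RMSSD, SDNN, HF/LF/VLF band
powers, Poincaré SD1/SD2 (via the stress and composite autonomic
indices), Baevsky's stress index, and the PNS/SNS composites — with
explicit artifact cleaning (3% budget flagging) and 5-minute window
selection. A seeded synthetic-cohort generator reproduces the study
conditions (n = 105, 78.1% female, age 70.9 ± 5.9, paired sessions with
configurable concordance and shift) for calibration and recovery testing.

## Worked example

Extract features from one synthetic 10-minute recording:

```r
library(hrvretest)
rr <- generate_rr(rr_synth_config(duration_s = 600, ectopic_rate = 0.02, seed = 8L))
rr
#> <rr_series> 751 beats, 606.6 s, mean RR 807.8 ms (subject NA, session 1, pre)
compute_all(rr, age = 71)
#> <hrv_features>
#>   mean_rr      798.67
#>   hr_mean      75.125
#>   rmssd        26.523
#>   sdnn         23.111
#>   sd1          18.754
#>   ...
```

`rmssd` is the root mean square of successive R-R differences (vagal
tone, ms), `sd1` its Poincaré equivalent (= RMSSD/√2), and the cleaning
report attached to the result says 2% of beats were flagged — inside the
3% usability budget.

Run the full study on a simulated cohort and read the two report tables:

```r
cfg <- study_config(cohort = cohort_synth_config(seed = 42L),
                    mcmc = mcmc_config(seed = 42L), seed = 42L)
rep <- run_study(cfg)
subset(rep$delta_summary, index_name == "rmssd" & condition == "pre")
#>   index_name condition   n median ci_low ci_high    pd rope_pct_inside   bf10
#>        rmssd       pre 105 -0.141  -1.81    1.62 0.565            67.8 0.0404
#>                  bf_label pass
#>   strong in favor of null TRUE
```

The pre-exercise RMSSD shift between sessions is −0.14 ms with a 95% HDI
of [−1.81, 1.62]: pd barely above chance, two-thirds of the posterior
inside the ROPE, and BF10 = 0.04 — strong evidence that nothing changed
between sessions, which is exactly what the generator (zero session
shift) encodes.

```r
subset(rep$concordance, condition == "pre")
#>   index_name   ccc interpretation ci_low ci_high
#>      mean_rr 0.848    Very strong  0.789   0.897
#>        rmssd 0.730         Strong  0.641   0.816
#>           lf 0.308           Weak  0.131   0.463
#>          ... 
rep$hrmax
#>   session   n median  q2.5 q97.5
#>         1 105  67.13 46.74 84.99
#>         2 105  66.18 50.80 82.12
```

Concordance recovers each index's configured target (mean R-R 0.87,
RMSSD 0.72, LF 0.38, ...) within sampling error, and the median exercise
intensity sits at ~67% of age-predicted maximum heart rate — a moderate
bout. `write_report(rep, "out/")` emits the tables as CSV plus a
full-precision `report.json` validated by `validate_report()`.

A thin command-line wrapper with `simulate`, `analyze` and `features`
subcommands ships in `inst/cli/hrvretest.R`.

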