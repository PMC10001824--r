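---
title: "Methods: Bayesian test-retest reliability of short-term HRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian test-retest reliability of short-term HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Short-term heart rate variability (HRV) is widely used to read cardiac
autonomic modulation off beat-to-beat (R-R) interval recordings, and a
natural clinical protocol is to measure it before and immediately after a
submaximal exercise bout such as the 2-minute step test used with older
adults. For such a protocol to be useful, the response it measures must be
reproducible: when the same person repeats the identical test a few hours
later, analogous HRV readings should agree. `hrvretest` implements the full
analysis chain for that question:

1. **Feature extraction** — nine standard HRV indices per recording, with
   explicit artifact handling and analysis-window selection;
2. **Between-session difference models** — an intercept-only Bayesian model
   per index and condition, described with the SEXIT summary set
   (median, 95% HDI, probability of direction, ROPE occupancy,
   Savage-Dickey Bayes factor);
3. **Agreement** — Bayesian Lin's concordance correlation (CCC) and
   Bland-Altman limits of agreement between session pairs;
4. **Synthetic cohorts** — a seeded generator that produces data with the
   statistical structure the analysis assumes, used for calibration and
   parameter-recovery testing throughout the test suite.

## Per-recording feature extraction

A recording enters as a strictly positive R-R interval sequence in
milliseconds (`rr_series()`). The pipeline in `compute_all()` is:

* **Cleaning** (`clean_rr()`): beats deviating more than 25% (default) from
  an 11-beat running median are removed, mirroring the practice of
  excluding artifacts and ectopic beats rather than interpolating them.
  The report carries the flagged fraction and a flag when it exceeds the 3%
  budget conventionally treated as the usability limit for a short-term
  recording. The exact ectopic criterion is a design choice — commercial
  software does not publish its rule — so the threshold and window are
  exposed.
* **Window selection** (`select_segment()`): the trailing 300 s of the
  recording, matching the convention of analysing the final 5 minutes of a
  10-minute seated rest. Whether "5 of 10 minutes" means the first or last
  five is genuinely open; we chose the last window (most settled state) and
  expose the anchor.
* **Time domain**: mean R-R, heart rate, RMSSD, SDNN. SDNN uses the sample
  (n-1) denominator; sources are often silent on this, so it is documented
  here.
* **Poincare**: SD1 is computed about the line of identity (no
  mean-centring of the rotated short-axis coordinate), which makes
  SD1 = RMSSD/sqrt(2) an exact identity rather than an approximation; SD2
  is the centred spread along the identity direction. Centring SD1 would
  break the identity whenever successive differences have a non-zero mean.
* **Frequency domain** (`spectral_powers()`): conventional band edges
  VLF 0.003-0.04, LF 0.04-0.15, HF 0.15-0.40 Hz. The default estimator is
  a Welch periodogram (Hann windows, 50% overlap) on the tachogram
  cubic-spline resampled at 4 Hz after linear detrending; a Lomb-Scargle
  periodogram on the raw beat times is the alternative. Both are scaled as
  one-sided densities whose integral recovers the signal variance, so band
  powers are in ms^2. A band whose slowest frequency cannot complete two
  cycles within the recording (VLF needs about 11 minutes) is flagged
  unreliable rather than silently reported — a 5-minute window supports HF
  and LF but only nominally VLF.
* **Baevsky stress index** (`baevsky_si()`): AMo/(2·Mo·MxDMn) from a 50-ms
  histogram (the standard bin width; configurable). A constant series has
  MxDMn = 0 and raises a degenerate-distribution error instead of
  returning infinity. Downstream reporting uses sqrt(SI), the usual
  normalised "stress index".
* **Composite autonomic indices** (`autonomic_indices()`): PNS is the mean
  z-score of {mean R-R, RMSSD, SD1}, SNS the mean z-score of
  {-mean R-R, +SI, -SD2}, oriented so larger = more sympathetic
  (sympathetic activation shortens R-R, raises SI and suppresses overall
  variability). The population constants behind the commercial indices are
  proprietary; the shipped `norm_reference()` defaults are anchored to
  published resting norms for healthy adults and the indices should be
  compared only within one reference.
* **Relative intensity** (`pct_hrmax()`): percentage of age-predicted
  maximum heart rate, default 220 - age with Tanaka (208 - 0.7·age) as an
  alternative.

## The between-session difference model

For each index and condition the response is the per-subject difference
y = session2 - session1. Extreme outliers are removed once, before
anything else, using the 3 x IQR box-plot rule with type-7 (linearly
interpolated) quartiles and strict inequalities: a value exactly on a
fence stays. Removal is single-pass — fences are never recomputed.

The model is y ~ Normal(mu, sigma) with

* mu ~ Normal(0, 2.5 · sd(y)) — centred on zero because the design's
  premise is "no change between sessions", scaled to the response;
* sigma ~ half-Student-t(3, 0, 2.5 · sd(y)). The original analysis this
  mirrors used a general-purpose MCMC engine whose sigma prior it did not
  print; ours is the standard weakly-informative choice and, at n near
  100, the posterior for mu is insensitive to it.

Because the model is two-parameter, we sample it with a blocked Gibbs
scheme instead of a general HMC engine: the half-t prior is represented as
a scale mixture of inverse-gammas, making every full conditional standard
(normal for mu, inverse-gamma for sigma^2 and the mixing variable). The
sampler mixes essentially perfectly (near-iid draws), so the default
test-scale configuration — 4 chains x 5,000 iterations, half warm-up —
already yields effective sample sizes near the raw draw count;
replication-scale settings (5 x 50,000) are one argument away.

The SEXIT description (`sexit_summary()`) reports: posterior median; 95%
highest-density interval (for a unimodal posterior never wider than the
equal-tailed interval); probability of direction by sign-counting with
ties at zero excluded; ROPE bounds ±0.1 · sd(y) with occupancy measured on
the full posterior (not the HDI-restricted variant, which exists in the
literature but is not used here); and the Savage-Dickey BF10, i.e. the
prior density at zero over the posterior density at zero. The posterior
density at zero is evaluated from a moment-matched normal by default —
the posterior of an intercept under a normal model is extremely close to
normal — with a Gaussian KDE alternative. Degenerate cases are handled
explicitly: a point-mass posterior at zero yields BF10 = 0, labelled as
the extreme-evidence-for-null limit.

Convergence gates follow the usual thresholds: split R-hat below 1.01 and
effective sample size above 1000 for every parameter. A failed gate flags
the affected row; it never silently passes and never aborts the study.

## Agreement between sessions

`lin_ccc_point()` is Lin's coefficient with population (1/n) moments, the
original definition. The Bayesian version models the session pair as
bivariate normal under a vague conjugate normal-inverse-Wishart prior
(prior weight kappa0 = 0.01 on the sample mean, nu0 = 4 degrees of
freedom, prior scale matrix diagonal at the sample variances) and maps
each posterior (mu, Sigma) draw to a CCC draw. The exact prior used by the
reference implementation of this idea is not published; the contract we
verify instead is that the posterior median agrees with the closed-form
point estimate within 0.02 for n of 100 or more, and that 95% credible
intervals cover a known simulation truth at their nominal rate. The vague
prior's diagonal scale shrinks the correlation by O(1/n), which is why
"identical measurements" score slightly below 1 at n = 100.

Subjects excluded from a difference model by the outlier rule still enter
the agreement analysis: outlier removal is a property of the difference
distribution, not of the raw pairs, and propagating it would conflate the
two questions. Bland-Altman limits are bias ± 1.96 · SD of the
differences, the standard 95% convention.

## What the synthetic cohort does and does not emulate

`generate_cohort()` produces the study-shaped dataset the analysis
expects: 105 subjects by default (78.1% female; ages normal 70.9 ± 5.9
truncated at 60, the usual inclusion floor), each with a 2 x 2 grid of
recordings (two sessions, pre/post exercise) and nine indices per
recording. Each index follows

    value = index mean + exercise effect (post only) + subject effect
            + session shift (session 2 only) + noise

with the subject effect Normal(0, between-SD) shared across the grid and
the within-subject SD *solved* from the target between-session CCC via
ccc = between^2 / (between^2 + within^2 + shift^2/2); unattainable targets
raise a solver error. Default index means, exercise effects and
between-subject SDs are simulation conveniences chosen once at plausible
magnitudes for older adults (e.g. resting mean R-R 850 ms dropping 150 ms
after stepping; RMSSD 25 ms dropping 8 ms); default target CCCs span the
weak-to-very-strong range seen in test-retest HRV work; the default
session shift is zero — the design premise. Exercise heart rates are
drawn at 67% ± 10% of age-predicted maximum, the moderate intensity a
2-minute step test elicits.

Raw tachograms (`generate_rr()`) are mean R-R plus HF and LF sinusoids
plus white noise, with artifacts injected as isolated halved or doubled
intervals. A premature beat in real ECG is usually a short-long pair; we
model single deviant intervals instead so that the artifact fraction seen
by the cleaner equals the configured rate one-for-one, which is the
property the calibration tests rely on. One global seed fans out to
per-subject substreams, so any subject subset regenerates identically.

Known gaps between the generator and real data — and therefore limits on
what green tests demonstrate: index values are Gaussian (real spectral
powers are right-skewed and strictly positive; simulated HF/LF values can
go negative at realistic dispersions), indices are generated independently
of each other (real RMSSD, HF and SD1 are strongly dependent), tachograms
are stationary sinusoids (no respiration drift, no trends), and the
exercise effect is a pure mean shift. Passing calibration here shows the
statistical machinery is correct, not that any physiological claim holds.

## Numerical and testing choices

* All fits are seeded and reproducible; per-model seeds in `run_study()`
  are derived from the model's (index, condition) identity, never from
  loop order, so editing one index's data cannot perturb another's draws.
* Quartiles: type 7 everywhere (R default, linear interpolation).
* pd is reported at full precision and rounded to 0.1% only in the CSV
  display layer; the JSON report keeps full precision.
* Calibration tests run 200 replicates at n = 80 with 4 x 5,000 MCMC;
  recovery tests use 80 replicates per concordance target at n = 105 and
  200 runs for interval coverage. These sizes put the Monte Carlo error of
  each checked quantity well inside its acceptance band while keeping the
  default suite run to a few minutes.
* The report schema shipped in `inst/extdata/report-schema.json` is the
  structural contract of `run_study()` output; `validate_report()` checks
  it.

## Limitations

* ECG-level processing (R-peak detection, waveform QC) is out of scope:
  input is assumed to be already-detected R-R intervals.
* Nonlinear indices beyond SD1/SD2 (entropy, DFA) are not implemented.
* The difference models are intercept-only by design; covariate-adjusted
  or hierarchical reliability models are out of scope.
* The composite PNS/SNS indices are norm-relative; values are comparable
  only within one `norm_reference()` and are not the proprietary
  commercial indices, even though they follow the same construction.
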