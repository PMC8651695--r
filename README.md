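# ctdnatrack

Longitudinal monitoring of circulating tumor DNA (ctDNA) for patients on
targeted therapy — built for the two-arm liquid-biopsy design used in
ALK-positive non-small-cell lung cancer: ultra-deep targeted panel
sequencing (tNGS) and shallow whole-genome sequencing (sWGS) on the same
serial plasma samples. The package is aimed at translational researchers
who want to quantify ctDNA kinetics across therapy lines, derive decision
thresholds, and ask whether molecular progression anticipates radiographic
progression.

## What it computes

**Per-sample burden.** From tNGS variant tables: germline exclusion
(VAF ≥ 30%), a 0.01% VAF detection floor, and the mean variant allele
frequency

&nbsp;&nbsp;&nbsp;&nbsp;V̄ = Σᵢ VAFᵢ / n&nbsp;&nbsp;(V̄ = 0 when n = 0).

From sWGS: 1-Mb genome-bin log2 copy-number ratios and the t-MAD score —
the trimmed median absolute deviation of retained autosomal log2 ratios
from the copy-number-neutral state.

**Between-visit kinetics.** ΔVAF_mean = V̄₂ − V̄₁ (percentage points) and
%Δt-MAD = 100 × (t-MAD₂ − t-MAD₁)/t-MAD₁ for every consecutive sample
pair.

**Thresholds.** Per-metric ROC curves against "progressive disease with
therapy change" labels, AUC as rank-sum concordance with DeLong CIs, and
Youden-index cutoffs. The packaged defaults are the study-derived pair
ΔVAF_mean ≥ 0.0850 pp and %Δt-MAD ≥ 0.5%.

**Early molecular progression.** Candidates at radiographically stable
samples whose incoming delta meets a threshold, validated by a
sustained-increase rule within the therapy line, with lead times (days
from the first validated candidate to the next radiographic progression).

**Outcome statistics.** Kaplan–Meier / log-rank stratification of
time-to-progression by baseline ctDNA detectability, plus Mann–Whitney,
paired Wilcoxon, one-way ANOVA and rank-correlation comparisons.

**Synthetic cohorts.** A seeded generator (`simulate_cohort()`) emulating
the study design — 43 patients, 4–31 samples each, visits every 56–84
days, response/resistance kinetics, variant shedding, binned copy-number
profiles — with ground-truth progression days for recovery testing. See
the methods vignette (`vignettes/ctdna-monitoring-methods.Rmd`) for the
model and every default.

## Worked example

```r
library(ctdnatrack)

cohort <- simulate_cohort(sim_config(rng_seed = 42))
tmad   <- cohort_tmad(cohort)
res    <- analyze_cohort(cohort$variants, cohort$clinical, tmad)

res$call_summary$per_category
#> # A tibble: 3 x 4
#>   category  n_candidates n_validated validation_rate
#>   <fct>            <int>       <int>           <dbl>
#> 1 tNGS_only            6           5            83.3
#> 2 sWGS_only           45           0             0
#> 3 both                26          22            84.6

res$call_summary$median_lead_time_days
#> [1] 78

res$survival$medians
#> # A tibble: 2 x 4
#>   group                   n events median_days
#> 1 baseline_detected      42     21         399
#> 2 baseline_undetected    15      0          NA
```

Reading: of 77 threshold-crossing stable time points, the ones flagged by
both assays validate at 84.6% — sustained rises confirmed by later
progression — while isolated %Δt-MAD blips (a 0.5% relative change is
within assay noise) almost never validate; the median validated call
precedes radiographic progression by 78 days. Therapy lines with
detectable ctDNA at baseline progress earlier (median 399 days vs. not
reached; log-rank p = 7.5e-4 in this cohort).

Thresholds can also be re-derived from the cohort instead of fixed:

```r
derive_thresholds(res$series)$roc$delta_vaf_mean
#> <roc_result> AUC 0.7472 [0.5748-0.9195] (delong), P = 0.004944; n = 21 pos / 184 neg
#>   Youden cutoff 5.342: sensitivity 71.43%, specificity 98.91%
```

File-based runs use the same machinery end to end:

```r
write_fixtures(cohort, "cohort_dir")
run_pipeline(run_config(
  variants = "cohort_dir/variants.tsv",
  clinical = "cohort_dir/clinical.csv",
  bins_dir = "cohort_dir/bins",
  out_dir  = "results"))   # tables + results/report.json
```

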