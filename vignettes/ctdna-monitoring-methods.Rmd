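---
title: "Methods: longitudinal ctDNA monitoring with mean VAF and t-MAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal ctDNA monitoring with mean VAF and t-MAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnatrack)
```

## The monitoring problem

Patients with ALK-rearranged non-small-cell lung cancer on tyrosine kinase
inhibitors are followed with radiographic imaging every 8–12 weeks, but
acquired resistance often emerges between scans. Circulating tumor DNA
(ctDNA) in plasma offers a molecular readout of tumor burden at every
outpatient visit. `ctdnatrack` implements a two-arm quantification of serial
plasma samples and a rule set for calling *early molecular progression* —
a rise in ctDNA at a radiographically stable time point that anticipates
the next progression call.

Two complementary assays feed the pipeline:

* **Targeted panel sequencing (tNGS).** Each plasma sample yields variant
  calls with allele frequencies (VAF, in percent). Calls with VAF ≥ 30%
  are classified germline and excluded; a calling floor of 0.01% VAF
  defines detectability. The per-sample burden metric is the mean VAF,

  $$\overline{\mathrm{VAF}} = \frac{\sum_{i=1}^{n}\mathrm{VAF}_i}{n},$$

  defined as 0 when no somatic variant is detected, and the between-visit
  change is $\Delta \overline{\mathrm{VAF}} = \overline{\mathrm{VAF}}_2 -
  \overline{\mathrm{VAF}}_1$ in percentage points. The mean (rather than
  the maximum) is used so the metric reflects polyclonal burden and is less
  exposed to single-variant sampling noise.

* **Shallow whole-genome sequencing (sWGS).** Read counts in fixed 1-Mb
  genome bins are normalized to log2 copy-number ratios against a control
  reference. The t-MAD score is the trimmed median absolute deviation of
  the retained autosomal log2 ratios from the copy-number-neutral state
  (log2 = 0). The between-visit change is relative:

  $$\%\Delta t\text{-MAD} = 100 \times
  \frac{t\text{-MAD}_2 - t\text{-MAD}_1}{t\text{-MAD}_1}.$$

  A relative change is used because absolute t-MAD ranges differ widely
  between patients and therapy lines.

## Threshold derivation and progression calling

Every consecutive sample pair contributes one observation per metric; pairs
are treated as independent, including pairs from the same patient. The
positive label is *extracranial progressive disease accompanied by a
therapy change* at the later sample. Thresholds are the Youden-index optima
of the per-metric ROC curves (predicate score ≥ threshold); the packaged
defaults, `threshold_set()`, are the study-derived pair 0.0850 percentage
points of ΔVAF~mean~ and 0.5% of %Δt-MAD. AUC is computed as the
normalized rank-sum concordance (ties counted ½), so it is exactly the
Mann–Whitney U statistic divided by the number of positive–negative pairs;
the tests pin this to an explicit brute-force pairwise count at 1e-12.

A **candidate** early-molecular-progression event is any radiographically
stable sample whose incoming delta meets either threshold (≥, so exact
attainment counts), with both samples of the pair inside one therapy line.
A candidate is **validated** when every later sampling point in the line
before the next progression keeps each triggering metric at or above its
candidate-point level, and an extracranial progression eventually occurs in
the same line. The **lead time** is the number of days from the first
validated candidate of the line to that first progression.

Design choices where the procedure was genuinely open:

* *Units of the ΔVAF~mean~ cutoff.* 0.0850 is interpreted as percentage
  points of VAF. The worked trigger examples (0.13 and 0.14 percentage
  points against the 0.0850 cutoff) are only consistent with this reading.
* *"Sustained"* is operationalized as non-decreasing triggering-metric
  levels at interim points, with a configurable relative tolerance
  (default 0). Interim response-status samples are held to the same rule.
* *Intracranial-only progression* neither labels ROC positives, nor
  validates, nor terminates a calling window: CNS lesions shed little
  ctDNA into plasma, so plasma metrics are not expected to track them.
* *Therapy-line boundaries* are hard: pairs straddling a line change are
  never candidates, and validation windows do not cross a change.
* *%Δt-MAD with a zero previous score* is undefined and excluded (with a
  machine-readable reason), as are ΔVAF~mean~ values for patients with no
  detectable variant at any visit.
* *Youden ties* break toward higher sensitivity, then the lower threshold —
  the monitoring use case prefers the more inclusive cutoff.
* *AUC confidence intervals* use the DeLong variance by default because it
  is deterministic; a seeded stratified bootstrap (2000 replicates) is
  available. The association between lead time and response duration uses
  Spearman rank correlation by default.
* Survival stratification treats each therapy line as an independent unit
  (time from the line's first sample to first extracranial progression,
  censored at the last sample), grouped by baseline detectability
  (mean VAF > 0 at the line's first sample). Kaplan–Meier and log-rank
  computations are delegated to the `survival` package; no multiplicity
  correction is applied and all tests are two-sided.

## The synthetic cohort generator

Patient-level plasma data from monitoring studies are controlled-access, so
`simulate_cohort()` generates a cohort with the same longitudinal
structure, plus the ground truth needed for recovery testing. Defaults
(`sim_config()`) emulate the study design: 43 patients; 4–31 samples per
patient (negative-binomial above the minimum, mean ≈ 8); plasma and
imaging share visit dates spaced 56–84 days; detection floor 0.01% VAF;
germline variants near 50% VAF in every sample; 63% of patients with
measurable shedding, which lands sample-level ctDNA positivity near the
51% observed in the motivating cohort.

Tumor kinetics within a therapy line are two exponentials: the sensitive
clone's tumor fraction decays at `k_resp` = 0.035/day under therapy, and a
resistant clone emerges after a delay of 150 days plus an exponential tail
(mean 100 days), growing at `k_grow` = 0.042/day from an initial fraction
of 1e-4. Variant VAFs are `0.5 × carrier tumor fraction × 100` percent
(heterozygous, diploid) with multiplicative log-normal noise (sdlog 0.15);
values below the floor are not reported. A RECIST-like status is assigned
at each visit: progression when the total tumor fraction exceeds
max(2 × nadir, 0.06), response when it falls below 0.7 × the previous
visit, stable otherwise; progression triggers a therapy change with
probability 0.8, starting a new line in which the previously resistant
clone becomes the drug-sensitive trunk.

The kinetic constants were chosen so that molecular detectability precedes
radiographic progression by one to two visits — matching the observed
lead-time scale of roughly one imaging interval — and so that, for any
visit gap in the 56–84-day range, the resistant clone's VAF increment
between successive visits exceeds the 0.0850-point threshold within one
visit of first detectability. Ground truth is recorded at sampling
resolution: the true molecular progression day is the first *visit* at
which the noiseless resistant-clone VAF reaches the floor, because a
between-visit crossing is unobservable by any assay run on the drawn
samples.

Bin profiles are produced directly as log2 ratios: a fixed per-patient
segment profile (integer copy states, ≥ 55% of the autosomal genome
altered) mixed with normal DNA at the sample's tumor fraction, plus
per-bin Gaussian noise (sd 0.01). The altered-fraction floor exists
because a median-based score is blind to alterations covering less than
half the genome; advanced, chromosomally unstable tumors motivate the
choice. The desk-scale genome is 3 autosomes of 100 × 1-Mb bins plus a
small X chromosome (excluded from t-MAD, as in the analysis). The
count-to-log2 path (`bin_fragments()`, `normalize_to_log2()`,
`build_trim_mask()`) is exercised with constructed counts in the unit
tests; the generator does not simulate reads.

What the generator does **not** emulate: sequencing error profiles and
background mutations (false-positive variant calls), GC and mappability
bias in bin counts, clonal hematopoiesis, variable plasma input mass,
intracranial-only progression in shedding patients, and partial or mixed
radiographic responses. Tests passing on this cohort therefore demonstrate
the correctness and calibration of the *analysis rules*, not the clinical
performance of the assays on real plasma.

## Numerical conventions

VAFs and both change metrics are carried in percent end to end; dates are
integer days since diagnosis; bin intervals are 0-based half-open. The
trim mask breaks variance ties by bin order; degenerate inputs (single
ROC class, empty retention set, zero previous t-MAD, negative lead time)
raise errors or reason-coded missing values rather than silent defaults.
Validation-rate denominators of zero report an undefined rate, not 0%.

## Problem sizes in the test suite

The suite runs the full default cohort (43 patients, ≈ 350 samples) for
the recovery and calibration checks — 25 replicate cohorts for the
positivity calibration — 100+ random ROC instances of up to 200
observations against brute-force oracles, 500 null replicates for the
log-rank type-I-error check, and small constructed datasets for the exact
worked examples. These sizes keep the whole suite within a few minutes on
one CPU while leaving the statistical checks well-powered.

## Known limitations

The t-MAD trimming here is a variance-based control mask rather than a
reconstruction of the original blacklist; tumor-fraction estimation (e.g.
ichorCNA) is out of scope, and the log2 pipeline is deliberately simple.
The sustained-increase rule is one reasonable formalization of
"sustained"; its tolerance is exposed for sensitivity analyses. Treating
therapy lines and sample pairs as independent ignores within-patient
correlation and will anti-conservatively narrow p-values on real cohorts.
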