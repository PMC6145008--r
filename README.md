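# hrvci

Multiscale-entropy complexity indices for heart rate variability, with a
diagnostic classification layer for disorders of consciousness.

## The problem

Distinguishing the unresponsive wakefulness syndrome (UWS) from the minimally
conscious state (MCS) is one of the hardest calls in clinical neurology:
behavioural assessment with the Coma Recovery Scale-Revised (CRS-R) is slow,
requires trained assessors, and still misses covert awareness. Because the
heart and brain regulate each other continuously, the *complexity* of the
interbeat-interval (IBI) series — how unpredictable the tachogram is across
time scales — is an inexpensive, non-invasive window on the integrity of that
regulation: unresponsive patients tend toward periodic, low-complexity heart
rhythms, minimally conscious patients toward broadband, 1/f-like variability.

`hrvci` is for physiologists and biostatisticians who want that analysis as a
tested, reproducible pipeline:

1. **Signal ingest** — read ECG/PPG traces or RR-interval files, zero-phase
   FFT bandpass filtering (no detrending), Pan-Tompkins-style beat detection
   with sub-sample refinement, running-median ectopic screening, 10-minute
   segment extraction.
2. **Multiscale entropy** — coarse-graining over scales τ = 1..10 and sample
   entropy SampEn(m, r, N) = −ln(A/B) with m = 2, Chebyshev matching, and
   tolerance r = 0.15 × SD of the scale-1 segment (per-scale convention also
   available). The Complexity Indices are CI_s = Σ SE(τ), τ = 1..5 and
   CI_l = Σ SE(τ), τ = 6..10.
3. **Group statistics** — Mann-Whitney U with an *exact* two-sided p
   (count-recursion over the tie-adjusted rank multiset) and Spearman
   correlation with the CRS-R total.
4. **Classification** — One-R single-attribute rule induction
   (Weka-style discretization, `min_bucket = 6`), a Zero-R baseline,
   stratified 10-fold cross-validation, and the full confusion-matrix panel
   (sensitivity, specificity, FPR/FNR, per-class precision, accuracy, F1,
   MCC).
5. **Synthetic cohorts** — a seeded generator (Mayer-wave + respiratory
   oscillations + 1/f + white noise, with CRS-R-like scores driven by a
   latent complexity) so the whole pipeline runs and is validated without
   patient data.

## Worked example

```r
library(hrvci)

# a synthetic cohort of 16 MCS-like and 14 UWS-like subjects, 10 min each;
# complexity indices are computed through the real entropy pipeline
cohort <- generate_cohort(cohort_spec(seed = 2001), keep_ibi = FALSE)

mann_whitney_exact(cohort, ci_l, diagnosis)
#>   method         group1 group2    n1    n2 statistic     z    p_value exact
#> 1 Mann-Whitney U MCS    UWS       16    14       211  4.09 0.00000513 TRUE

spearman_test(cohort, crs_r_total, ci_l)
#>   method                        n   rho statistic   p_value exact
#> 1 Spearman rank correlation    30 0.683      4.94 0.0000325 FALSE

analysis <- run_cohort(cohort, seed = 7)
analysis$model
#> <oner_model> One-R rule on ci_l
#>   [-Inf, 8.118) -> UWS
#>   [8.118, Inf) -> MCS
#>   training error: 2 / 30
report_table(analysis$cv$pooled)
#>   metric                                   value printed
#> 1 True positive (MCS) rate (%)            93.8   94
#> 2 True negative (UWS) rate (%)            85.7   86
#> 3 False negative rate (%)                  6.25  6
#> 4 False positive rate (%)                 14.3   14
#> 5 Precision MCS classification (%)        88.2   88
#> 6 Precision UWS classification (%)        92.3   92
#> 7 Accuracy (%)                            90     90
#> 8 F1-score (%)                            90.9   91
#> 9 Matthews Correlation Coefficient [-1:1]  0.800 0.80
```

Reading the output: the long-scale index separates the synthetic groups
(higher in the MCS-like group, exact Mann-Whitney p ≈ 5 × 10⁻⁶), correlates
with the CRS-R-like behavioural score (Spearman ρ ≈ 0.68), and the One-R
classifier selects `ci_l` with a single decision boundary; after stratified
10-fold cross-validation the pooled panel shows 90 % accuracy with a 6 %
false-negative rate. `classify_by_threshold()` applies the published
long-scale boundary (4.876 — UWS below, MCS at or above) to new values.

Per-subject processing from raw signals uses the same verbs:

```r
ibi <- generate_ibi(synthetic_profile(), duration = 615, seed = 1)
ecg <- synthesize_ecg(ibi, sampling_rate = 500)
run_subject(ecg, subject_id = "demo", input_type = "waveform")
#> one row: subject_id, n_intervals, sd_ref, se_1..se_10, ci_s, ci_l, ci_total
```

`autoplot()` methods cover tachograms and entropy curves;
`plot_ci_by_group()` and `plot_ci_vs_crsr()` reproduce the standard cohort
figures; `tidy()`/`glance()` methods expose fitted rules and CV results.

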