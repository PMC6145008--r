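---
title: "Multiscale entropy complexity indices for heart rate variability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy complexity indices for heart rate variability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvci)
```

## The problem

Patients with disorders of consciousness are split clinically into the
unresponsive wakefulness syndrome (UWS, eye opening without behavioural signs
of awareness) and the minimally conscious state (MCS, reproducible but
inconsistent non-reflexive behaviours). The behavioural gold standard, the
Coma Recovery Scale-Revised (CRS-R), is demanding to administer and
misdiagnosis is common. Because the heart and brain form a two-way regulatory
loop, the *complexity* of heart rate variability — how unpredictable the
interbeat-interval (IBI) series is across time scales — carries information
about the integrity of that loop: periodic, low-complexity tachograms are
typical of unresponsive patients, while broadband, 1/f-like variability
accompanies preserved regulation.

`hrvci` implements the full analysis chain: tachogram extraction from ECG or
photoplethysmography (PPG), coarse-grained multiscale sample entropy, the
short- and long-scale Complexity Indices, non-parametric group statistics,
and a One-R diagnostic rule with cross-validation — plus a synthetic cohort
generator so that every stage can be exercised and validated without patient
data.

## Signal ingest

A waveform enters as a sampled trace with a declared rate. Preprocessing is a
zero-phase **FFT mask filter**: DFT bins outside the passband are zeroed
symmetrically and the transform inverted. No detrending is applied; any mean
or trend removal comes from the low edge of the passband alone. Defaults are
0.5–40 Hz for ECG and 0.5–8 Hz for PPG; the cutoffs are package choices
(exposed as arguments) since no universal convention exists.

Beat detection is a derivative-energy detector in the Pan–Tompkins style:
band-limit (5–25 Hz for QRS, 0.5–8 Hz for the pulse wave), differentiate,
square, smooth with a centred moving window (150 ms ECG / 300 ms PPG), and
threshold adaptively at a fraction of the 99.5th percentile of the energy
envelope. Candidates are refined to the apex of the unfiltered signal and
then to sub-sample precision by parabolic interpolation, because intervals
are consumed downstream at millisecond precision — finer than one sample at
typical rates. A 250 ms refractory period prevents double-detection, and a
flat (zero-variance) trace returns zero beats with an explicit warning, never
silent success. When both ECG and PPG are available, ECG is authoritative and
PPG serves as an agreement check (the two interval series should be
superimposable to a few milliseconds).

Ectopic screening replaces the visual screen used in clinical practice with a
deterministic rule: an interval deviating from the running median of an
11-beat window by more than 20 % is flagged ectopic; it can be left flagged,
replaced by the local median (flagged `edited`), or deleted. The rule is
idempotent under flagging and its hit fraction is always reported. Finally,
`extract_segment()` takes the maximal run of intervals whose cumulative sum
fits the 10-minute (600 s) analysis window, recording the start policy.

## Multiscale sample entropy and the Complexity Indices

For a series $x_1,\dots,x_N$ the coarse-grained series at scale $\tau$ is

$$y_j^{(\tau)} = \frac{1}{\tau}\sum_{i=(j-1)\tau+1}^{j\tau} x_i,
\qquad j = 1,\dots,\lfloor N/\tau\rfloor,$$

with the trailing incomplete window dropped; $\tau = 1$ is the original
series. Sample entropy with template length $m$ and absolute tolerance $r$ is

$$\mathrm{SampEn}(m, r, N) = -\ln\frac{A}{B},$$

where $B$ counts pairs of length-$m$ templates and $A$ pairs of
length-$(m+1)$ templates whose Chebyshev (maximum-coordinate) distance is at
most $r$. Self-matches are excluded (the Richman–Moorman definition) and both
counts run over the first $N-m$ template starts, so their normalisations
cancel in the ratio. If either count is zero the entropy is undefined and
flagged — never reported as a silent infinity. A constant segment is the one
special case: its reference SD is zero, and exact self-matches are counted at
machine tolerance so the entropy is 0 rather than undefined.

The defaults are $m = 2$ and $r = 0.15$ as a fraction of a reference SD, over
scales $\tau = 1,\dots,10$. Two tolerance conventions are implemented and
recorded on every curve:

* `fixed_scale1_sd` (default): $r$ times the SD of the original segment,
  held fixed across scales — the standard multiscale convention, under which
  white noise yields the analytic curve
  $\mathrm{SE}(\tau) = -\ln\,\mathrm{erf}\!\left(0.075\sqrt{\tau}\right)$,
  decreasing in $\tau$;
* `per_scale_sd`: $r$ times the SD of each coarse-grained series, under
  which the white-noise curve is flat.

Both are offered because published analyses are frequently silent about the
choice; the fixed convention is the default and the one used throughout the
package's own checks.

The Complexity Index over a scale range is the sum
$\mathrm{CI} = \sum_\tau \mathrm{SE}(\tau)$: `ci_s` over scales 1–5 (the
short scales, conventionally associated with the 0.15–0.4 Hz
parasympathetic band) and `ci_l` over scales 6–10 (0.04–0.15 Hz,
predominantly sympathetic). The band interpretation is documentation only; no
spectral computation is performed. In strict mode an undefined scale inside
the range is an error naming the scale; a flagged partial sum is available,
a silent one is not.

```{r example-curve, eval = FALSE}
ibi <- generate_ibi(synthetic_profile(), duration = 600, seed = 1)
curve <- mse_curve(ibi)          # m = 2, r = 0.15, scales 1..10
complexity_indices(curve)        # ci_s, ci_l, ci_total
autoplot(curve)
```

## Group statistics

Group comparisons use a **Mann–Whitney U test with an exact two-sided p**:
the null distribution of U over all $\binom{n_1+n_2}{n_1}$ group labelings of
the observed mid-rank multiset is computed by a count recursion (the shift
algorithm), which handles ties exactly; the smaller tail is doubled and
capped at 1. The exact distribution is used up to a combined sample size of
40 — comfortably covering cohorts of around 30, where counts remain exactly
representable in doubles — with the tie-corrected, continuity-corrected
normal approximation (flagged `exact = FALSE`) beyond. The approximation z is
always reported alongside, because some software prints z even for exact
tests. Correlations with the CRS-R total use Spearman mid-rank correlation
with a t-approximation p, plus an exact permutation option for $n \le 10$.

## The One-R classifier

One-R induces a one-level decision tree: each candidate feature (`ci_s`,
`ci_l`) is discretized by sorting and growing bins until a class holds at
least `min_bucket` members of the bin (default 6, the reference
implementation's default — the toy examples in the tests use smaller
values); the bin then keeps extending while the next value is identical or
the next label equals the bin majority, so a pure class run is never
fragmented. Adjacent bins with equal majority labels are merged, boundaries
sit at midpoints between adjacent distinct values, and the feature with the
minimum training error wins (ties resolved by feature order; majority ties
inside a bin toward the first class level). Prediction assigns boundary
values to the upper bin, so a value exactly at the threshold is classified
with the $\ge$ side. The Zero-R baseline always predicts the majority class,
ties toward MCS.

Generalisation is assessed by stratified k-fold cross-validation (default
$k = 10$): folds of equal size within one, class proportions balanced, every
record tested exactly once, and the *pooled* (micro-averaged) confusion
matrix across folds reported — matching how a single confusion matrix is
conventionally printed for a cross-validated rule. The fold assignment is a
deterministic function of a mandatory seed.

The metric panel reports, with MCS as the positive condition: sensitivity
(MCS correctly classified), specificity (UWS correctly classified), false
positive/negative rates, per-class precisions, accuracy,
$F_1 = 2\,\mathrm{TP} / (2\,\mathrm{TP} + \mathrm{FP} + \mathrm{FN})$ (the
Dice coefficient), and the Matthews Correlation Coefficient, defined as 0
(and flagged) when a confusion-matrix marginal is empty.

## The synthetic cohort generator

No patient recordings ship with the package; a generative model stands in for
them. It is a test fixture chosen to span the regimes of interest and to
admit analytic limits — not a physiological claim. Each tachogram is

$$x_i = \mu + a_{LF}\sin(2\pi f_{LF} t_i + \phi_1)
      + a_{HF}\sin(2\pi f_{HF} t_i + \phi_2)
      + \sigma_p\,\xi^{1/f}_i + \sigma_w\,\varepsilon_i,$$

sampled at nominal beat times $t_i = i\mu$, with $\mu = 800$ ms,
target SD 40 ms, a Mayer-wave oscillation at 0.1 Hz, a respiratory
oscillation at 0.25 Hz, 1/f noise generated by spectral shaping of seeded
white noise, and white noise. A `regularity` knob sets the fraction of
variance carried by the deterministic oscillations; the default 0.125 makes
the oscillation amplitude fractions (0.4 and 0.3 of the SD) literal.
Intervals are clipped to the physiological band 300–2000 ms (clips are
counted and essentially never occur at the default moments).

A cohort draws one latent complexity $c \in [0,1]$ per subject around its
group mean ($0.5 \pm \mathrm{gap}/2$, MCS high; subject SD 0.12) and maps it
monotonically to the generator — regularity falls from 0.75 to 0.10 and the
1/f share of the residual rises from 0.2 to 0.8 as $c$ goes 0 to 1 — so a
zero gap makes the two groups exchangeable by construction, which is what a
type-I-error check requires. CRS-R-like totals are
$\mathrm{round}(3 + 13c + \mathcal{N}(0, \sigma_{CRS}))$ clamped to the
observed range $[3, 16]$. The complexity indices of every synthetic subject
are computed through the real entropy pipeline, never short-cut from $c$.

Two generator constants were fixed by a one-off calibration simulation and
then frozen: the default group gap 0.6 and the CRS-R noise
$\sigma_{CRS} = 3.0$, chosen so that across replicate cohorts of 16 + 14 the
Spearman correlation between CRS-R and `ci_l` falls in the moderate-to-strong
band 0.5–0.8 in well over 80 % of replicates (median around 0.66), while the
Mann–Whitney comparison of `ci_l` is significant far below the 0.001 level in
almost all replicates. A rare draw whose entropy is undefined at some scale
(possible for short, strongly periodic series) fails quality control and is
redrawn, the in-silico analogue of excluding an artifact-laden recording.

What the generator does *not* emulate: ectopy and arrhythmia, non-station-
arity and circadian drift, sedation effects, respiratory coupling beyond a
fixed-frequency oscillation, and any realistic ECG morphology beyond a
stylised PQRST template. Passing tests therefore demonstrate the correctness
and calibration of the *pipeline*, not clinical performance on real
recordings.

## Numerical choices and degenerate inputs

* Chebyshev distance for template matching; matches at distance exactly $r$
  count as matches.
* Coarse-graining drops the trailing incomplete window
  (length $\lfloor N/\tau \rfloor$).
* Zero-match entropies, constant segments, flatline waveforms, undefined
  MCC marginals and partial complexity indices are all explicit flags,
  warnings or named errors — never silent values.
* The sub-sample beat refinement clamps the parabolic offset to half a
  sample; synthetic templates are rendered in continuous time so that the
  true beat instants are not quantised to the grid.
* All randomness flows from user-supplied seeds through a local RNG scope
  that leaves the caller's generator state untouched.

## Problem sizes used in the package's own checks

The test suite validates the entropy implementation against a quadratic
template-counting oracle on hundreds of short series, the white-noise curve
against its analytic form at $N = 9000$ over 100 replicates, the 1/f-versus-
white complexity ordering at the same length over 50 replicates, the exact
Mann–Whitney p against full enumeration for all combined sizes up to 10, the
null calibration of the cohort generator over 1000 replicate cohorts, and
rule recovery on 100 planted-boundary cohorts. These sizes were chosen so
that Monte-Carlo standard errors are small relative to the tolerances being
asserted.

## Known limitations

* The beat detector is tuned for clean or lightly noisy signals; it is not a
  production arrhythmia-robust QRS detector.
* Sample entropy at coarse scales of a 10-minute tachogram rests on fewer
  than a hundred points and is accordingly noisy; undefined scales are
  flagged rather than imputed.
* The One-R threshold learned on any one cohort — synthetic or clinical — is
  a property of that cohort; the package ships the published boundary only
  as the default of `classify_by_threshold()`.
* Exact Mann-Whitney enumeration is limited to combined samples of about 40;
  beyond that the flagged normal approximation is used.
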