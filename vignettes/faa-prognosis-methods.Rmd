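---
title: "Methods: frontal alpha asymmetry as a prognostic marker in pediatric status epilepticus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frontal alpha asymmetry as a prognostic marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faaprog)
```

## The problem

Status epilepticus (SE) — prolonged or rapidly repeating seizures without
recovery — is a pediatric neurological emergency whose outcome is hard to
predict at admission. Frontal alpha asymmetry (FAA) is a resting-state EEG
index: the normalized difference in alpha-band (8–13 Hz) power between the
right (F4) and left (F3) frontal electrodes,

$$\mathrm{FAA} = \frac{P_{F4} - P_{F3}}{P_{F4} + P_{F3}},$$

a dimensionless ratio in $[-1, 1]$, conventionally reported on a
$\times 10^{-3}$ scale (`reported = 1000 * ratio`). Reduced left-relative
alpha power reflects an excitability imbalance of frontal networks, and in a
published cohort of 177 children with SE (126 good prognosis by Glasgow
Outcome Scale level V at one month, 51 poor, levels I–IV), lower FAA
predicted poor outcome with an AUC of 0.805 and a Youden-optimal cutoff of
88.96 on the reported scale.

`faaprog` re-implements that analysis as a reusable, fully tested pipeline:
signal chain (raw EEG → FAA), cohort statistics (univariate battery,
logistic regression, sample size), ROC/cutoff analysis, and a synthetic-data
module that stands in for the unavailable patient data.

## Signal chain

The per-subject chain in `faa_from_recording()` is:

1. **(Optional) common average reference.** Each scalp channel minus the
   instantaneous scalp-channel mean; EOG/auxiliary channels are excluded
   from the average and untouched. The transform is idempotent.
2. **Zero-phase bandpass 0.3–40 Hz.** 4th-order Butterworth applied
   forward–backward (`signal::filtfilt`), so alpha power is not phase
   shifted. At 500 Hz sampling, a 10 Hz sinusoid passes with < 0.2%
   amplitude loss, while DC and 60 Hz are attenuated by > 95%.
3. **Robust artifact rejection.** A sample is masked when its robust
   z-score, $|x - \mathrm{median}|/\mathrm{MAD}$ (MAD scaled for normal
   consistency), exceeds a threshold (default 6) on any scalp channel,
   padded by 0.2 s per side. This is an automated, reproducible surrogate
   for manual marking of noisy segments; the defaults were fixed once as
   values that flag high-amplitude blink/movement transients but never a
   clean sinusoid.
4. **Welch PSD.** Hann-windowed, mean-subtracted 2 s segments with 50%
   overlap, one-sided density scaling; windows that touch a masked sample
   are dropped entirely. 2 s windows give a 0.5 Hz grid, covering 8–13 Hz
   with 11 points.
5. **Alpha power and FAA.** Mean PSD over grid frequencies in $[8, 13]$
   (both edges inclusive) per electrode, then the FAA ratio. The mean is
   interchangeable with the band integral here because the constant
   bandwidth factor cancels in the ratio.

### Numerical and design choices

* **Welch rather than a single periodogram**: the standard estimator for
  resting EEG; averaging stabilizes band power, and window dropping gives a
  clean semantics for artifact masks. The implementation is checked against
  an independently coded periodogram average to $10^{-9}$ relative error.
* **Re-referencing defaults to off in `faa_from_recording()`.** With only
  F3 and F4 recorded, subtracting the two-channel mean makes the channels
  exact mirror images and forces FAA to 0; a common average is only
  meaningful on a fuller montage. `rereference_common_average()` is exposed
  for montage data (the synthetic generator can emit extra channels), and
  the order used is re-reference, then filter.
* **Band edges inclusive** at 8 and 13 Hz.
* **Degenerate inputs**: FAA is an error when $P_{F3}+P_{F4}=0$; PSD
  estimation is an error when fewer than two clean windows remain; the
  average reference is an error for a single scalp channel.

## Synthetic data

`generate_eeg()` synthesizes the study's recording conditions: 500 Hz
sampling, a fixed-frequency alpha carrier (default 10 Hz) with a slow shared
amplitude modulation, broadband background (half white, half $1/f$), 0.5 s
raised-cosine blink transients on the frontal channels, and 0.3 s
high-amplitude broadband bursts. The F3/F4 amplitudes are solved
analytically from the target asymmetry ($A_{F4,F3} = A_0\sqrt{1 \pm f}$), and
because the carrier phase and modulation envelope are shared between the two
channels, every linear channel-identical operation preserves the power ratio
— which is what makes the noise-free round trip testable to $10^{-6}$
rather than merely approximately. A deliberate consequence: the generator is
*not* a realistic EEG simulator (no 1/f-embedded alpha bursts with random
phase, no ictal morphology, no inter-channel coherence structure), so
passing round-trip tests demonstrate correctness of the signal chain, not
performance on real recordings.

`generate_cohort()` draws patient tables under the published study
conditions, which are the defaults: 126/51 good/poor records, FAA normal
within stratum (89.10 ± 17.04 vs 66.64 ± 17.77 on the reported scale —
within-stratum normality is an assumption, consistent with the original
analysis passing Shapiro–Wilk before t tests), categorical covariates from
the published stratum-conditional proportions, and serum markers (GFAP,
S100-β, GABA; pre/post treatment) drawn conditional on the record's FAA
side of the 88.96 cutoff. GOS within the poor stratum is drawn from a fixed
severity mix (0.10, 0.20, 0.35, 0.35 over levels I–IV) — the dichotomy, not
the level, drives every downstream statistic, so this choice is cosmetic.

In **model mode** the prognosis is instead drawn from a logistic model with
the published slopes ($\beta_{FAA} = -0.077$ per reported unit,
$\beta_{time} = 1.010$ for cessation > 30 min) and an intercept calibrated
deterministically (numerical integration over the FAA mixture plus
`uniroot`) so the marginal poor-prognosis rate equals 51/177. This mode
exists for parameter-recovery experiments; refitting recovers both slopes
within their 95% Wald CIs in ≈ 90% of replicates (the theoretical joint
coverage of two ~independent 95% intervals, $0.95^2 \approx 0.90$).

## Cohort statistics

* **Pooled-variance t test** (`pooled_t_test()`), from raw vectors or
  published group summaries. The pooled (not Welch) form is deliberate:
  it is the only variant that reproduces every published t statistic from
  the printed summaries (e.g. 7.844 for FAA, 4.317/6.747/6.780 for the
  post-treatment markers).
* **Pearson chi-square without continuity correction**
  (`chi_square_test()`), again matching all printed values (8.367, 5.894,
  1.729 with 2 df, …); a zero expected count errors with a pointer to
  `fisher_exact_test()`, whose two-sided p sums hypergeometric
  probabilities no larger than the observed table's.
* **Logistic regression** (`fit_logistic()`): IRLS/Newton with
  step-halving (log-likelihood provably non-decreasing), convergence at
  max |score| < 1e-8 or relative log-likelihood change < 1e-10, explicit
  errors for separation (caught both as diverging coefficients and as
  exactly-fitted outcomes, since the score itself vanishes under
  separation). Wald statistic $(\beta/\mathrm{se})^2$, odds ratio
  $e^\beta$, CI $e^{\beta \pm 1.96\,\mathrm{se}}$ with the fixed 1.96
  normal quantile — the conventions of the published table.
* **Sample size** (`sample_size()`):
  $N = z_{\alpha/2}^2\, \pi(1-\pi)/\delta^2$. At the published inputs
  ($\pi = 0.139$, $\alpha = 0.05$, $\delta = 0.06$) the formula gives
  127.7, while the source text says "at least about 126"; the package
  reports the formula value and does not force agreement.
* Records with missing fields are dropped listwise per test; the design
  assumes complete data and this path only guards synthetic edge cases.

## ROC and cutoff analysis

`empirical_roc()` uses the distinct observed scores as thresholds with the
orientation *lower score ⇒ positive* and positive class *poor prognosis* —
the only orientation that reproduces the published sensitivity
(90.20% = 46/51) and specificity (52.38% = 66/126) from the cutoff-table
counts. Trapezoidal AUC on the full threshold set equals the Mann–Whitney
pair statistic (half weight for ties) to machine precision, which the tests
assert against an explicit pair-counting oracle. The standard error is
Hanley–McNeil ($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$) with a 1.96 CI clipped
to $[0,1]$. The published SE of 0.035 cannot be recomputed without
subject-level scores (Hanley–McNeil at AUC 0.805, n = 51/126 gives ≈ 0.040),
so the SE is validated structurally against the formula, and the published
CI is validated as an interval-reconstruction consistency check
($0.805 \pm 1.96 \times 0.035 = (0.736, 0.874)$, bracketing the printed
0.738–0.873 within rounding).

`youden_optimal()` maximizes $J = \mathrm{sens} + \mathrm{spec} - 1$ over
thresholds, breaking ties by higher sensitivity then lower cutoff, and is
tested against exhaustive search. `stratify_by_cutoff()` rebuilds the
cutoff-stratified outcome table and the marker comparisons.

## Problem sizes in the test and acceptance runs

Simulation sizes were chosen once, as the smallest that keep Monte-Carlo
noise far from the tolerances they certify: moment-matching convergence at
$n = 10^4$ per stratum (2% bands vs ~1% sampling error); artifact-rejection
benefit as a median over 50 seeds of 40 s recordings; Welch split-half
calibration over 40 seeds (decimating to every second frequency bin, since
adjacent Welch bins are correlated through the Hann window and would make
the nominal KS level anti-conservative); AUC sampling behaviour over 500
replicates of the 126/51 design, whose mean sits within 0.03 of the
binormal value $\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2}) \approx 0.819$
with the published 0.805 inside the central 95% interval; and logistic
recovery over 100 replicates at $n = 5000$.

## Known limitations

* The EEG generator trades realism for analytic checkability (see above);
  no claim is made about artifact-rejection performance on real EOG/EMG
  contamination.
* EEG interchange is the plain CSV channel-matrix + JSON sidecar dialect;
  EDF files should be converted upstream.
* The published regression table and AUC are not exactly reproducible
  without subject-level data; they are covered by parameter-recovery and
  sampling-interval checks rather than value equality. Relatedly, some
  printed table entries are internally inconsistent at printed precision
  (e.g. a Wald statistic computed from unrounded values whose rounded
  $\beta$ and se imply a different number); `worked_examples()` checks such
  entries against the interval implied by half-unit rounding.
* No multiple-testing correction and no model selection beyond
  "significant univariate variables enter the logistic model", mirroring
  the original analysis.
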