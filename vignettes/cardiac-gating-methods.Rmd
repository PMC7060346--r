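---
title: "Cardiac-gated stimulus timing, interoception scoring and default-prior Bayes factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-gated stimulus timing, interoception scoring and default-prior Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiogate)
```

# The problem

Experiments on cardiac interoception present task cues at defined phases of
the cardiac cycle. Arterial baroreceptors fire maximally about 280–300 ms
after the ECG R-wave (systole); between beats (diastole) they are quiescent.
A systole cue can therefore be anchored *reactively*: detect an R-wave, wait
290 ms, present the cue. A diastole cue targeted at 10 ms *before* the next
R-wave cannot — the anchoring beat has not happened yet — so it requires a
forward prediction of the next beat. `cardiogate` implements this scheduling
algorithm, evaluates its achieved precision, scores the accompanying
heartbeat-counting (interoception) and Go/NoGo/Choose (intentional
inhibition) tasks, computes RMSSD heart-rate variability, and provides the
frequentist tests and default-prior Bayesian counterparts used to analyse
such studies — including Bayes factors computable from printed summary
statistics alone.

# The scheduling model

Let $R_1 < R_2 < \dots$ be detected R-peak times and let trial $i$ become
schedulable at time $e_i$ (previous trial end plus a 1000 ms fixation). The
anchor is $R^\* = \min\{R_j : R_j \ge e_i\}$.

* **Systole**: onset $= R^\* + 290$ ms. No prediction is involved; if
  detection is perfect the timing error is identically zero.
* **Diastole**: the next beat is predicted as
  $\hat{R}_{next} = R^\* + \operatorname{median}(\mathrm{IBI}_{-1},
  \mathrm{IBI}_{-2}, \mathrm{IBI}_{-3})$, the median of the three inter-beat
  intervals ending at $R^\*$, and the onset is $\hat{R}_{next} - 10$ ms. The
  achieved error equals the prediction miss,
  $\operatorname{median}(\mathrm{IBI}_{prev,3}) - \mathrm{IBI}_{next}$,
  exactly — a property the test suite checks trial by trial.

The median-of-3 predictor is robust to a single deviant beat (one ectopic or
mis-detected interval cannot move the median beyond the adjacent interval),
which is why it is preferred over a mean in online use.

## Evaluating achieved timing

`evaluate_timing()` histograms, per phase, the signed offset of each onset
from its reference R-peak in 50 ms bins spanning [−400, 600) ms, and reports
the fraction of trials whose |error| is within a 200 ms tolerance. The
reference beat is the *preceding* R for systole trials. For diastole trials
we use the *nearest* R: the prediction error is roughly symmetric around
zero, so on close to half of diastole trials the cue lands just *after* the
true beat; measuring those against the following beat instead would record
an offset near −IBI for what is actually a near-perfect trial. The nearest-R
convention keeps the diastole cluster just below 0 with small spill-over to
small positive offsets, which is how achieved-precision histograms for this
design are conventionally displayed.

At the cohort-typical operating point (75 bpm, RMSSD 54 ms), the prediction
miss has a standard deviation of roughly
$\sqrt{\sigma^2(1 + c_{med})} \approx 46$ ms (with $\sigma = 54/\sqrt{2}$ ms
per-interval jitter and $c_{med} \approx 0.45$ the variance factor of a
median of three), so essentially all diastole trials fall within the 200 ms
tolerance; precision degrades monotonically as RMSSD grows, a property the
suite verifies over a sweep.

## Numerical conventions and degenerate inputs

Bin edges sit at integer multiples of the bin width; offsets outside
[−400, 600) are clipped into the end bins. A perfectly periodic stream
produces exactly one occupied bin per phase and zero error. If the R-peak
stream is exhausted mid-session, the completed prefix is returned with a
`truncated` attribute and a warning rather than an error. R-peak detection
uses an upward threshold crossing followed by a local maximum, with a 250 ms
refractory period (the physiological upper bound on heart rate) replacing
interactive thresholding.

# Interoception scoring

From six heartbeat-counting trials (25, 30, 35, 40, 45, 50 s, randomized)
with 0–10 confidence ratings, seven indices are computed:

| Index | Definition |
|---|---|
| standard accuracy | mean of $1 - |n_{real}-n_{rep}|/n_{real}$ |
| alternative accuracy | mean of $1 - |n_{real}-n_{rep}|/((n_{real}+n_{rep})/2)$ |
| insight | mean of (per-trial standard accuracy − confidence/10), signed |
| awareness | Pearson r across trials between alternative accuracy and confidence |
| confidence | mean 0–10 rating |
| sensibility | Body Perception Questionnaire mean (45 items, 1–5) |
| TIPE | z(sensibility) − z(alternative accuracy), z-scored across the cohort |

Three conventions deserve note, because the formulas are sometimes typeset
ambiguously in the literature:

* **Absolute differences inside both accuracy formulas.** With a signed
  numerator, under-estimation would yield accuracies above 1 and the
  documented score ranges (standard accuracy bounded above by 1, alternative
  accuracy in [−1, 1]) could not arise. The absolute-difference reading is
  the one under which the ">2× real beats" over-estimator heuristic is
  algebraically equivalent to "standard accuracy negative", a consistency
  the tests assert.
* **Insight is signed.** A discrepancy of 0 is optimal; negative values mean
  low performance with high confidence, positive values the reverse. Taking
  absolute values per trial would destroy that interpretation. The per-trial
  discrepancies (not subject means) are averaged.
* **Over-estimators.** A subject reporting more than twice their total real
  beats across the six trials is flagged; standard accuracy and insight are
  withheld (returned as `NA`) and only alternative-accuracy-based indices
  are reported. Totals rather than per-trial flags are used so a single
  miscount does not exclude a subject. Missing indices propagate as missing
  into cohort statistics via pairwise deletion, never as zeros.

TIPE uses the $n-1$ sample standard deviation in its z-scores, the
convention of mainstream statistical packages; cohort TIPE therefore has
mean exactly 0. Awareness with degenerate (zero-variance) confidence is
undefined and reported `NA` with a warning.

# Heart-rate variability

RMSSD — $\sqrt{\operatorname{mean}(\Delta \mathrm{IBI}^2)}$ over successive
inter-beat-interval differences — and mean heart rate (60000 / mean IBI,
which equals beats over elapsed time for a complete window and is stable for
partial ones). The default analysis window is 150 s of a resting recording.
An automated artifact screen replaces visual inspection: any interval
outside [300, 2000] ms flags the recording; nothing is silently removed.

# Statistics

Frequentist tests delegate to the standard R implementations (`t.test`,
`wilcox.test`, `cor.test`, `lm`); the package's own contribution is the
default-prior Bayes factor family, evaluated by adaptive numerical
integration and exposed both from raw columns and from summary statistics —
the only route available when reproducing printed results without raw data.

* **t-tests** (`bf_ttest`): Cauchy(0, 0.707) prior on the standardized
  effect, computed via the mixture-of-g representation
  ($g \sim$ inverse-gamma(1/2, 1/2)), which needs only central-t kernels.
* **Correlations** (`bf_pearson`): stretched-beta prior of width 1 (the
  uniform prior on (−1, 1), its exact special case), integrating the exact
  sampling-density ratio of the observed correlation; the hypergeometric
  factor is summed by its Gauss series, convergent on the whole domain.
* **Regression** (`bf_regression`): full-vs-null Zellner–Siow mixture-of-g
  Bayes factor with scale $\sqrt{2}/4$, the "medium" continuous-covariate
  default of the reference Bayesian-regression implementations. The
  "beta-binomial" model-space prior sometimes quoted alongside this default
  governs model averaging across subsets and is irrelevant for a single
  full-vs-null comparison, so the prior scale is the only free choice;
  reproduction of published regression Bayes factors is therefore expected
  to ~2% rather than to the printed decimal.

Integrals use `stats::integrate` at a requested relative tolerance of 1e-10
(contract: 1e-6); the suite checks all three families against independent
fixed-grid quadrature oracles (a 1e5-point Cauchy-quantile grid under the
noncentral-t density for the t family; midpoint Riemann sums for the
others) to 1e-4 relative error. Bayes factors computed from a *printed*
statistic inherit its rounding: a t of 1.553 only determines the Bayes
factor up to the image of ±0.0005, and the acceptance tests check printed
values against that interval rather than pretending more precision exists.
`bf_robustness` re-evaluates any family over a width grid; as the width
shrinks the prior collapses onto the null and BF10 → 1.

No multiple-comparison correction is applied anywhere, matching the
analysis practice the package reproduces (noted, not endorsed). Missing
data are handled by pairwise deletion with the per-cell n reported and used
in each Bayes factor.

The Wilcoxon signed-rank test reports W (sum of positive ranks) with exact
p for n ≤ 25 without ties and the tie-corrected normal approximation
otherwise, plus the z deviate separately — rank statistics are sometimes
printed under ambiguous labels, so both are exposed. A Bayesian Wilcoxon
counterpart is deliberately not provided: there is no canonical default-
prior formulation to reproduce.

# The synthetic cohort generator

`gen_cohort()` produces every input the pipeline consumes under a single
master seed (per-subject substreams are derived deterministically, so
cohorts are reproducible and parallelizable). Its defaults are the study
conditions the package targets:

* 41 subjects; 400-trial sessions — 200 Go, 66 NoGo, 134 Choose (exact
  counts by construction: Go and NoGo are rounded, Choose takes the
  remainder), half of each type per cardiac phase (counts differ by at most
  1), order shuffled per seed.
* R-peak streams with iid Gaussian inter-beat intervals: mean 60000/75 ms
  and SD $54/\sqrt{2}$ ms, so the expected RMSSD is exactly the 54 ms
  target (for iid intervals successive differences have variance
  $2\sigma^2$), truncated to [300, 2000] ms. Autoregressive structure and
  respiratory sinus arrhythmia are deliberately omitted: RMSSD is the only
  HRV quantity consumed downstream, and this model controls it exactly.
  Subject-level rates are Normal(75, 10) bpm and subject RMSSD lognormal
  around 54 ms, matching cohort descriptive ranges.
* Six counting trials per subject; reported beats are
  `round(ability × real + Normal(0, 2))` floored at 0, with ability
  Normal(0.72, 0.17) truncated — the simplest model with tunable accuracy.
  Confidence ratings are drawn around a subject-level base and then
  *rank-matched* to a latent that correlates with per-trial accuracy at the
  subject's coupling strength: coupling is controlled without ever leaving
  the 0–10 scale.
* Go omissions at 1%, NoGo commission errors at a 4% baseline scaled
  logistically by an impulsivity latent, lognormal reaction times (one
  family for Go and Choose-Go; subject means Normal(482, 57) and
  Normal(523, 82) ms respectively) clipped to the 1000 ms response window.
* Questionnaire scores are integers clipped to instrument-legal ranges,
  positively inter-correlated through the impulsivity latent (loading 0.6);
  the BIS total is the sum of its subscales.

## Effect calibration

Two cohort-level effects are tunable: the correlation between *measured*
awareness and %Choose-Go, and between *measured* insight and Choose-Go RT.
Both targets refer to noisy six-trial indices, so the latent path must be
stronger than the target to survive attenuation. The generator linearizes
the logistic Choose model around its 60% operating point: with logit slope
$s$ on the metacognition latent, idiosyncratic logit SD $s_0 = 0.45$
(chosen to reproduce a ~11-point between-subject SD in %Choose-Go) and
binomial noise over 134 Choose trials, the %Choose-Go–latent correlation is
$\rho_B(s) = ds / \sqrt{d^2(s^2+s_0^2) + p(1-p)/134}$ with $d = p(1-p)$.
The awareness–latent correlation was measured once by simulation at
n = 600 as $\rho_A \approx 0.73$ (a constant frozen in the code), and the
slope solves $\rho_A \rho_B(s) =$ target. Over 20 independent cohorts of
200 subjects at a target of −0.44 the recovered correlation averaged −0.43
(SD 0.075), consistent with the sampling distribution of r at that design.
The insight→RT path uses the same logic with measured attenuation 0.93.

The joint distribution linking interoception, impulsivity and behaviour is
a modelling *stand-in*: real studies report only pairwise correlations, and
no claim is made that a single metacognition latent is the mechanism. What
passing recovery tests show is that the pipeline's estimators are unbiased
and appropriately attenuation-aware on data whose generating process is
known — not that real data obey this latent structure. Likewise the
generator omits features of real recordings (ectopic beats, electrode
artifacts, attention drift), so detector and screen behaviour on real ECG
is only exercised down to the toy-waveform level.

# Pipeline

`run_pipeline()` chains generation (or validated reading of user CSVs),
HRV, behaviour scoring with the exclusion rule — subjects whose NoGo
commission-error rate exceeds the cohort mean by more than 2 sample SDs are
removed before any analysis, in a single pass — interoception profiles, the
four systole-vs-diastole paired comparisons (with a Wilcoxon alongside the
t-test for the skewed NoGo errors), the interoception×behaviour and
impulsivity×behaviour correlation matrices, and the four HRV regressions.
Outputs carry no timestamps, so repeated runs with one seed are
byte-identical; a manifest records the config, seed and file checksums.
Every table cell is reproducible by calling the owning module's function
directly — the pipeline performs no computation of its own.

# Problem sizes used in the checks

The shipped verification uses cohorts of 200 subjects for effect-recovery
checks (the size at which a ±0.12 band corresponds to ~2 SDs of the
sampling distribution of r), 10⁴ null simulations at n = 41 for t-test
calibration, 10⁴-beat streams for RMSSD convergence (2% band), and 20
seeds × 400 trials for gating precision — sizes chosen so each property is
tested against its own sampling noise.

# Known limitations

* The scheduler assumes perfect online R-detection when run on generated
  streams; detector error can be studied only via the toy waveform.
* The stretched-beta correlation prior is implemented for width values
  around the default; extremely narrow widths (< 0.05) stress the beta
  density numerically.
* The over-estimator rule and the exclusion rule are single-pass by design;
  iterative re-screening would change cohort composition and is not
  provided.
* `% NoGo errors` floor effects (many subjects with zero errors) make the
  paired t on that index fragile in small cohorts; the Wilcoxon is reported
  alongside for that reason.
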