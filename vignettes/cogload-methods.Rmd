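---
title: "Methods: autonomic markers of cognitive load from EDA and HRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomic markers of cognitive load from EDA and HRV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

## The problem

Cognitive load and emotional arousal both drive the autonomic nervous
system, and are hard to tell apart at the end-effector level.  Two
peripheral signals carry complementary information: electrodermal activity
(EDA), whose phasic component reflects sudomotor sympathetic bursts, and
heart-rate variability (HRV), whose high-frequency (HF, ~0.15-0.4 Hz) band
is predominantly vagal while the low-frequency band (LF, ~0.04-0.15 Hz) is
mixed.  `cogload` implements a complete chain for a three-epoch protocol
(rest baseline, emotional stimulation, cognitive 2-back tasking, 10 min
each): time-frequency markers from both signals, condition comparisons,
mixed-effects prediction of perceived workload (NASA-TLX), and k-means
autonomic profiling.

Because no public recordings accompany this design, the package ships a
synthetic-session generator with known ground truth; every stage is tested
against it.

## Synthetic sessions

**EDA.**  Tonic level per condition (smoothed across epoch boundaries with a
30 s moving average) plus a bounded AR(1) drift (relaxation ~60 s, SD
0.05 uS), a Poisson train of skin-conductance responses (SCRs) convolved
with the biexponential kernel `exp(-t/2) - exp(-t/0.7)` (seconds; the same
time constants the convex decomposition assumes, so recovery is
well-specified), lognormal amplitudes (median kernel scale 1.5, giving SCR
peaks around 0.5 uS), and white noise (SD 0.01 uS).  EDA is synthesized at
32 Hz rather than an acquisition-grade kHz rate: the analysis only ever
consumes 2 Hz and 1 Hz versions, so 32 Hz exercises the decimation path at a
fraction of the cost.

**Beats.**  An integral pulse frequency modulation model: the instantaneous
rate `m(t) = (HR/60)(1 + a_LF x_LF + a_HF x_HF)` is integrated to unit
crossings; `x_LF`, `x_HF` are unit-variance sinusoids whose instantaneous
frequency random-walks inside narrow bands around 0.1 and 0.25 Hz
(reflected at the edges), so spectral leakage behaves like real HRV; a
`pure_tones` switch makes them exact tones for tests that need closed-form
spectra.

**Default condition profile.**  The protocol constrains only effect
directions (cognitive tasking raises SCR rate and lowers vagal HF
modulation; the emotional condition matches baseline sympathetically).
Magnitudes are package choices fixed once at physiologically realistic
values: SCR rates 4/4/8 per minute (Baseline/EMOT/COG), heart rate 70 bpm
throughout, LF depth 0.03 everywhere, HF depth 0.04/0.04/0.028.  These
depths put RMSSD near 40 ms and keep honest beat-to-beat fluctuation below
the 20% ectopic-detection threshold.

**Ectopics.**  An extrasystole is modelled by shifting a beat 40% of the
preceding interval early, which automatically creates the compensatory
pause; both affected intervals are flagged in the truth.

**Self-reports.**  Scores follow a random-intercept linear model on the
z-scored sympathetic (EDA_TVSYMP) and vagal (HF_VFCDM) markers with
intercept 48, slopes +13.80 and -6.24 points per SD, between-subject
variance 100.2 and residual variance 300.4, clipped to the 1-100 instrument
range.  The intraclass correlation of generated scores converges to
100.2/(100.2+300.4) ~ 0.25.

**What the generator does not emulate:** motion artifacts with realistic
spectra, respiration-HRV coupling, circadian tonic trends, or floor/ceiling
behavior of self-report scales beyond hard clipping.  Passing tests
demonstrate that the chain recovers what it is designed to recover, not
that real recordings are this clean — in particular the classical Fourier
HRV indices discriminate conditions in synthetic data more sharply than
they typically do in vivo, because the generator modulates the HF band
directly and stationarily.

## Preprocessing

* Resampling: linear-phase FIR anti-alias filter (unit DC gain, pass band
  to 0.4x the target rate, stop band from 0.45x), applied centered (zero
  phase) with even-reflection padding, then interpolation onto the target
  grid.  Filter transients occupy roughly one filter length (~30 s when
  decimating 32 to 2 Hz) at each record edge.
* EDA high-pass before complex demodulation: zero-phase order-2 Butterworth
  at 0.01 Hz on the demeaned record, with odd-reflection padding because the
  0.01 Hz forward-backward transient would otherwise leak ~100 s into the
  record.
* Quality screening replaces visual inspection by explicit rules: EDA
  samples outside 0.01-60 uS or slewing faster than 5 uS/s; RR intervals
  deviating more than 20% from an 11-beat running median.  A record is
  discarded when *strictly more than* 2% of samples/intervals are flagged.
* Flagged RR runs are replaced by a natural cubic spline through adjacent
  valid intervals, evaluated on a 2 Hz grid and rescaled so the replaced run
  preserves elapsed time exactly; the correction is idempotent.
* Epochs are half-open `[start, end)` intervals, 0-based in seconds; series
  that begin at the first beat are clipped to their support.

## The three decompositions

**Convex tonic/phasic split.**  The EDA model is the standard convex
program: quadratic misfit, L1 penalty (weight `alpha = 0.008`) on the
non-negative sudomotor driver, and ridge penalty (`gamma = 0.01`) on a
10 s-knot cubic-spline tonic with an offset-plus-drift term; the SCR shape
enters as the AR/MA pair of the bilinear discretization of the biexponential
(0.7 s rise, 2 s decay) at the 2 Hz working rate.  The solver is ADMM with
the non-negativity split onto the driver: the quadratic step is a sparse
banded Cholesky solve (refactored only when the penalty parameter
rebalances), the driver step a soft threshold, stopping at a relative
primal/dual tolerance of 1e-6.  ADMM iterates are not monotone in the
objective — convergence is certified by the residuals instead — and the
returned solution is reproducible to 1e-6 across runs.  Tonic + phasic +
residual reconstruct the input exactly by construction.

**Variable-frequency complex demodulation (VFCDM).**  Stage 1 demodulates at
fixed centers `f_k = (2k-1) f_w` (half-bandwidth `f_w = 0.04` Hz, eight
components: centers 0.04, 0.12, ..., 0.60 Hz), low-passing at `f_w` with a
zero-phase FIR whose transition stays narrower than `f_w`.  Stage 2
re-demodulates each band along its instantaneous-frequency track, estimated
from the stage-1 analytic phase with deviations weighted by local analytic
power — an empty band therefore keeps its nominal center instead of riding
phase noise toward a strong neighbour — smoothed, and clamped to the inner
quarter-band.  Two numerical choices deserve note:

* components whose nominal center reaches Nyquist (numbers 7-8 at a 1 Hz
  input) cannot be demodulated without aliasing and are returned as zero
  signals with band edges truncated at Nyquist, keeping the count of eight
  so that "component k" is stable across sampling rates;
* the quarter-band clamp trades a little adaptivity for tiling: with it,
  sums of in-band narrowband processes reconstruct to within ~8% RMS, while
  genuinely broadband noise still reconstructs only to ~20-30% — adaptive
  demodulation is not an orthogonal filter bank, and the package treats
  reconstruction of broadband inputs as out of scope.

**Level-3 wavelet packets (WPT3).**  A full three-level Daubechies-4 packet
tree (periodized, orthonormal) on the 1 Hz series; each of the eight leaves
is reconstructed to signal length and the leaves are reordered from the
tree's native Paley order to frequency order via the Gray code, so
component `k` covers `[(k-1) 0.0625, k 0.0625]` Hz.  Reconstruction and
energy conservation are exact to machine precision; lengths not divisible
by 8 are handled by reflect-pad-and-crop, which keeps reconstruction exact
but makes edge band energies approximate.

## From components to markers

Each marker is an epoch-averaged Hilbert amplitude of a *session-normalized*
band signal:

| marker | input | bands |
|---|---|---|
| EDA_CVX | 2 Hz EDA | phasic part of the convex split |
| EDA_TVSYMP | 2 Hz, 0.01 Hz high-passed EDA | VFCDM components 2-3 (0.08-0.24 Hz) |
| EDA_WPT3 | 1 Hz EDA | WPT3 components 2-4 (0.0625-0.25 Hz) |
| LF_VFCDM / HF_VFCDM | 1 Hz RR | component 2 / components 3-5 |
| LF_WPT3 / HF_WPT3 | 1 Hz RR | components 2-3 / 4-7 |

plus the scalar classics per epoch slice: RMSSD and Welch-integrated LF
(0.04-0.15 Hz) and HF (0.15-0.4 Hz) power of the 4 Hz RR series (120 s Hann
segments, 50% overlap, per-segment linear detrend — validated against a
Parseval oracle on pure tones).

Normalization is *whole-session* unit variance, for three reasons: the
sympathetic-index lineage normalizes to unit variance; the mean Hilbert
envelope of a unit-variance narrowband Gaussian signal is
`sqrt(pi/2) ~ 1.2533`, which anchors the dimensionless scale these markers
are reported on; and per-epoch normalization would erase exactly the
between-condition contrasts of interest.  A 10 s guard at both ends of every
epoch slice is excluded from envelope means (edge transients of the
zero-phase filters); the guard is configurable.

## Inference chain

* **Condition comparisons** are assumption-guarded: Shapiro-Wilk in every
  condition (alpha 0.05) gates a repeated-measures ANOVA — with
  Greenhouse-Geisser correction when Mauchly's test rejects sphericity —
  followed by paired t-tests; otherwise Friedman followed by pairwise
  Conover tests (rank-sum form, pooled rank variance, `(n-1)(k-1)` df).
  The three pairwise p-values are Bonferroni-adjusted (`min(1, 3p)`).
  Under a null simulation the per-pair family-wise rejection stays at or
  below 2%.
* **Mixed model**: random-intercept REML fit with predictors z-scored
  across all subject-by-condition rows, so coefficients read as score
  points per SD of marker (raw normalized-unit scales have SDs near 0.1,
  which would make the published effect sizes implausible).  Wald t
  statistics use residual-style degrees of freedom
  `n_obs - n_fixed - n_groups + 1`; no reference df convention is canonical
  for this design, and this choice is deliberately conservative.
* **Collinearity** is screened by iteratively dropping the largest
  `VIF = 1/(1-R^2)` above 10.  When two predictors are near-duplicates
  (r ~ 0.999, VIF ~ 385) which member leaves is data-dependent — they are
  statistically exchangeable at that correlation.
* **Stepwise backward selection** removes the largest-p predictor above
  alpha = 0.05 and refits (REML Wald p-values throughout; the rule compares
  no likelihoods, so ML refitting never enters).  A structural property of
  this rule worth knowing: each truly null predictor survives with its
  calibrated ~5% probability, so the joint event "every null removed and
  every active retained" plateaus near 80% at these effect sizes — not
  because of an implementation defect but because of the selection rule
  itself.
* **Profiling**: k-means (25 restarts per k) on z-scored features over
  k = 2..8, with the elbow curve reported and k chosen by average silhouette
  width.  By default all subject-by-condition rows are clustered; a
  single-condition scope (e.g. only the cognitive epoch) is available via
  `scope=` — both row scopes are defensible for this design and the choice
  is left explicit.

## Problem sizes used in the tests

Module tests run on 120-600 s single-epoch records and cohorts of 2-3
subjects with 300 s epochs; the end-to-end recovery checks use 20 subjects
at the full 3 x 600 s protocol, 200-replicate simulate-refit experiments at
34 subjects, and 500-seed null calibrations at n = 30.  These sizes were
chosen so the whole suite exercises every path at full protocol scale at
least once while staying comfortably fast on a laptop.

## Known limitations

* VFCDM reconstruction of broadband inputs is approximate (see above);
  band *energies*, which the markers use, are accurate.
* Anti-alias and demodulation filters leave edge transients of up to ~30 s;
  the epoch guard absorbs them inside sessions but the first/last guard of a
  session remains the least reliable stretch.
* The ectopic detector is an algorithmic stand-in (20% running-median rule)
  for a step that is done by eye in practice; its threshold is exposed.
* Synthetic self-report subscales (mental demand, effort, the two visual
  analogue scales) are noisy companions of the global score, present for
  schema completeness, not modelled constructs.
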