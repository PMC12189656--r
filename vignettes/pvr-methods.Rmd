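---
title: "Quantitative forefoot PVR analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative forefoot PVR analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvrdx)
```

## The problem

Pulse volume recording (PVR) measures the pulsatile volume change of a limb
segment under a cuff inflated to a standard pressure (50 mmHg at the
forefoot) and displays it as a pressure oscillation around zero. In diabetic
foot syndrome, medial arterial calcification renders ankle pressures and the
ankle–brachial index (ABI) unreliable, which makes waveform-based measures
attractive: the shape and size of the forefoot pulse degrade characteristically
with upstream arterial obstruction. `pvrdx` implements the quantitative
analysis of such recordings — feature extraction, semiquantitative grading,
calibrated cohort simulation, and diagnostic-test-accuracy statistics against
angiographic disease labels (GLASS stage for overall severity, the P0/P1/P2
inframalleolar descriptor for below-the-ankle outflow).

## Waveform model

A beat is synthesised as a piecewise curve through its fiducial knots:

* foot at value 0;
* systolic peak of height MSA (mmHg) at the upstroke time UST (ms);
* optionally a dicrotic notch at `UST + notch_delay`, carved to a fraction
  `notch_depth` below the notch-free descending limb, followed by a dicrotic
  wave recovering half the carved depth;
* a descent to baseline, with an optional flat tail occupying up to 35% of
  the period (`interbeat_flatness` scales this; 1 reproduces the scooped/flat
  diastolic interval of a healthy recording, 0 a continuous descent into the
  next foot).

The upstroke uses quarter-sine easing (finite slope at the foot, zero slope
at the peak), so the systolic onset is a sharp, localizable corner — the
"sharp upstroke" a reader sees on a healthy curve — while all other segments
use raised-cosine easing with zero slope at each knot. Knot interpolation
guarantees the notch is an exact local minimum at its nominal time, which is
what makes the generator usable as ground truth for detector validation. We
deliberately chose knot easing over a superposition of forward and reflected
waves: both produce realistic shapes, but only the former pins every fiducial
to an exact, known location.

Recordings concatenate beats with per-beat period jitter (2% coefficient of
variation by default, so segmentation cannot cheat by assuming a fixed
period), then add a slow sinusoidal baseline wander (8 s period, 0.05 mmHg
default amplitude, standing in for respiratory and vasomotor drift), white
Gaussian measurement noise (0.02 mmHg default), and optional uniform
quantization (18-bit over a 10 mmHg full scale reproduces the amplitude
resolution of a modern recorder; at 3.8e-5 mmHg steps it is practically
invisible). Motion artifacts are intentionally not modelled: studies exclude
non-analyzable recordings, so the simulator emulates the analyzable ones.

The four canonical class presets (at an 800 ms period): normal — UST 220 ms,
MSA 1.1 mmHg, notch depth 0.15, flat interval present; mildly abnormal —
UST 250 ms, MSA 0.6 mmHg, no notch, no flat interval; severely abnormal —
UST 300 ms, MSA 0.25 mmHg, no notch (upstroke approaching the downslope
duration); non-pulsatile — MSA 0. Recording duration defaults to 10 s
(about 12 beats), our choice: long enough for a median over beats to be
robust, short enough to be realistic for routine cuff recordings.

## Fiducial detection and features

Detection runs on filtered copies of the trace (4th-order zero-phase
Butterworth low-pass at 15 Hz for shape criteria; a 40 Hz copy for value and
timing readout; a 0.3–15 Hz band-pass for segmentation):

1. **Pulsatility.** A recording is pulsatile when the band-passed signal has
   an autocorrelation peak ≥ 0.25 at a lag in the physiologic 300–2000 ms
   band and the cycle-averaged waveform (folding at the detected period
   averages noise away) has an excursion of at least 0.05 mmHg. The
   published grading criterion is qualitative ("no visible pulsation"); the
   0.05 mmHg floor is our operationalization, and the simulator-swept
   decision boundary sits at ~0.05 mmHg of true amplitude.
2. **Feet.** One maximal-upslope event is found per cycle; the foot is the
   local minimum immediately preceding it. Because that minimum sits on a
   near-flat segment (exactly flat when a diastolic plateau is present), its
   argmin wanders under noise, so the foot is refined by back-projecting the
   fitted maximal-upslope tangent onto the minimum's level — the classical
   intersecting-tangent construction, used here only to resolve the plateau
   ambiguity. On noise-free synthetic beats this localizes feet within
   ±2 ms.
3. **Peak and notch.** The peak is the window argmax, refined on the 40 Hz
   copy; the dicrotic notch is the most prominent local minimum strictly
   between the peak and 85% of the window, requiring prominence ≥ 2% of the
   beat amplitude (shallower troughs are indistinguishable from noise
   ripple).
4. **Amplitudes.** MSA is the peak height above a linear baseline through
   the two adjacent feet (cancelling residual drift without distorting the
   beat), read from the 40 Hz copy because heavier smoothing blurs the sharp
   foot corner upward by about 2% of the amplitude.
5. **Summaries.** Per-beat values are summarised by the median over
   quality-accepted beats (≥ 3 required), making one corrupted beat
   harmless. USR is computed as the reported UST divided by the reported
   wavelength — never rounded independently. The flat-interval indicator
   uses the magnitude of a least-squares slope over the last 15% of the beat
   (< 10% of the mean upstroke slope counts as flat); a fitted slope is used
   because the mean absolute sample-to-sample slope is floored by noise even
   on a truly flat segment.

All times are reported on the native 1 ms grid without sub-sample
interpolation. Whether a clinical device derives MSA from a best beat or an
average is not documented anywhere we know of; median-of-beats is this
package's contract.

## Morphology grading

The rule cascade mirrors the visual grading vocabulary: non-pulsatile if no
pulsation; normal if notch present, flat interval present, and the upstroke
sharp; severely abnormal if the upstroke is prolonged *and* the amplitude
flattened (MSA < 0.35 mmHg); otherwise mildly abnormal. "Prolonged" means an
upstroke/downslope duration ratio ≥ 0.53 or USR ≥ 0.344. These thresholds are
placed equidistant between the mildly-abnormal (ratio 0.455, USR 0.3125) and
severely-abnormal (ratio 0.60, USR 0.375) class prototypes, maximizing the
noise margin of the boundary; because rule 3 also requires a flattened
amplitude, the upstroke boundary cannot touch normal or mildly abnormal
curves with preserved amplitude. The absolute amplitude threshold is a
modelling choice — human raters are not documented to use one — anchored just
above the severe-disease MSA mean (≈ 0.31 mmHg). All three constants are
config-exposed via `morphology_thresholds()`; the defaults are fixed and used
by the tests. With these defaults each canonical preset classifies as itself
in ≥ 99% of noisy simulations (noise SD 0.03 mmHg), and grading is total,
exclusive, and monotone: decreasing MSA or prolonging the upstroke never
moves a limb toward normal.

## Cohort simulation

The simulator is calibrated to the published per-cell feature statistics by
GLASS stage × inframalleolar descriptor: 11 populated cells, 90 limbs, 6 of
them non-pulsatile (one in P0/GLASS II, five in P1/GLASS III). Cell
statistics are treated as describing the pulsatile limbs (n − non-pulsatile),
the reading under which the n-weighted pooled means reproduce the published
overall UST 260 ms and USR 0.32 over 84 limbs exactly; treating them as
all-limb statistics does not. The single-limb P2/no-PAD cell prints no SD
and is simulated as a point mass at its printed values.

Each feature is drawn from an independent truncated normal (MSA ≥ 0,
UST > 0, 0 < USR < 1) whose parent parameters are solved by moment matching
so the *realized* post-truncation mean/SD equal the printed cell statistics
— the printed values are sample moments, so the realized moments are the
calibration target. One cell (GLASS III/P0, MSA 0.16 ± 0.16 mmHg) sits at
the dispersion supremum of a zero-truncated normal (coefficient of variation
1); the calibrator matches its mean exactly and its SD to within 2%, and
raises an explicit error for targets outside that band. Draws go through the
quantile function with antithetic uniform pairs (on by default): marginals
are exact and realized cell means converge fast, which is the point of a
*calibrated* simulator — at scale 100 the realized no-PAD/P0 MSA mean is
within ±0.02 mmHg of its 1.10 mmHg target across seeds.

Joint structure is deliberately minimal: features are independent within a
cell (only marginals are published), elevated ABI (≥ 1.3, prevalence 54.4%)
is independent of GLASS stage by default (published mean ABI is nearly
identical for normal and mildly abnormal recordings; a log-odds coupling
knob exists for sensitivity analyses), infection is Bernoulli(59/90), and
the notch/flat-interval indicators are generated as present exactly for
GLASS 0 limbs. That last simplification slightly understates the published
38.9% prevalence of normal morphology (GLASS 0 is 28.9% of limbs) and makes
visual grade and disease stage more coupled than in real patients. What
passing tests on these cohorts show is therefore that the *pipeline*
reproduces the qualitative published pattern under the published marginals —
not that real forefoot PVRs behave this way; real data carry feature
correlations, rater noise, and morphology/stage discordance the simulator
does not emulate.

`features_to_traces()` closes the loop by rendering each simulated limb as a
waveform, so the whole chain trace → features → grade → statistics can be
exercised end to end; at the default noise level the extracted MSA matches
the simulated record within 5% for ≥ 95% of limbs of a study-sized cohort.

## Diagnostic accuracy statistics

ROC analysis uses the empirical curve over all distinct thresholds with
trapezoidal AUC — equal, under the Mann–Whitney tie convention, to
P(diseased marker worse than disease-free) + ½ P(tied), which the test suite
verifies against a brute-force all-pairs count. MSA is analyzed with lower
values indicating disease; UST and USR with higher values; cut-offs keep
their units and sign. The AUC confidence interval is a stratified bootstrap
percentile interval (2000 resamples, seeded); the published work does not
state its CI method, and a bootstrap makes the fewest distributional
assumptions. Cut-offs maximize Youden's J (the selection rule is likewise
unstated in the literature this package follows; Youden is the standard
default), with ties broken toward higher specificity. Kappa is unweighted
Cohen's kappa. Mann–Whitney/Kruskal–Wallis/χ² wrap the standard R
implementations; for ≤ 8 observations per group the Mann–Whitney p-value is
computed by exhaustive permutation (and, with ties, by enumeration over the
tied pool). No multiple-testing adjustment is applied, matching univariate
reporting practice; reports round percentages to one decimal and AUCs to
two. The revascularization-response rule classifies a limb as responder when
MSA increases by at least 0.1 mmHg (inclusive).

Non-pulsatile limbs are excluded from all quantitative accuracy analyses —
their time-domain features are undefined — mirroring the published handling
(84 of 90 limbs analyzed quantitatively).

## Numerical choices and degenerate inputs

* Filters: Butterworth, zero-phase via forward–backward application; traces
  shorter than the warm-up raise an error rather than returning transients.
* Beat windows shorter than 200 ms are flagged `rejected`, not silently
  used; pulsatile recordings with fewer than 3 usable beats raise an
  insufficient-data error.
* Undefined ratios (PPV with no positive calls, features of non-pulsatile
  limbs) are reported as `NA`, never as 0.
* Single-class label vectors, empty rating sets, all-tied rank tests and
  empty subgroups raise explicit errors or warnings naming the condition.
* All stochastic entry points take a seed and are bitwise reproducible;
  pipeline reports embed a configuration hash.

## Problem sizes used by the test suite

Module tests run on 10 s traces (12 beats); recovery and separability
properties use 200 seeds per morphology class at noise SD 0.03 mmHg;
calibration checks use scale-100 cohorts (9000 limbs); the qualitative
accuracy-ordering check averages AUCs over five replicate scale-100 cohorts,
because a single cohort's AUC differences are of the same order as their
Monte-Carlo spread; the round-trip check uses a study-sized (scale-1)
cohort. These sizes were chosen so each check is decisively powered for the
property it tests.

## Known limitations

* The simulator reproduces published *marginal* feature distributions;
  correlations between UST, USR and MSA within a limb are not calibrated
  (no published source), so multivariable analyses on simulated cohorts are
  not meaningful.
* Grading thresholds operationalize qualitative clinical language; absolute
  values (especially the 0.35 mmHg flattening threshold) are choices, not
  measurements.
* Only the forefoot level is modelled; thigh/calf gradients, arrhythmia,
  motion artifacts and absolute volume calibration are out of scope.
* The AUC levels attainable on simulated cohorts (≈ 0.72–0.81) are lower
  than the published real-data figures (0.82–0.89): independent truncated
  normals calibrated to the printed per-cell moments overlap more than the
  real joint distribution evidently does. The qualitative pattern — MSA
  strongest for any-PAD detection, MSA depressed with impaired
  inframalleolar outflow, severe grades accumulating with GLASS stage — is
  reproduced; the exact real-data operating points are not reproducible
  without the clinical dataset.
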