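# pvrdx

Forefoot **pulse volume recordings** (PVR) for noninvasive detection of
peripheral arterial disease (PAD) in diabetic foot syndrome.

In diabetic feet, medial arterial calcification makes ankle pressures and the
ankle–brachial index (ABI) unreliable, so cuff-based plethysmography at the
forefoot is one of the few noninvasive windows on foot perfusion. `pvrdx`
implements the full quantitative PVR analysis chain for researchers in
vascular medicine and diagnostic-accuracy methodology:

- **Waveform simulation** — annotated synthetic PVR traces of the four
  classical morphology classes (normal, mildly abnormal, severely abnormal,
  non-pulsatile), with heart-period jitter, baseline drift, noise, and
  quantization, plus ground-truth fiducials for validating detectors.
- **Fiducial detection & feature extraction** — beat segmentation, waveform
  foot / systolic peak / dicrotic notch detection, and the quantitative
  features **UST** (upstroke time, ms), **USR** (upstroke ratio,
  UST / wavelength), and **MSA** (maximum systolic amplitude, mmHg;
  peak minus preceding foot).
- **Semiquantitative grading** — a deterministic rule cascade mapping
  features to the four morphology classes.
- **Cohort simulation** — limb-level synthetic cohorts whose per-cell
  (GLASS stage × inframalleolar descriptor) feature distributions,
  non-pulsatile counts, elevated-ABI fraction and infection prevalence are
  calibrated to published study statistics via moment-matched truncated
  normals.
- **Diagnostic test accuracy** — ROC/AUC with stratified bootstrap CIs,
  Youden-optimal cut-offs, 2×2 contingency metrics, Cohen's kappa,
  Mann–Whitney/Kruskal–Wallis/χ² tests, and the revascularization-response
  rule (ΔMSA ≥ 0.1 mmHg).

Everything is tidyverse-shaped: data frames in, tibbles out, `autoplot()`
for every result type, `tidy()`/`glance()` for fitted objects.

## Worked example

Simulate a mildly abnormal recording, extract its features, grade it, and
evaluate diagnostic accuracy on a calibrated synthetic cohort:

```r
library(pvrdx)

tr <- generate_trace(trace_config(duration = 10, noise_sd = 0.02, seed = 42),
                     "mildly_abnormal")
f  <- extract_features(tr)
f[, c("ust_ms", "usr", "msa_mmhg", "wavelength_ms", "n_beats_used")]
#>   ust_ms    usr msa_mmhg wavelength_ms n_beats_used
#> 1    265 0.3268   0.5986           811           12
```

The true generator values were UST 250 ms, MSA 0.6 mmHg and an 800 ms
wavelength; at this noise level the detector recovers MSA within 0.3% and
UST within a beat-jitter-dominated 15 ms. Grading applies the rule cascade —
no dicrotic notch, no flat interval, steep upstroke, preserved amplitude:

```r
classify_morphology(f)$morphology
#> [1] mildly_abnormal
```

A Table-calibrated cohort at 100× the study size, evaluated for severe PAD
(GLASS ≥ II):

```r
cohort <- simulate_cohort(scale = 100, seed = 1)
evaluate_cohort(cohort, "severe_pad", ci = FALSE)
#>    feature   auc  cutoff sensitivity specificity
#> 1 msa_mmhg 0.721   0.412       0.852       0.559
#> 2   ust_ms 0.711 270.267       0.577       0.739
#> 3      usr 0.725   0.331       0.612       0.727
```

The MSA cut-off (0.41 mmHg here) falls in the clinically plausible
0.2–0.45 mmHg band for severe PAD; AUCs near 0.72 reflect the overlap of
the per-stage feature distributions the simulator was calibrated to. For
any-PAD detection (GLASS ≥ I) MSA reaches AUC ≈ 0.81 and is systematically
the strongest of the three markers.

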