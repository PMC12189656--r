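test_that("beat segmentation finds every complete cycle", {
  tr <- generate_trace(clean_config(seed = 2), "normal")
  win <- segment_beats(tr)
  expect_equal(nrow(win), 12)
  # flat trace: empty segmentation
  flat <- generate_trace(trace_config(noise_sd = 0.01,
                                      baseline_drift_amplitude = 0,
                                      seed = 1), "non_pulsatile")
  expect_equal(nrow(segment_beats(flat)), 0)
})

test_that("segmentation tracks jittered feet within 40 ms", {
  n_windows <- integer(0)
  worst <- 0
  for (s in 1:40) {
    tr <- generate_trace(trace_config(seed = s, noise_sd = 0.02), "normal")
    gt <- attr(tr, "ground_truth")
    win <- segment_beats(tr)
    n_windows <- c(n_windows, nrow(win))
    err <- vapply(win$foot_ms, function(f) min(abs(f - gt$foot_ms)),
                  numeric(1))
    worst <- max(worst, max(err))
  }
  expect_true(all(n_windows >= 11 & n_windows <= 12))
  expect_lte(worst, 40)
})

test_that("noise-free features match the generator ground truth", {
  tr <- generate_trace(clean_config(seed = 1), plain_beat(0.6, 250))
  f <- extract_features(tr)
  expect_true(f$pulsatile)
  expect_equal(f$ust_ms, 250, tolerance = 3 / 250)
  expect_equal(f$usr, 0.3125, tolerance = 0.005 / 0.3125)
  expect_equal(f$msa_mmhg, 0.6, tolerance = 0.01)
  expect_equal(f$wavelength_ms, 800, tolerance = 2 / 800)
  # the preset contract: every canonical shape is recovered
  for (m in PULSATILE_PRESETS) {
    p <- morphology_preset(m)
    fm <- extract_features(generate_trace(clean_config(seed = 2), m))
    expect_lte(abs(fm$ust_ms - p$upstroke_time), 3)
    expect_lte(abs(fm$wavelength_ms - p$wavelength), 2)
    expect_lte(abs(fm$msa_mmhg - p$amplitude) / p$amplitude, 0.01)
  }
})

test_that("non-pulsatile recordings yield msa 0 and undefined time features", {
  tr <- generate_trace(trace_config(noise_sd = 0.02,
                                    baseline_drift_amplitude = 0,
                                    seed = 4), "non_pulsatile")
  f <- extract_features(tr)
  expect_false(f$pulsatile)
  expect_equal(f$msa_mmhg, 0)
  expect_true(is.na(f$ust_ms))
  expect_true(is.na(f$usr))
  expect_true(is.na(f$wavelength_ms))
})

test_that("usr is the exact ratio of reported ust and wavelength", {
  for (s in 1:5) {
    f <- extract_features(generate_trace(noisy_config(seed = s), "normal"))
    expect_identical(f$usr, f$ust_ms / f$wavelength_ms)
    expect_gt(f$usr, 0)
    expect_lt(f$usr, 1)
  }
})

test_that("features are scale-equivariant in amplitude", {
  tr <- generate_trace(noisy_config(seed = 6), "normal")
  f0 <- extract_features(tr)
  for (c_mult in c(2, 10)) {
    tr2 <- tr
    tr2$pressure_mmhg <- tr$pressure_mmhg * c_mult
    f <- extract_features(tr2)
    expect_equal(f$msa_mmhg, c_mult * f0$msa_mmhg, tolerance = 0.01)
    expect_lte(abs(f$ust_ms - f0$ust_ms), 3)
    expect_equal(f$wavelength_ms, f0$wavelength_ms, tolerance = 0.01)
    expect_identical(f$notch_present, f0$notch_present)
  }
})

test_that("features are invariant to a circular time shift", {
  tr <- generate_trace(clean_config(seed = 9), "mildly_abnormal")
  f0 <- extract_features(tr)
  for (shift in c(150, 413)) {
    tr2 <- tr
    tr2$pressure_mmhg <- c(tail(tr$pressure_mmhg, shift),
                           head(tr$pressure_mmhg, -shift))
    f <- extract_features(tr2)
    expect_lte(abs(f$ust_ms - f0$ust_ms), 3)
    expect_lte(abs(f$wavelength_ms - f0$wavelength_ms), 3)
    expect_equal(f$msa_mmhg, f0$msa_mmhg, tolerance = 0.02)
  }
})

test_that("a pulsatile trace with too few beats raises insufficient-data", {
  tr <- generate_trace(clean_config(seed = 1, duration = 3.05),
                       plain_beat(0.8, 250, wavelength = 1400))
  expect_error(extract_features(tr), "insufficient")
})

test_that("fiducial detection rejects too-short windows and finds the argmax peak", {
  short <- detect_fiducials(rep(0.1, 150))
  expect_identical(short$quality_flag, "rejected")
  y <- generate_beat(morphology_preset("mildly_abnormal"))
  ann <- detect_fiducials(y)
  expect_identical(ann$quality_flag, "ok")
  expect_equal(ann$peak_ms, which.max(y) - 1)
  expect_true(is.na(ann$notch_ms))  # notch-free preset
})
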