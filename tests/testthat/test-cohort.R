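test_that("the default configuration reproduces the study bookkeeping", {
  cfg <- default_cohort_config()
  expect_equal(sum(cfg$cells$n), 90)
  expect_equal(sum(cfg$cells$n_nonpulsatile), 6)
  p0_nopad <- dplyr::filter(cfg$cells, glass == "0", imd == "P0")
  expect_equal(p0_nopad$msa_mean, 1.10)
  pooled <- pooled_feature_means(cfg)
  expect_equal(pooled$n_pulsatile, 84)
  expect_equal(pooled$ust_mean, 260, tolerance = 0.5 / 260)
  expect_equal(pooled$usr_mean, 0.32, tolerance = 0.005 / 0.32)
})

test_that("a scale-1 cohort has exactly the study counts", {
  cohort <- simulate_cohort(scale = 1, seed = 2)
  expect_equal(nrow(cohort), 90)
  expect_equal(sum(!cohort$pulsatile), 6)
  expect_equal(sum(cohort$pulsatile), 84)
  by_cell <- dplyr::count(cohort, glass, imd)
  expect_equal(nrow(by_cell), 11)
})

test_that("simulated cohorts are reproducible and respect truncation", {
  a <- simulate_cohort(scale = 10, seed = 5)
  b <- simulate_cohort(scale = 10, seed = 5)
  expect_identical(a, b)
  pu <- dplyr::filter(a, pulsatile)
  expect_true(all(pu$msa_mmhg >= 0))
  expect_true(all(pu$usr > 0 & pu$usr < 1))
  expect_true(all(pu$ust_ms > 0))
  expect_true(all(a$abi >= 0))
})

test_that("realized cell and pooled moments match the calibration table", {
  cohort <- simulate_cohort(scale = 100, seed = 1)
  p0 <- dplyr::filter(cohort, glass == "0", imd == "P0")
  expect_equal(mean(p0$msa_mmhg), 1.10, tolerance = 0.02 / 1.10)
  pu <- dplyr::filter(cohort, pulsatile)
  expect_equal(mean(pu$ust_ms), 260, tolerance = 2 / 260)
  expect_equal(mean(pu$usr), 0.32, tolerance = 0.005 / 0.32)
  expect_equal(mean(cohort$abi_ge_1_3), 0.544, tolerance = 0.01 / 0.544)
})

test_that("mean MSA decreases over GLASS stage within P0", {
  cohort <- simulate_cohort(scale = 50, seed = 7)
  p0 <- dplyr::filter(cohort, imd == "P0", pulsatile)
  means <- tapply(p0$msa_mmhg, droplevels(p0$glass), mean)
  expect_true(all(diff(means) < 0))
})

test_that("limb records render to traces that close the loop", {
  cohort <- simulate_cohort(scale = 1, seed = 1)
  traces <- features_to_traces(cohort, noise_sd = 0.02,
                               baseline_drift_amplitude = 0, seed = 1)
  expect_length(traces, 90)
  # non-pulsatile records give flat traces
  np <- which(!cohort$pulsatile)[1]
  expect_lt(diff(range(smooth_trace(traces[[np]], 15)$pressure_mmhg)), 0.05)
  # determinism
  again <- features_to_traces(cohort, noise_sd = 0.02,
                              baseline_drift_amplitude = 0, seed = 1)
  expect_identical(traces[[1]]$pressure_mmhg, again[[1]]$pressure_mmhg)
})

test_that("msa survives the record -> trace -> extraction round trip", {
  cohort <- simulate_cohort(scale = 1, seed = 11)
  traces <- features_to_traces(cohort, noise_sd = 0.02, seed = 3)
  rel_err <- purrr::map_dbl(seq_len(nrow(cohort)), function(i) {
    truth <- cohort$msa_mmhg[i]
    got <- tryCatch(extract_features(traces[[i]])$msa_mmhg,
                    error = function(e) NA_real_)
    if (!cohort$pulsatile[i]) {
      return(if (isTRUE(got == 0)) 0 else 1)
    }
    abs(got - truth) / truth
  })
  expect_gte(mean(rel_err <= 0.05, na.rm = FALSE), 0.95)
})
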