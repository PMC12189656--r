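feat_row <- function(msa, usr, notch = FALSE, flat = FALSE,
                     pulsatile = TRUE, ratio = NULL) {
  tibble::tibble(
    pulsatile = pulsatile, msa_mmhg = msa, usr = usr,
    upstroke_downslope_ratio = ratio %||% (usr / (1 - usr)),
    notch_present = notch, flat_interval_present = flat
  )
}

test_that("the rule cascade reproduces the four class definitions", {
  # canonical normal: notch + flat interval + sharp upstroke
  g <- classify_morphology(feat_row(1.1, 0.275, notch = TRUE, flat = TRUE))
  expect_equal(as.character(g$morphology), "normal")
  # non-pulsatile short-circuits everything
  g <- classify_morphology(feat_row(0, NA, pulsatile = FALSE))
  expect_equal(as.character(g$morphology), "non_pulsatile")
  # flattened amplitude + prolonged upstroke
  g <- classify_morphology(feat_row(0.2, 0.43))
  expect_equal(as.character(g$morphology), "severely_abnormal")
  # preserved amplitude, steep upstroke, no notch
  g <- classify_morphology(feat_row(0.6, 0.31))
  expect_equal(as.character(g$morphology), "mildly_abnormal")
})

test_that("every feature vector maps to exactly one grade with a rationale", {
  grid <- tidyr::expand_grid(
    msa = c(0.05, 0.2, 0.34, 0.36, 0.6, 1.2),
    usr = c(0.2, 0.3, 0.355, 0.365, 0.45),
    notch = c(TRUE, FALSE),
    flat = c(TRUE, FALSE)
  )
  f <- feat_row(grid$msa, grid$usr, grid$notch, grid$flat)
  g <- classify_morphology(f)
  expect_false(anyNA(g$morphology))
  expect_true(all(nzchar(g$morphology_rationale)))
  expect_setequal(intersect(levels(g$morphology), unique(as.character(g$morphology))),
                  c("normal", "mildly_abnormal", "severely_abnormal"))
})

test_that("lower msa or longer upstroke never moves a limb toward normal", {
  rank_of <- function(g) match(as.character(g), c("normal",
                                                  "mildly_abnormal",
                                                  "severely_abnormal",
                                                  "non_pulsatile"))
  msa_grid <- seq(1.2, 0.05, by = -0.05)
  usr_grid <- seq(0.2, 0.48, by = 0.02)
  for (notch in c(TRUE, FALSE)) {
    # decreasing msa at fixed usr
    for (usr in c(0.25, 0.37)) {
      g <- classify_morphology(feat_row(msa_grid, usr, notch, notch))
      expect_true(all(diff(rank_of(g$morphology)) >= 0))
    }
    # increasing usr at fixed msa
    for (msa in c(0.2, 0.8)) {
      g <- classify_morphology(feat_row(msa, usr_grid, notch, notch))
      expect_true(all(diff(rank_of(g$morphology)) >= 0))
    }
  }
})

test_that("severe and non-pulsatile grades accumulate with GLASS stage", {
  cohort <- simulate_cohort(scale = 50, seed = 3)
  graded <- classify_morphology(cohort)
  frac <- tapply(
    graded$morphology %in% c("severely_abnormal", "non_pulsatile"),
    graded$glass,
    mean
  )
  expect_true(all(diff(frac) > 0))
})
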