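test_that("the empirical AUC equals all-pairs counting on random instances", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(10:200, 1)
      d <- tibble::tibble(
        score = round(rnorm(n), sample(c(0, 1, 3), 1)),  # induce ties
        label = rbinom(n, 1, 0.4)
      )
      if (length(unique(d$label)) < 2) next
      for (dir in c("higher_is_disease", "lower_is_disease")) {
        r <- pvr_roc(d, "score", "label", direction = dir, ci = FALSE)
        expect_equal(r$auc, auc_bruteforce(d$score, d$label, dir),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("toy ROC examples behave as expected", {
  d <- tibble::tibble(score = c(1, 2, 3, 4), label = c(0, 0, 1, 1))
  r <- pvr_roc(d, "score", "label", ci = FALSE)
  expect_equal(r$auc, 1)
  cut <- youden_cutoff(r)
  expect_gt(cut$threshold, 2)
  expect_lt(cut$threshold, 3)
  expect_equal(cut$youden_j, 1)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)

  # alternating labels: 1 concordant of 4 pairs
  d2 <- tibble::tibble(score = c(1, 2, 3, 4), label = c(1, 0, 1, 0))
  expect_equal(pvr_roc(d2, "score", "label", ci = FALSE)$auc,
               auc_bruteforce(d2$score, d2$label, "higher_is_disease"))

  # direction symmetry
  withr::with_seed(1, {
    d3 <- tibble::tibble(score = rnorm(40), label = rbinom(40, 1, 0.5))
  })
  a_hi <- pvr_roc(d3, "score", "label", "higher_is_disease", ci = FALSE)$auc
  a_lo <- pvr_roc(d3, "score", "label", "lower_is_disease", ci = FALSE)$auc
  expect_equal(a_hi + a_lo, 1)

  expect_error(pvr_roc(tibble::tibble(score = 1:4, label = rep(1, 4)),
                       "score", "label"),
               "at least one")
})

test_that("ROC curves are monotone and the bootstrap CI brackets the AUC", {
  withr::with_seed(7, {
    d <- tibble::tibble(score = c(rnorm(60, 1), rnorm(60)),
                        label = rep(c(1, 0), each = 60))
  })
  r <- pvr_roc(d, "score", "label", ci = TRUE, boot_n = 400, seed = 3)
  # as the threshold tightens, sensitivity falls and specificity rises
  expect_true(all(diff(r$curve$sens) <= 0))
  expect_true(all(diff(r$curve$spec) >= 0))
  expect_lte(r$auc_ci_low, r$auc)
  expect_gte(r$auc_ci_high, r$auc)
  expect_true(all(r$curve$sens >= 0 & r$curve$sens <= 1))
  # CI reproducible under the same seed
  r2 <- pvr_roc(d, "score", "label", ci = TRUE, boot_n = 400, seed = 3)
  expect_identical(c(r$auc_ci_low, r$auc_ci_high),
                   c(r2$auc_ci_low, r2$auc_ci_high))
})

test_that("contingency metrics equal their defining ratios", {
  m <- contingency_metrics(9, 0, 1, 10)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 1.0)
  m0 <- contingency_metrics(0, 0, 5, 5)
  expect_equal(m0$sensitivity, 0)
  expect_true(is.na(m0$ppv))
  expect_error(contingency_metrics(-1, 0, 0, 0), "non-negative")
  withr::with_seed(21, {
    for (i in 1:25) {
      cts <- rpois(4, 5)
      m <- contingency_metrics(cts[1], cts[2], cts[3], cts[4])
      if (cts[1] + cts[3] > 0) {
        expect_equal(m$sensitivity, cts[1] / (cts[1] + cts[3]))
      }
      if (cts[4] + cts[2] > 0) {
        expect_equal(m$specificity, cts[4] / (cts[4] + cts[2]))
      }
      if (cts[1] + cts[2] > 0) {
        expect_equal(m$ppv, cts[1] / (cts[1] + cts[2]))
      }
      if (cts[4] + cts[3] > 0) {
        expect_equal(m$npv, cts[4] / (cts[4] + cts[3]))
      }
    }
  })
})

test_that("Cohen's kappa matches hand-computed values", {
  expect_equal(cohens_kappa(c("a", "b", "c"), c("a", "b", "c"))$kappa, 1)
  # confusion matrix [[20, 5], [10, 15]]: po 0.7, pe 0.5, kappa 0.4
  a <- c(rep("x", 25), rep("y", 25))
  b <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  k <- cohens_kappa(a, b)
  expect_equal(k$observed_agreement, 0.7)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0.4)
  expect_lte(k$kappa, k$observed_agreement)
  # constant rater: po equals pe, kappa 0
  a2 <- c(rep("x", 6), rep("y", 4))
  k2 <- cohens_kappa(a2, rep("x", 10), categories = c("x", "y"))
  expect_equal(k2$kappa, 0)
  expect_error(cohens_kappa(character(0), character(0)), "no rating")
})

test_that("small-sample Mann-Whitney p equals exhaustive permutation", {
  withr::with_seed(5, {
    for (i in 1:5) {
      x <- round(rnorm(5), 2)
      y <- round(rnorm(6, 0.5), 2)
      res <- mann_whitney_u(x, y)
      expect_equal(res$p_value, mwu_perm_p(x, y), tolerance = 1e-9)
    }
  })
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u, 0)
  # identical large samples: p near 1
  z <- rnorm(50)
  expect_gt(mann_whitney_u(z, z, exact = FALSE)$p_value, 0.9)
  expect_error(mann_whitney_u(rep(1, 5), rep(1, 5)), "tied")
})

test_that("exact and asymptotic Mann-Whitney p agree for moderate n", {
  withr::with_seed(31, {
    for (i in 1:5) {
      x <- rnorm(20)
      y <- rnorm(20, 0.3)
      p_exact <- mann_whitney_u(x, y, exact = TRUE)$p_value
      p_asym <- mann_whitney_u(x, y, exact = FALSE)$p_value
      expect_lte(abs(p_exact - p_asym), 0.02)
      expect_true(p_exact >= 0 && p_exact <= 1)
    }
  })
})

test_that("Kruskal-Wallis and chi-squared wrappers return standard results", {
  g <- list(c(1, 2, 3, 9), c(4, 5, 6), c(7, 8, 10))
  kw <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(kw$h, unname(ref$statistic))
  expect_equal(kw$p_value, ref$p.value)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "tied")

  tab <- matrix(c(20, 10, 5, 25), 2)
  cs <- chi_square(tab)
  ref2 <- chisq.test(tab, correct = FALSE)
  expect_equal(cs$statistic, unname(ref2$statistic))
  expect_equal(cs$p_value, ref2$p.value)
})

test_that("revascularization response uses an inclusive 0.1 mmHg threshold", {
  # clean separation
  m <- revasc_response(pre_msa = c(0.2, 0.2, 0.3, 0.4),
                       post_msa = c(0.5, 0.55, 0.3, 0.42),
                       success_labels = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  # a delta of exactly 0.1 counts as response
  m2 <- revasc_response(0.3, 0.4, TRUE)
  expect_equal(m2$tp, 1)
  expect_error(revasc_response(c(0.1, 0.2), c(0.2), TRUE), "equal length")
})

test_that("simulated revascularization cohorts recover plausible sensitivity", {
  # paired-change model: success deltas N(0.24, 0.26) for 35 limbs,
  # failure deltas N(-0.07, 0.3) for 9 limbs
  withr::with_seed(17, {
    sens <- replicate(1000, {
      d_s <- rnorm(35, 0.24, 0.26)
      d_f <- rnorm(9, -0.07, 0.3)
      pre <- rep(0.3, 44)
      post <- pre + c(d_s, d_f)
      revasc_response(pre, post, rep(c(TRUE, FALSE), c(35, 9)))$sensitivity
    })
  })
  expect_gte(mean(sens), 0.5)
  expect_lte(mean(sens), 0.8)
})
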