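#' ROC analysis of a diagnostic marker
#'
#' Empirical ROC over all distinct thresholds with trapezoidal AUC (ties get
#' the Mann-Whitney half-credit, so the AUC equals
#' `P(marker_disease > marker_healthy) + 0.5 P(equal)` under the stated
#' direction) and a stratified-bootstrap percentile confidence interval.
#' Implemented on top of pROC.
#'
#' @param data Data frame holding marker and label columns.
#' @param score Column name (string) of the marker.
#' @param label Column name of the disease indicator (logical or 0/1).
#' @param direction `"higher_is_disease"` (e.g. upstroke time) or
#'   `"lower_is_disease"` (e.g. maximum systolic amplitude); cut-offs keep
#'   their original sign and units either way.
#' @param ci Compute a bootstrap CI for the AUC (default TRUE).
#' @param boot_n Bootstrap resamples (default 2000, stratified, percentile).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return An object of class `"pvr_roc"`: list with `thresholds`, `sens`,
#'   `spec` (tibble `curve`), `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `direction`, `n_pos`, `n_neg`, and the underlying `pROC::roc` object.
#' @export
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
#' pvr_roc(d, "x", "y", ci = FALSE)$auc  # 1
pvr_roc <- function(data, score, label,
                    direction = c("higher_is_disease", "lower_is_disease"),
                    ci = TRUE, boot_n = 2000, conf_level = 0.95,
                    seed = 1L) {
  direction <- match.arg(direction)
  s <- data[[score]]
  y <- as.integer(as.logical(data[[label]]))
  keep <- is.finite(s) & !is.na(y)
  s <- s[keep]
  y <- y[keep]
  if (length(unique(y)) < 2) {
    abort("ROC requires at least one diseased and one disease-free case")
  }
  dir <- if (direction == "higher_is_disease") "<" else ">"
  r <- pROC::roc(response = y, predictor = s, direction = dir,
                 levels = c(0, 1), quiet = TRUE)
  ci_vals <- c(NA_real_, NA_real_)
  if (ci) {
    ci_obj <- withr::with_seed(as.integer(seed), {
      pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n,
                   boot.stratified = TRUE, conf.level = conf_level)
    })
    ci_vals <- as.numeric(ci_obj)[c(1, 3)]
  }
  curve <- tibble(
    threshold = r$thresholds,
    sens = r$sensitivities,
    spec = r$specificities
  ) |> arrange(.data$threshold)
  structure(
    list(
      curve = curve,
      auc = as.numeric(pROC::auc(r)),
      auc_ci_low = ci_vals[1],
      auc_ci_high = ci_vals[2],
      direction = direction,
      n_pos = sum(y == 1),
      n_neg = sum(y == 0),
      roc_obj = r
    ),
    class = "pvr_roc"
  )
}

#' @export
print.pvr_roc <- function(x, ...) {
  cat(sprintf(
    "<pvr_roc> AUC %.3f%s (%s; %d diseased / %d disease-free)\n",
    x$auc,
    if (is.finite(x$auc_ci_low)) {
      sprintf(" [95%% CI %.3f-%.3f]", x$auc_ci_low, x$auc_ci_high)
    } else "",
    x$direction, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Youden-optimal cut-off
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1, with
#' ties broken toward the higher specificity (the more conservative rule-in
#' cut-off).
#'
#' @param roc A [pvr_roc()] result.
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "pvr_roc"))
  cv <- roc$curve
  j <- cv$sens + cv$spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(cv$spec[best])]
  tibble(
    threshold = cv$threshold[best],
    sensitivity = cv$sens[best],
    specificity = cv$spec[best],
    youden_j = j[best]
  )
}

#' 2x2 contingency metrics
#'
#' Sensitivity, specificity and predictive values from the four cells of a
#' diagnostic 2x2 table. Ratios with a zero denominator are reported as `NA`
#' rather than 0.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return One-row tibble with the counts and `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
#' @examples
#' contingency_metrics(9, 0, 1, 10)
contingency_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("contingency counts must be non-negative integers")
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Cohen's kappa for interrater agreement
#'
#' Unweighted kappa from the k x k confusion matrix of two raters, as used
#' for interobserver agreement of semiquantitative PVR grading.
#'
#' @param ratings_a,ratings_b Equal-length rating vectors.
#' @param categories Category levels (default: union of observed values).
#' @return An object of class `"pvr_kappa"`: list with
#'   `observed_agreement`, `expected_agreement`, `kappa`, `n_pairs`,
#'   `confusion` (matrix).
#' @export
#' @examples
#' cohens_kappa(c("a", "a", "b"), c("a", "a", "b"))$kappa  # 1
cohens_kappa <- function(ratings_a, ratings_b, categories = NULL) {
  if (length(ratings_a) != length(ratings_b)) {
    abort("rating vectors must have equal length")
  }
  if (length(ratings_a) == 0) abort("no rating pairs supplied")
  categories <- categories %||%
    sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = categories)
  b <- factor(as.character(ratings_b), levels = categories)
  if (anyNA(a) || anyNA(b)) abort("ratings outside the category set")
  cm <- table(a, b)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  structure(
    list(observed_agreement = po, expected_agreement = pe, kappa = kappa,
         n_pairs = as.integer(n), confusion = unclass(cm)),
    class = "pvr_kappa"
  )
}

#' @export
print.pvr_kappa <- function(x, ...) {
  cat(sprintf(
    "<pvr_kappa> kappa %.3f (observed %.3f, expected %.3f, n = %d)\n",
    x$kappa, x$observed_agreement, x$expected_agreement, x$n_pairs
  ))
  invisible(x)
}

#' Nonparametric group comparisons
#'
#' Thin wrappers over the standard univariate tests used for group
#' comparisons of continuous PVR features (Mann-Whitney U, Kruskal-Wallis)
#' and categorical variables (chi-squared without continuity correction).
#' For small samples without ties `mann_whitney_u()` can compute the exact
#' permutation p-value.
#'
#' @param x,y Numeric samples.
#' @param exact Force the exact distribution (default: automatic for
#'   `length(x), length(y) <= 8`).
#' @return `mann_whitney_u()`: one-row tibble `u`, `p_value`, `exact`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    abort("all observations tied: rank variance is zero")
  }
  exact <- exact %||% (length(x) <= 8 && length(y) <= 8)
  ties <- any(duplicated(c(x, y)))
  if (exact && ties && length(x) + length(y) <= 16) {
    # exhaustive permutation distribution of U, valid under ties
    return(mwu_exact(x, y))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact)
  )
  tibble(u = unname(wt$statistic), p_value = wt$p.value,
         exact = exact && !ties)
}

mwu_exact <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pool <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pool), n)
  u_obs <- u_stat(x, y)
  mu <- n * length(y) / 2
  us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
  tibble(u = u_obs,
         p_value = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9),
         exact = TRUE)
}

#' @rdname mann_whitney_u
#' @param groups List of numeric vectors (>= 2 groups).
#' @return `kruskal_wallis()`: one-row tibble `h`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("need at least two non-empty groups")
  }
  if (length(unique(unlist(groups))) == 1) {
    abort("all observations tied: rank variance is zero")
  }
  kt <- kruskal.test(groups)
  tibble(h = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' @rdname mann_whitney_u
#' @param table A contingency table (matrix) of counts.
#' @return `chi_square()`: one-row tibble `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(table) {
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Revascularization response by MSA change
#'
#' Classify each limb as hemodynamic responder when its MSA increased by at
#' least `threshold` (inclusive) after the procedure, and cross-tabulate the
#' responder flag against angiographically adjudicated treatment success.
#'
#' @param pre_msa,post_msa Paired MSA values (mmHg) before/after
#'   revascularization.
#' @param success_labels Logical vector: angiographic success.
#' @param threshold Minimum MSA increase in mmHg (default 0.1).
#' @return One-row tibble: contingency metrics plus `threshold`.
#' @export
#' @examples
#' revasc_response(c(0.2, 0.3), c(0.5, 0.31), c(TRUE, FALSE))
revasc_response <- function(pre_msa, post_msa, success_labels,
                            threshold = 0.1) {
  n <- length(pre_msa)
  if (length(post_msa) != n || length(success_labels) != n) {
    abort("pre/post/success vectors must have equal length")
  }
  delta <- post_msa - pre_msa
  responder <- delta >= threshold
  success <- as.logical(success_labels)
  out <- contingency_metrics(
    tp = sum(responder & success),
    fp = sum(responder & !success),
    fn = sum(!responder & success),
    tn = sum(!responder & !success)
  )
  out$threshold <- threshold
  out
}
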