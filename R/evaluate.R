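ENDPOINTS <- c("any_pad", "severe_pad", "very_severe", "imd_disease")

endpoint_label <- function(records, endpoint) {
  switch(endpoint,
    any_pad = records$glass >= "I",
    severe_pad = records$glass >= "II",
    very_severe = records$glass == "III",
    imd_disease = records$imd %in% c("P1", "P2"),
    abort(sprintf("unknown endpoint '%s'", endpoint))
  )
}

FEATURE_DIRECTIONS <- c(
  msa_mmhg = "lower_is_disease",
  ust_ms = "higher_is_disease",
  usr = "higher_is_disease"
)

#' Diagnostic-test-accuracy evaluation of a cohort
#'
#' For each quantitative feature, run ROC analysis against the chosen
#' disease endpoint, pick the Youden-optimal cut-off, and derive the 2x2
#' contingency metrics at that cut-off. Non-pulsatile limbs are excluded
#' from quantitative analysis (their features are undefined), as are limbs
#' outside the optional subgroup. MSA is analyzed with lower values
#' indicating disease; UST and USR with higher values indicating disease, so
#' printed cut-offs keep their units and sign.
#'
#' @param records Cohort tibble ([simulate_cohort()] schema).
#' @param endpoint One of `"any_pad"` (GLASS >= I), `"severe_pad"`
#'   (GLASS >= II), `"very_severe"` (GLASS III), `"imd_disease"`
#'   (inframalleolar descriptor P1 or P2).
#' @param features Feature columns to evaluate.
#' @param subgroup Optional logical vector or one-sided formula (e.g.
#'   `~ abi_ge_1_3`, `~ infection`) restricting the analysis.
#' @param ci,boot_n,seed Bootstrap options forwarded to [pvr_roc()].
#' @return A tibble with one row per feature: `feature`, `endpoint`,
#'   `direction`, `n`, `n_pos`, `n_neg`, `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
#' @examples
#' cohort <- simulate_cohort(scale = 2, seed = 1)
#' evaluate_cohort(cohort, "any_pad", ci = FALSE)
evaluate_cohort <- function(records,
                            endpoint = "any_pad",
                            features = c("msa_mmhg", "ust_ms", "usr"),
                            subgroup = NULL,
                            ci = TRUE, boot_n = 2000, seed = 1L) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  keep <- records$pulsatile
  if (!is.null(subgroup)) {
    sel <- if (inherits(subgroup, "formula")) {
      rlang::eval_tidy(subgroup[[2]], data = records)
    } else {
      subgroup
    }
    keep <- keep & as.logical(sel)
  }
  d <- records[keep, ]
  if (nrow(d) == 0) {
    warn(sprintf("empty subgroup for endpoint '%s': skipped", endpoint))
    return(tibble(feature = character(), endpoint = character()))
  }
  d$.label <- endpoint_label(d, endpoint)

  map(features, function(feat) {
    dir <- FEATURE_DIRECTIONS[[feat]] %||% "higher_is_disease"
    r <- pvr_roc(d, feat, ".label", direction = dir, ci = ci,
                 boot_n = boot_n, seed = seed)
    cut <- youden_cutoff(r)
    pos_test <- if (dir == "lower_is_disease") {
      d[[feat]] <= cut$threshold
    } else {
      d[[feat]] >= cut$threshold
    }
    cm <- contingency_metrics(
      tp = sum(pos_test & d$.label), fp = sum(pos_test & !d$.label),
      fn = sum(!pos_test & d$.label), tn = sum(!pos_test & !d$.label)
    )
    tibble(
      feature = feat, endpoint = endpoint, direction = dir,
      n = nrow(d), n_pos = r$n_pos, n_neg = r$n_neg,
      auc = r$auc, auc_ci_low = r$auc_ci_low, auc_ci_high = r$auc_ci_high,
      cutoff = cut$threshold,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      ppv = cm$ppv, npv = cm$npv
    )
  }) |> list_rbind()
}
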