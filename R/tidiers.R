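#' Tidy an ROC result
#'
#' One row per threshold with sensitivity and specificity, broom-style.
#'
#' @param x A [pvr_roc()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pvr_roc <- function(x, ...) x$curve

#' @rdname tidy.pvr_roc
#' @return `glance()`: one-row tibble with `auc`, its CI, direction and
#'   group sizes.
#' @export
glance.pvr_roc <- function(x, ...) {
  tibble(
    auc = x$auc, auc_ci_low = x$auc_ci_low, auc_ci_high = x$auc_ci_high,
    direction = x$direction, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Tidy a kappa result
#'
#' @param x A [cohens_kappa()] result.
#' @param ... Unused.
#' @return `tidy()`: the confusion matrix in long form; `glance()`: one-row
#'   tibble with kappa, observed/expected agreement and pair count.
#' @export
tidy.pvr_kappa <- function(x, ...) {
  cm <- as_tibble(as.data.frame(as.table(x$confusion)))
  names(cm) <- c("rater_a", "rater_b", "n")
  cm
}

#' @rdname tidy.pvr_kappa
#' @export
glance.pvr_kappa <- function(x, ...) {
  tibble(
    kappa = x$kappa,
    observed_agreement = x$observed_agreement,
    expected_agreement = x$expected_agreement,
    n_pairs = x$n_pairs
  )
}
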