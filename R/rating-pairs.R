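#' Synthetic interobserver rating pairs
#'
#' A synthetic stand-in for the study's 51 interobserver rating pairs of
#' semiquantitative PVR grades: 44 concordant pairs (distributed over the
#' four classes roughly as the cohort's morphology prevalences) and 7
#' discordant pairs, mainly disagreements between normal and mildly
#' abnormal, the pattern reported for real raters. Useful for exercising
#' [cohens_kappa()] on realistic category structure and for reproducing the
#' published agreement arithmetic (44/51 = 86% observed agreement).
#'
#' @return A tibble with columns `rater_a`, `rater_b` (51 rows).
#' @export
#' @examples
#' k <- cohens_kappa(synthetic_rating_pairs()$rater_a,
#'                   synthetic_rating_pairs()$rater_b)
#' k$observed_agreement  # 44/51
synthetic_rating_pairs <- function() {
  concordant <- rep(c("normal", "mildly_abnormal", "severely_abnormal",
                      "non_pulsatile"),
                    times = c(18, 10, 13, 3))
  disc_a <- c(rep("normal", 3), rep("mildly_abnormal", 3),
              "severely_abnormal")
  disc_b <- c(rep("mildly_abnormal", 3), rep("normal", 3),
              "mildly_abnormal")
  tibble(
    rater_a = c(concordant, disc_a),
    rater_b = c(concordant, disc_b)
  )
}
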