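#' Morphology grading thresholds
#'
#' Numeric thresholds that operationalize the qualitative semiquantitative
#' grading vocabulary. A "prolonged" upstroke is one whose duration
#' approaches the downslope duration (`ratio_prolonged`) or occupies an
#' unusually large part of the cardiac cycle (`usr_prolonged`); a "flattened"
#' amplitude is an MSA below `msa_flattened`. Defaults are anchored to the
#' published per-class feature distributions: normal limbs run at USR near
#' 0.28, diseased limbs near 0.33-0.37, and MSA falls below ~0.31 mmHg in
#' severe disease. The prolonged-upstroke boundary is placed equidistant
#' from the canonical mildly-abnormal (USR 0.3125, upstroke/downslope ratio
#' 0.455) and severely-abnormal (USR 0.375, ratio 0.60) class prototypes,
#' which maximizes the noise margin of the rule; the flattened-amplitude
#' boundary sits just above the severe-disease MSA mean. Since rule 3 also
#' requires a flattened amplitude, the upstroke boundary never touches
#' normal or mildly abnormal curves with preserved amplitude.
#'
#' @param ratio_prolonged Upstroke/downslope duration ratio at or above which
#'   the upstroke counts as prolonged (default 0.53).
#' @param usr_prolonged USR at or above which the upstroke counts as
#'   prolonged (default 0.344).
#' @param msa_flattened MSA (mmHg) below which the amplitude counts as
#'   flattened (default 0.35).
#' @return Named list of thresholds.
#' @export
morphology_thresholds <- function(ratio_prolonged = 0.53,
                                  usr_prolonged = 0.344,
                                  msa_flattened = 0.35) {
  list(
    ratio_prolonged = ratio_prolonged,
    usr_prolonged = usr_prolonged,
    msa_flattened = msa_flattened
  )
}

#' Semiquantitative morphology grading
#'
#' Deterministic rule cascade reproducing the four-class visual grading of
#' forefoot PVRs:
#'
#' 1. no pulsatility: `non_pulsatile` (the PVR correlate of critical
#'    limb-threatening ischemia);
#' 2. dicrotic notch present, flat/scooped interval between peaks present,
#'    and a sharp (not prolonged) upstroke: `normal`;
#' 3. prolonged upstroke and flattened amplitude: `severely_abnormal`;
#' 4. otherwise: `mildly_abnormal` (notch and flat interval lost, upstroke
#'    still steep, amplitude preserved).
#'
#' Every feature row maps to exactly one grade, and decreasing MSA or
#' prolonging the upstroke never moves a limb toward `normal`.
#'
#' @param features A features tibble as returned by [extract_features()] (or
#'   a cohort tibble with columns `pulsatile`, `msa_mmhg`, `usr`, and
#'   optionally `upstroke_downslope_ratio`, `notch_present`,
#'   `flat_interval_present`). Missing notch/flat columns are treated as
#'   absent notch/flat interval; a missing ratio is derived as
#'   `usr / (1 - usr)`.
#' @param thresholds A [morphology_thresholds()] list.
#' @return The input tibble with columns `morphology` (factor with levels
#'   normal < mildly_abnormal < severely_abnormal < non_pulsatile) and
#'   `morphology_rationale` (rule identifiers that fired) appended.
#' @export
#' @examples
#' f <- extract_features(generate_trace(trace_config(seed = 1), "normal"))
#' classify_morphology(f)$morphology
classify_morphology <- function(features,
                                thresholds = morphology_thresholds()) {
  stopifnot(is.data.frame(features))
  f <- as_tibble(features)
  ratio <- if ("upstroke_downslope_ratio" %in% names(f)) {
    f$upstroke_downslope_ratio
  } else {
    rep(NA_real_, nrow(f))
  }
  miss <- is.na(ratio) & !is.na(f$usr)
  ratio[miss] <- f$usr[miss] / (1 - f$usr[miss])
  notch <- if ("notch_present" %in% names(f)) f$notch_present else FALSE
  flat <- if ("flat_interval_present" %in% names(f)) {
    f$flat_interval_present
  } else {
    FALSE
  }
  notch <- !is.na(notch) & notch
  flat <- !is.na(flat) & flat

  prolonged <- (!is.na(ratio) & ratio >= thresholds$ratio_prolonged) |
    (!is.na(f$usr) & f$usr >= thresholds$usr_prolonged)
  flattened <- !is.na(f$msa_mmhg) & f$msa_mmhg < thresholds$msa_flattened

  grade <- rep("mildly_abnormal", nrow(f))
  rationale <- rep("default_mildly_abnormal", nrow(f))

  sev <- f$pulsatile & prolonged & flattened
  grade[sev] <- "severely_abnormal"
  rationale[sev] <- "prolonged_upstroke+flattened_amplitude"

  nor <- f$pulsatile & notch & flat & !prolonged & !sev
  grade[nor] <- "normal"
  rationale[nor] <- "notch+flat_interval+sharp_upstroke"

  np <- !f$pulsatile
  grade[np] <- "non_pulsatile"
  rationale[np] <- "no_visible_pulsation"

  f$morphology <- factor(grade, levels = MORPHOLOGY_LEVELS, ordered = TRUE)
  f$morphology_rationale <- rationale
  f
}
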