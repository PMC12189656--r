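GLASS_LEVELS <- c("0", "I", "II", "III")
IMD_LEVELS <- c("P0", "P1", "P2")

#' Default cohort configuration
#'
#' The calibration table for the synthetic limb cohort: one cell per
#' GLASS stage x inframalleolar descriptor (IMD) combination, each carrying
#' its limb count, the count of non-pulsatile limbs, and mean/SD of UST, USR
#' and MSA for the pulsatile limbs. Values are the published forefoot PVR
#' feature statistics by angiographic severity: 90 limbs overall, 6 of them
#' non-pulsatile (one in the P0/GLASS II cell, five in P1/GLASS III); cell
#' statistics are treated as describing the pulsatile limbs
#' (`n_eff = n - n_nonpulsatile`), which reproduces the published pooled
#' means (UST 260 ms, USR 0.32 over the 84 quantitatively analyzed limbs).
#' The P2/no-PAD cell has a single limb and no printed SD; its SDs are 0.
#'
#' @param infection_prevalence Probability of a clinically evident foot
#'   infection (default 59/90).
#' @param abi_elevated_prob Probability of an incompressible-artery ankle
#'   brachial index >= 1.3 (default 0.544), independent of GLASS stage by
#'   default.
#' @param abi_glass_coupling Log-odds increment of elevated ABI per GLASS
#'   stage (default 0; sensitivity-analysis knob).
#' @param antithetic Use antithetic uniform pairs when sampling features so
#'   realized cell moments converge quickly (default TRUE).
#' @return A list of class `"cohort_config"` with elements `cells` (tibble),
#'   `infection_prevalence`, `abi_elevated_prob`, `abi_glass_coupling`,
#'   `antithetic`.
#' @export
#' @examples
#' cfg <- default_cohort_config()
#' sum(cfg$cells$n)               # 90 limbs
#' sum(cfg$cells$n_nonpulsatile)  # 6 non-pulsatile
default_cohort_config <- function(infection_prevalence = 59 / 90,
                                  abi_elevated_prob = 0.544,
                                  abi_glass_coupling = 0,
                                  antithetic = TRUE) {
  cells <- tibble(
    glass = factor(rep(c("0", "I", "II", "III"), times = c(3, 3, 3, 2)),
                   levels = GLASS_LEVELS, ordered = TRUE),
    imd = factor(c("P0", "P1", "P2", "P0", "P1", "P2", "P0", "P1", "P2",
                   "P0", "P1"),
                 levels = IMD_LEVELS),
    n = c(18L, 7L, 1L, 13L, 7L, 2L, 16L, 9L, 3L, 3L, 11L),
    n_nonpulsatile = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 5L),
    ust_mean = c(221, 215, 291, 271, 264, 231, 291, 296, 277, 236, 276),
    ust_sd   = c(30, 41, 0, 38, 38, 46, 51, 68, 97, 22, 53),
    usr_mean = c(0.28, 0.25, 0.43, 0.32, 0.33, 0.34, 0.37, 0.37, 0.33,
                 0.29, 0.33),
    usr_sd   = c(0.05, 0.03, 0, 0.03, 0.08, 0.11, 0.08, 0.06, 0.03,
                 0.06, 0.04),
    msa_mean = c(1.10, 0.66, 0.65, 0.47, 0.30, 0.17, 0.31, 0.29, 0.29,
                 0.16, 0.21),
    msa_sd   = c(0.78, 0.48, 0, 0.38, 0.14, 0.01, 0.26, 0.05, 0.05,
                 0.16, 0.19)
  )
  stopifnot(sum(cells$n) == 90L, sum(cells$n_nonpulsatile) == 6L)
  structure(
    list(
      cells = cells,
      infection_prevalence = infection_prevalence,
      abi_elevated_prob = abi_elevated_prob,
      abi_glass_coupling = abi_glass_coupling,
      antithetic = antithetic
    ),
    class = "cohort_config"
  )
}

#' Pooled feature means implied by the cell table
#'
#' n-weighted pooled means of the printed cell means over the pulsatile
#' limbs (`n - n_nonpulsatile` per cell), the internal-consistency check
#' linking the per-cell statistics to the published overall means.
#'
#' @param config A [default_cohort_config()]-style configuration.
#' @return One-row tibble: `n_pulsatile`, `ust_mean`, `usr_mean`, `msa_mean`.
#' @export
#' @examples
#' pooled_feature_means(default_cohort_config())  # UST ~260 ms, USR ~0.32
pooled_feature_means <- function(config = default_cohort_config()) {
  cells <- config$cells
  w <- cells$n - cells$n_nonpulsatile
  tibble(
    n_pulsatile = sum(w),
    ust_mean = sum(w * cells$ust_mean) / sum(w),
    usr_mean = sum(w * cells$usr_mean) / sum(w),
    msa_mean = sum(w * cells$msa_mean) / sum(w)
  )
}

simulate_cell <- function(cell, scale, antithetic) {
  n_pulse <- (cell$n - cell$n_nonpulsatile) * scale
  n_np <- cell$n_nonpulsatile * scale
  draw <- function(mean, sd, lower, upper = Inf) {
    cal <- tnorm_calibrate(mean, sd, lower, upper)
    rtnorm_calibrated(n_pulse, cal, lower, upper, antithetic)
  }
  pulsatile <- tibble(
    glass = cell$glass,
    imd = cell$imd,
    pulsatile = TRUE,
    ust_ms = draw(cell$ust_mean, cell$ust_sd, 0),
    usr = draw(cell$usr_mean, cell$usr_sd, 0, 1),
    msa_mmhg = draw(cell$msa_mean, cell$msa_sd, 0)
  )
  if (n_np > 0) {
    pulsatile <- bind_rows(pulsatile, tibble(
      glass = cell$glass, imd = cell$imd, pulsatile = FALSE,
      ust_ms = NA_real_, usr = NA_real_, msa_mmhg = 0
    ))[c(seq_len(n_pulse), rep(n_pulse + 1, n_np)), ]
  }
  pulsatile
}

#' Simulate a limb-level cohort
#'
#' Draw a synthetic cohort of limbs whose per-cell feature distributions
#' (independent truncated normals), category sizes, non-pulsatile counts,
#' elevated-ABI fraction and infection prevalence are calibrated to the
#' configuration table. At `scale = 1` the cohort reproduces the study
#' counts exactly (90 limbs, 6 non-pulsatile); larger scales multiply each
#' cell for stable statistics. Dicrotic-notch and flat-interval indicators
#' are generated as present for limbs without angiographic disease (GLASS 0)
#' and absent otherwise.
#'
#' @param config A [default_cohort_config()]-style configuration.
#' @param scale Integer cell multiplier (>= 1).
#' @param seed Integer seed; draws are reproducible.
#' @return A tibble with one row per limb: `limb_id`, `glass`, `imd`,
#'   `pulsatile`, `ust_ms`, `usr`, `msa_mmhg`, `wavelength_ms`,
#'   `notch_present`, `flat_interval_present`, `upstroke_downslope_ratio`,
#'   `abi`, `abi_ge_1_3`, `infection`.
#' @export
#' @examples
#' cohort <- simulate_cohort(scale = 1, seed = 1)
#' nrow(cohort)            # 90
#' sum(!cohort$pulsatile)  # 6
simulate_cohort <- function(config = default_cohort_config(),
                            scale = 1,
                            seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), scale >= 1)
  scale <- as.integer(scale)
  cells <- config$cells
  withr::with_seed(as.integer(seed), {
    records <- map(seq_len(nrow(cells)), function(i) {
      simulate_cell(cells[i, ], scale, config$antithetic)
    }) |> list_rbind()
    n <- nrow(records)
    records$limb_id <- sprintf("limb-%04d", seq_len(n))

    # derived waveform quantities for pulsatile limbs
    records$wavelength_ms <- ifelse(records$pulsatile,
                                    records$ust_ms / records$usr, NA_real_)
    records$upstroke_downslope_ratio <-
      ifelse(records$pulsatile, records$usr / (1 - records$usr), NA_real_)
    records$notch_present <- ifelse(records$pulsatile,
                                    records$glass == "0", NA)
    records$flat_interval_present <- records$notch_present

    # ABI: elevated (>= 1.3, incompressible ankle arteries) with the
    # configured probability, by default independent of GLASS stage
    stage_idx <- as.integer(records$glass) - 1L
    lo <- qlogis_safe(config$abi_elevated_prob) +
      config$abi_glass_coupling * stage_idx
    p_elev <- 1 / (1 + exp(-lo))
    elevated <- runif(n) < p_elev
    abi <- numeric(n)
    cal_hi <- tnorm_calibrate(1.5, 0.15, 1.3, Inf)
    cal_lo <- tnorm_calibrate(1.0, 0.2, 0, 1.3)
    abi[elevated] <- rtnorm_calibrated(sum(elevated), cal_hi, 1.3, Inf,
                                       antithetic = FALSE)
    abi[!elevated] <- rtnorm_calibrated(sum(!elevated), cal_lo, 0, 1.3,
                                        antithetic = FALSE)
    records$abi <- abi
    records$abi_ge_1_3 <- abi >= 1.3
    records$infection <- runif(n) < config$infection_prevalence
  })
  select(records, "limb_id", "glass", "imd", "pulsatile", "ust_ms", "usr",
         "msa_mmhg", "wavelength_ms", "notch_present",
         "flat_interval_present", "upstroke_downslope_ratio", "abi",
         "abi_ge_1_3", "infection")
}

qlogis_safe <- function(p) log(p / (1 - p))

#' Render limb records as PVR traces
#'
#' Close the simulation loop: turn each limb's feature record into a
#' synthetic trace whose generator parameters equal the limb's features
#' (notch and flat interval present when the record flags them), so the full
#' pipeline trace -> features -> grading -> statistics can run end to end.
#' Non-pulsatile limbs yield flat traces.
#'
#' @param records Cohort tibble from [simulate_cohort()].
#' @param duration Trace duration in seconds.
#' @param noise_sd Measurement noise SD, mmHg.
#' @param baseline_drift_amplitude Baseline wander amplitude, mmHg.
#' @param seed Integer seed (per-limb seeds are derived from it).
#' @return A list of `pvr_trace` objects, one per record.
#' @export
features_to_traces <- function(records, duration = 10, noise_sd = 0.02,
                               baseline_drift_amplitude = 0.05, seed = 1L) {
  seeds <- as.integer(seed) + seq_len(nrow(records))
  map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    params <- if (!r$pulsatile || r$msa_mmhg <= 0) {
      beat_shape_params(0, 300, 800)
    } else {
      wl <- r$ust_ms / r$usr
      beat_shape_params(
        amplitude = r$msa_mmhg,
        upstroke_time = r$ust_ms,
        wavelength = wl,
        notch_depth = if (isTRUE(r$notch_present)) 0.15 else 0,
        notch_delay = 0.3 * (wl - r$ust_ms),
        interbeat_flatness = if (isTRUE(r$flat_interval_present)) 0.8 else 0
      )
    }
    generate_trace(
      trace_config(duration = duration, noise_sd = noise_sd,
                   baseline_drift_amplitude = baseline_drift_amplitude,
                   seed = seeds[i]),
      params,
      limb_id = r$limb_id
    )
  })
}
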