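#' Trace acquisition configuration
#'
#' Acquisition settings for a synthetic PVR recording: duration, sampling
#' interval (the native grid is 1 ms), additive white measurement noise, slow
#' sinusoidal baseline drift, optional amplitude quantization, and per-beat
#' heart-period jitter.
#'
#' @param duration Recording length in seconds.
#' @param sampling_interval Sample spacing in ms.
#' @param noise_sd SD of additive white Gaussian noise, mmHg.
#' @param baseline_drift_amplitude Amplitude of a slow sinusoidal baseline
#'   wander, mmHg. Its period is fixed at 8 s (respiratory-scale, slower than
#'   any plausible pulse).
#' @param quantization_bits Integer number of bits for amplitude quantization,
#'   or `NULL` for none.
#' @param quantization_full_scale Full scale used by the quantizer, mmHg.
#' @param period_jitter_cv Coefficient of variation of per-beat wavelength
#'   jitter (default 2%), which makes beat segmentation nontrivial.
#' @param seed Integer seed; the same (config, seed) pair always reproduces
#'   the same trace.
#'
#' @return A list of class `"trace_config"`.
#' @export
trace_config <- function(duration = 10,
                         sampling_interval = 1,
                         noise_sd = 0.02,
                         baseline_drift_amplitude = 0.05,
                         quantization_bits = NULL,
                         quantization_full_scale = 10,
                         period_jitter_cv = 0.02,
                         seed = 1L) {
  if (duration <= 0) abort("invalid trace config: `duration` must be > 0")
  if (sampling_interval <= 0) {
    abort("invalid trace config: `sampling_interval` must be > 0")
  }
  if (noise_sd < 0) abort("invalid trace config: `noise_sd` must be >= 0")
  structure(
    list(
      duration = duration,
      sampling_interval = sampling_interval,
      noise_sd = noise_sd,
      baseline_drift_amplitude = baseline_drift_amplitude,
      quantization_bits = quantization_bits,
      quantization_full_scale = quantization_full_scale,
      period_jitter_cv = period_jitter_cv,
      seed = as.integer(seed)
    ),
    class = "trace_config"
  )
}

DRIFT_PERIOD_MS <- 8000

#' Canonical morphology presets
#'
#' Beat-shape presets for the four semiquantitative PVR morphology classes.
#' A normal forefoot PVR has a sharp upstroke, a dicrotic notch and a scooped
#' or flat interval between peaks; mildly abnormal curves lose the notch and
#' the flat interval while the upstroke remains steep; severely abnormal
#' curves additionally flatten in amplitude and the upstroke lengthens toward
#' the downslope duration; non-pulsatile recordings show no visible
#' pulsation. Numeric anchors (UST 220/250/300 ms, MSA 1.1/0.6/0.25/0 mmHg at
#' a 800 ms period) follow typical published per-class feature values.
#'
#' @param morphology One of `"normal"`, `"mildly_abnormal"`,
#'   `"severely_abnormal"`, `"non_pulsatile"` (abbreviations `"mild"`,
#'   `"severe"` accepted).
#' @return A [beat_shape_params()] object.
#' @export
#' @examples
#' morphology_preset("normal")
morphology_preset <- function(morphology) {
  key <- normalize_morphology(morphology)
  switch(key,
    normal = beat_shape_params(
      amplitude = 1.1, upstroke_time = 220, wavelength = 800,
      notch_depth = 0.15, notch_delay = 120, interbeat_flatness = 0.8
    ),
    mildly_abnormal = beat_shape_params(
      amplitude = 0.6, upstroke_time = 250, wavelength = 800,
      notch_depth = 0, interbeat_flatness = 0
    ),
    severely_abnormal = beat_shape_params(
      amplitude = 0.25, upstroke_time = 300, wavelength = 800,
      notch_depth = 0, interbeat_flatness = 0
    ),
    non_pulsatile = beat_shape_params(
      amplitude = 0, upstroke_time = 300, wavelength = 800
    )
  )
}

MORPHOLOGY_LEVELS <- c("normal", "mildly_abnormal", "severely_abnormal",
                       "non_pulsatile")

normalize_morphology <- function(x) {
  x <- gsub("-", "_", tolower(as.character(x)))
  x[x == "mild"] <- "mildly_abnormal"
  x[x == "severe"] <- "severely_abnormal"
  x[x == "nonpulsatile"] <- "non_pulsatile"
  if (!all(x %in% MORPHOLOGY_LEVELS)) {
    abort(paste0("unknown morphology: ",
                 paste(setdiff(x, MORPHOLOGY_LEVELS), collapse = ", ")))
  }
  x
}

new_pvr_trace <- function(df, sampling_interval, cuff_pressure, limb_id,
                          ground_truth = NULL) {
  structure(
    df,
    sampling_interval = sampling_interval,
    cuff_pressure = cuff_pressure,
    limb_id = limb_id,
    ground_truth = ground_truth,
    class = c("pvr_trace", class(tibble()))
  )
}

#' Generate a synthetic PVR trace
#'
#' Concatenate jittered beats of a given morphology (or explicit beat shape)
#' into a uniformly sampled pressure-offset recording, then add slow baseline
#' drift, white measurement noise, and optional quantization. The shape
#' synthesis is deterministic given the seed, and ground-truth per-beat
#' fiducials are attached so detection algorithms can be scored against truth.
#'
#' @param config A [trace_config()].
#' @param morphology A morphology class name (see [morphology_preset()]) or a
#'   [beat_shape_params()] object.
#' @param limb_id Identifier stored in the trace metadata.
#' @param cuff_pressure Applied forefoot cuff pressure, mmHg (metadata only;
#'   the recording is a pressure offset around 0).
#'
#' @return A `pvr_trace` tibble with columns `t_ms`, `pressure_mmhg` and
#'   attributes `sampling_interval`, `cuff_pressure`, `limb_id`,
#'   `ground_truth` (tibble of true per-beat foot/peak/notch times and
#'   shape parameters).
#' @export
#' @examples
#' tr <- generate_trace(trace_config(duration = 10, seed = 7), "normal")
#' nrow(tr)
#' nrow(attr(tr, "ground_truth"))  # complete beats
generate_trace <- function(config = trace_config(),
                           morphology = "normal",
                           limb_id = "limb-1",
                           cuff_pressure = 50) {
  stopifnot(inherits(config, "trace_config"))
  params <- if (inherits(morphology, "beat_shape_params")) {
    morphology
  } else {
    morphology_preset(morphology)
  }
  dt <- config$sampling_interval
  n <- round(config$duration * 1000 / dt)

  withr::with_seed(config$seed, {
    samples <- numeric(0)
    gt <- list()
    t_cursor <- 0
    while (length(samples) < n) {
      p <- params
      if (config$period_jitter_cv > 0 && params$amplitude > 0) {
        jit <- max(0.5, 1 + rnorm(1, 0, config$period_jitter_cv))
        p$wavelength <- params$wavelength * jit
        p$upstroke_time <- params$upstroke_time * jit
        if (p$notch_depth > 0) p$notch_delay <- params$notch_delay * jit
      }
      beat <- generate_beat(p, dt)
      complete <- (length(samples) + length(beat)) <= n
      gt[[length(gt) + 1]] <- tibble(
        beat = length(gt) + 1L,
        foot_ms = t_cursor,
        peak_ms = t_cursor + p$upstroke_time,
        notch_ms = if (p$notch_depth > 0) {
          t_cursor + p$upstroke_time + p$notch_delay
        } else {
          NA_real_
        },
        ust_ms = p$upstroke_time,
        wavelength_ms = p$wavelength,
        msa_mmhg = p$amplitude,
        complete = complete
      )
      samples <- c(samples, beat)
      t_cursor <- t_cursor + length(beat) * dt
    }
    samples <- samples[seq_len(n)]
    gt <- list_rbind(gt)

    t_ms <- (seq_len(n) - 1) * dt
    if (config$baseline_drift_amplitude > 0) {
      phase <- runif(1, 0, 2 * pi)
      samples <- samples + config$baseline_drift_amplitude *
        sin(2 * pi * t_ms / DRIFT_PERIOD_MS + phase)
    }
    if (config$noise_sd > 0) {
      samples <- samples + rnorm(n, 0, config$noise_sd)
    }
  })

  tr <- new_pvr_trace(
    tibble(t_ms = t_ms, pressure_mmhg = samples),
    sampling_interval = dt,
    cuff_pressure = cuff_pressure,
    limb_id = limb_id,
    ground_truth = gt
  )
  if (!is.null(config$quantization_bits)) {
    tr <- quantize_trace(tr, config$quantization_bits,
                         config$quantization_full_scale)
  }
  tr
}

#' Quantize trace amplitudes
#'
#' Round samples to the nearest of `2^bits` uniformly spaced levels spanning
#' `full_scale` (level spacing `full_scale / (2^bits - 1)`), emulating the
#' finite amplitude resolution of a recorder. Idempotent.
#'
#' @param trace A `pvr_trace`.
#' @param bits Integer >= 2.
#' @param full_scale Full scale in mmHg; must be > 0.
#' @return The quantized `pvr_trace`.
#' @export
quantize_trace <- function(trace, bits = 18, full_scale = 10) {
  if (full_scale <= 0) abort("`full_scale` must be > 0")
  if (bits < 2) abort("`bits` must be >= 2")
  step <- full_scale / (2^bits - 1)
  trace$pressure_mmhg <- round(trace$pressure_mmhg / step) * step
  trace
}

#' @export
print.pvr_trace <- function(x, ...) {
  cat(sprintf(
    "<pvr_trace> limb %s: %d samples @ %g ms, cuff %g mmHg\n",
    attr(x, "limb_id"), nrow(x), attr(x, "sampling_interval"),
    attr(x, "cuff_pressure")
  ))
  NextMethod()
}
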