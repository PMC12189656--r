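# Shared fixtures: deterministic trace configs and small cohorts.

clean_config <- function(seed = 1L, duration = 10) {
  trace_config(duration = duration, noise_sd = 0,
               baseline_drift_amplitude = 0, period_jitter_cv = 0,
               seed = seed)
}

noisy_config <- function(seed = 1L, noise_sd = 0.02, duration = 10) {
  trace_config(duration = duration, noise_sd = noise_sd, seed = seed)
}

# a custom pulsatile beat without notch/flat tail, used for grids
plain_beat <- function(amplitude, ust, wavelength = 800) {
  beat_shape_params(amplitude = amplitude, upstroke_time = ust,
                    wavelength = wavelength)
}

PULSATILE_PRESETS <- c("normal", "mildly_abnormal", "severely_abnormal")
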