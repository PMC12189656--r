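#' Beat shape parameters
#'
#' Bundle the ground-truth shape parameters of a single PVR beat. The beat is
#' described by the quantities a vascular laboratory reads off the curve: its
#' maximum systolic amplitude (peak minus preceding foot, mmHg), upstroke time
#' (foot to systolic peak, ms), total wavelength (foot-to-foot period, ms),
#' the relative depth and timing of the dicrotic notch, and how flat the
#' diastolic interval between successive peaks is.
#'
#' @param amplitude Peak-minus-foot excursion in mmHg (the true MSA). `0`
#'   produces a non-pulsatile (flat) beat.
#' @param upstroke_time Foot-to-peak duration in ms (the true UST).
#' @param wavelength Foot-to-foot period in ms (the true total wavelength).
#' @param notch_depth Depth of the dicrotic notch as a fraction of the local
#'   descending-limb level, in `[0, 1)`. `0` removes the notch.
#' @param notch_delay Delay of the notch after the systolic peak, ms.
#' @param interbeat_flatness Fraction in `[0, 1]`: `1` gives a fully scooped /
#'   flat interval between peaks (the signal sits at the baseline well before
#'   the next foot), `0` a continuous descent into the next foot.
#'
#' @return A list of class `"beat_shape_params"`.
#' @export
#' @examples
#' beat_shape_params(amplitude = 1.1, upstroke_time = 220, wavelength = 800,
#'                   notch_depth = 0.15)
beat_shape_params <- function(amplitude,
                              upstroke_time,
                              wavelength,
                              notch_depth = 0,
                              notch_delay = 120,
                              interbeat_flatness = 0) {
  p <- list(
    amplitude = amplitude,
    upstroke_time = upstroke_time,
    wavelength = wavelength,
    notch_depth = notch_depth,
    notch_delay = notch_delay,
    interbeat_flatness = interbeat_flatness
  )
  validate_beat_shape_params(p)
  structure(p, class = "beat_shape_params")
}

validate_beat_shape_params <- function(p) {
  if (!is.numeric(p$amplitude) || p$amplitude < 0) {
    abort("invalid beat shape: `amplitude` must be >= 0")
  }
  if (p$upstroke_time <= 0 || p$upstroke_time >= p$wavelength) {
    abort("invalid beat shape: requires 0 < upstroke_time < wavelength")
  }
  if (p$notch_depth < 0 || p$notch_depth >= 1) {
    abort("invalid beat shape: requires 0 <= notch_depth < 1")
  }
  if (p$notch_depth > 0 &&
      p$upstroke_time + p$notch_delay >= p$wavelength) {
    abort("invalid beat shape: requires upstroke_time + notch_delay < wavelength")
  }
  if (p$interbeat_flatness < 0 || p$interbeat_flatness > 1) {
    abort("invalid beat shape: requires 0 <= interbeat_flatness <= 1")
  }
  invisible(p)
}

# Cosine easing between two knot values: zero slope at both knots, so every
# knot is a stationary point of the assembled curve (the notch knot is an
# exact local minimum by construction).
cosine_ease <- function(t, t1, t2, v1, v2) {
  s <- (t - t1) / (t2 - t1)
  v1 + (v2 - v1) * (1 - cos(pi * s)) / 2
}

# Quarter-sine easing: finite slope at the first knot, zero slope at the
# second. Used for the systolic upstroke so the waveform foot is a sharp,
# well-localized corner (the clinical "sharp upstroke") while the peak stays
# smooth and flat-topped.
sine_ease <- function(t, t1, t2, v1, v2) {
  s <- (t - t1) / (t2 - t1)
  v1 + (v2 - v1) * sin(pi / 2 * s)
}

# Fraction of the post-peak interval occupied by the flat baseline tail when
# interbeat_flatness = 1.
FLAT_TAIL_FRACTION <- 0.35

beat_knots <- function(params) {
  a <- params$amplitude
  ust <- params$upstroke_time
  w <- params$wavelength
  flat_len <- params$interbeat_flatness * FLAT_TAIL_FRACTION * w
  t_decay_end <- max(w - flat_len, ust + 0.05 * w)
  kt <- c(0, ust)
  kv <- c(0, a)
  if (params$notch_depth > 0) {
    t_n <- ust + params$notch_delay
    # level of the notch-free descending limb at time t (quarter cosine decay)
    base_level <- function(t) {
      a * cos(pi / 2 * pmin((t - ust) / (t_decay_end - ust), 1))
    }
    t_n <- min(t_n, t_decay_end - 0.05 * w)
    v_n <- base_level(t_n) * (1 - params$notch_depth)
    t_r <- t_n + min(0.6 * params$notch_delay, 0.5 * (t_decay_end - t_n))
    # dicrotic wave recovers half the carved depth above the notch level
    v_r <- v_n + 0.5 * params$notch_depth * base_level(t_n)
    kt <- c(kt, t_n, t_r)
    kv <- c(kv, v_n, v_r)
  }
  if (t_decay_end < w) {
    kt <- c(kt, t_decay_end, w)
    kv <- c(kv, 0, 0)
  } else {
    kt <- c(kt, w)
    kv <- c(kv, 0)
  }
  list(t = kt, v = kv)
}

#' Generate one PVR beat
#'
#' Synthesise a single noise-free beat as a piecewise cosine-easing curve
#' through its fiducial knots (foot, systolic peak, optional dicrotic notch
#' and dicrotic wave, end of decay). The returned sequence starts at the foot
#' (value 0), peaks at `upstroke_time` with value `amplitude`, and returns to
#' 0 at the period boundary so beats concatenate continuously.
#'
#' @param params A [beat_shape_params()] object.
#' @param sampling_interval Sample spacing in ms (default 1).
#'
#' @return Numeric vector of `round(wavelength / sampling_interval)` pressure
#'   offsets in mmHg.
#' @export
#' @examples
#' y <- generate_beat(beat_shape_params(1, 250, 800, notch_depth = 0.15))
#' length(y)            # 800 samples at 1 ms
#' which.max(y)         # peak at 250 ms
generate_beat <- function(params, sampling_interval = 1) {
  if (!inherits(params, "beat_shape_params")) {
    params <- do.call(beat_shape_params, as.list(params))
  }
  validate_beat_shape_params(params)
  n <- round(params$wavelength / sampling_interval)
  t <- (seq_len(n) - 1) * sampling_interval
  if (params$amplitude == 0) {
    return(rep(0, n))
  }
  k <- beat_knots(params)
  seg <- findInterval(t, k$t, rightmost.closed = TRUE)
  seg[seg < 1] <- 1
  seg[seg >= length(k$t)] <- length(k$t) - 1
  y <- cosine_ease(t, k$t[seg], k$t[seg + 1], k$v[seg], k$v[seg + 1])
  up <- seg == 1
  y[up] <- sine_ease(t[up], k$t[1], k$t[2], k$v[1], k$v[2])
  y
}
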