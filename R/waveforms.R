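#' Default single-beat ECG wave parameters
#'
#' Describes one cardiac cycle as five Gaussian deflections (P, Q, R, S, T),
#' each with an amplitude in millivolts, a center offset within the beat in
#' seconds, and a duration in seconds. A Gaussian with standard deviation
#' `duration / 6` renders essentially all (99.7%) of its mass inside the stated
#' duration. The defaults sit inside the typical adult ranges: P 0.1-0.3 mV
#' over 0.04-0.12 s, R up to 1.7 mV with duration under 0.07 s, QRS complex
#' 0.05-0.10 s, T 0.05-0.8 mV over 0.10-0.25 s, QT 0.30-0.40 s.
#'
#' @param heart_rate Beats per minute (> 0). Wave centers are laid out for one
#'   beat of `60 / heart_rate` seconds.
#' @param amplitudes,centers,durations Named numeric vectors overriding the
#'   per-wave defaults; names among `P`, `Q`, `R`, `S`, `T`. Amplitudes in mV
#'   (Q and S conventionally negative), centers and durations in seconds.
#' @param st_offset Additive ST-segment baseline shift in mV, rendered as a
#'   broad bump between the S and T centers. Default 0.
#'
#' @return An object of class `wave_params`: a list with a `waves` data frame
#'   (rows P, Q, R, S, T) plus `heart_rate` and `st_offset`.
#' @examples
#' wp <- wave_params()
#' beat <- generate_beat(wp, rate = 500)
#' @export
wave_params <- function(heart_rate = 60,
                        amplitudes = NULL,
                        centers = NULL,
                        durations = NULL,
                        st_offset = 0) {
  assert_scalar_number(heart_rate, "heart_rate", positive = TRUE)
  waves <- data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.20, -0.10, 1.00, -0.20, 0.30),
    center = c(0.17, 0.32, 0.35, 0.38, 0.60),
    duration = c(0.09, 0.03, 0.04, 0.03, 0.18),
    stringsAsFactors = FALSE
  )
  rownames(waves) <- waves$wave
  override <- function(col, vals) {
    if (is.null(vals)) return()
    bad <- setdiff(names(vals), waves$wave)
    if (length(bad) || is.null(names(vals))) {
      abort("Overrides must be named with waves among P, Q, R, S, T.")
    }
    waves[names(vals), col] <<- unname(vals)
  }
  override("amplitude", amplitudes)
  override("center", centers)
  override("duration", durations)
  # centers scale with the cycle length so faster rates compress the layout
  if (heart_rate != 60) {
    waves$center <- waves$center * (60 / heart_rate)
  }
  out <- structure(
    list(waves = waves, heart_rate = heart_rate, st_offset = st_offset),
    class = "wave_params"
  )
  validate_wave_params(out)
  out
}

validate_wave_params <- function(params) {
  w <- params$waves
  if (any(!is.finite(w$duration)) || any(w$duration <= 0)) {
    abort("All wave durations must be > 0.", class = "mrfecg_invalid_parameter")
  }
  if (params$heart_rate <= 0) {
    abort("heart_rate must be > 0.", class = "mrfecg_invalid_parameter")
  }
  if (any(diff(w$center) <= 0)) {
    abort("Wave centers must be strictly ordered P < Q < R < S < T.",
          class = "mrfecg_invalid_parameter")
  }
  beat <- 60 / params$heart_rate
  if (any(w$center >= beat)) {
    abort("Wave centers must fall inside one beat (60 / heart_rate seconds).",
          class = "mrfecg_invalid_parameter")
  }
  invisible(params)
}

#' Render one heartbeat as a sampled waveform
#'
#' Sums the five Gaussian deflections of [wave_params()] on a uniform sample
#' grid. The beat spans `round(rate * 60 / heart_rate)` samples. A non-zero
#' `st_offset` adds a broad Gaussian plateau centered midway between the S and
#' T waves (standard deviation one quarter of the S-to-T distance).
#'
#' @param params A [wave_params()] object.
#' @param rate Sampling rate in Hz (> 0).
#' @return Numeric vector of length `round(rate * 60 / heart_rate)`, in mV.
#' @examples
#' beat <- generate_beat(wave_params(), rate = 100)
#' length(beat) # 100 samples at 60 bpm
#' @export
generate_beat <- function(params, rate) {
  if (!inherits(params, "wave_params")) {
    abort("`params` must be a `wave_params` object.")
  }
  validate_wave_params(params)
  assert_scalar_number(rate, "rate", positive = TRUE)
  n <- round(rate * 60 / params$heart_rate)
  if (n < 1) abort("rate too low for one beat.", class = "mrfecg_invalid_parameter")
  t <- (seq_len(n) - 1) / rate
  y <- numeric(n)
  w <- params$waves
  for (i in seq_len(nrow(w))) {
    sigma <- w$duration[i] / 6
    y <- y + w$amplitude[i] * exp(-0.5 * ((t - w$center[i]) / sigma)^2)
  }
  if (params$st_offset != 0) {
    c_s <- w["S", "center"]
    c_t <- w["T", "center"]
    y <- y + params$st_offset *
      exp(-0.5 * ((t - (c_s + c_t) / 2) / ((c_t - c_s) / 4))^2)
  }
  y
}

#' Class-conditional morphology perturbation
#'
#' A `class_effect` rewrites the default beat morphology for records carrying
#' one diagnostic label: multiplicative deltas on wave amplitudes, QRS width
#' and heart rate, plus an additive ST-segment baseline offset. The identity
#' effect (all multipliers 1, offset 0) leaves [wave_params()] unchanged.
#'
#' @param label Class identifier (single string).
#' @param p_amp Multiplier on the P-wave amplitude.
#' @param r_amp Multiplier on the Q, R and S amplitudes (the QRS complex).
#' @param t_amp Multiplier on the T-wave amplitude (negative values invert T).
#' @param qrs_width Multiplier on the Q, R and S durations.
#' @param heart_rate Multiplier on the heart rate; wave centers compress
#'   proportionally so the layout stays inside the shorter beat.
#' @param st_offset Additive ST baseline shift in mV.
#' @return An object of class `class_effect`.
#' @examples
#' class_effect("tachycardia", heart_rate = 1.8)
#' @export
class_effect <- function(label,
                         p_amp = 1, r_amp = 1, t_amp = 1,
                         qrs_width = 1, heart_rate = 1, st_offset = 0) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort("`label` must be a non-empty string.")
  }
  for (nm in c("p_amp", "r_amp", "t_amp", "qrs_width", "heart_rate", "st_offset")) {
    assert_scalar_number(get(nm), nm)
  }
  if (qrs_width <= 0 || heart_rate <= 0) {
    abort("`qrs_width` and `heart_rate` multipliers must be > 0.")
  }
  structure(
    list(label = label, p_amp = p_amp, r_amp = r_amp, t_amp = t_amp,
         qrs_width = qrs_width, heart_rate = heart_rate, st_offset = st_offset),
    class = "class_effect"
  )
}

# Compose a set of class effects onto base wave parameters. `strength` scales
# every effect toward (strength = 0) or beyond (strength > 1) the identity:
# multipliers become 1 + strength * (m - 1), offsets strength * o. Multipliers
# compose multiplicatively across labels, offsets additively.
apply_effects <- function(params, effects, strength = 1) {
  stopifnot(inherits(params, "wave_params"))
  mult <- c(p_amp = 1, r_amp = 1, t_amp = 1, qrs_width = 1, heart_rate = 1)
  offset <- 0
  for (ef in effects) {
    stopifnot(inherits(ef, "class_effect"))
    for (nm in names(mult)) {
      mult[nm] <- mult[nm] * (1 + strength * (ef[[nm]] - 1))
    }
    offset <- offset + strength * ef$st_offset
  }
  w <- params$waves
  w["P", "amplitude"] <- w["P", "amplitude"] * mult[["p_amp"]]
  w[c("Q", "R", "S"), "amplitude"] <- w[c("Q", "R", "S"), "amplitude"] * mult[["r_amp"]]
  w["T", "amplitude"] <- w["T", "amplitude"] * mult[["t_amp"]]
  w[c("Q", "R", "S"), "duration"] <- w[c("Q", "R", "S"), "duration"] * mult[["qrs_width"]]
  hr <- params$heart_rate * mult[["heart_rate"]]
  # compress the layout with the shorter cycle
  w$center <- w$center * (params$heart_rate / hr)
  out <- structure(
    list(waves = w, heart_rate = hr, st_offset = params$st_offset + offset),
    class = "wave_params"
  )
  validate_wave_params(out)
  out
}
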