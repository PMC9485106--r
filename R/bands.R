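#' Frequency band definition
#'
#' A frequency band is a named interval `[f_lo, f_hi]` in Hz. The canonical
#' bands of the analysis are theta (4-10 Hz), slow gamma (30-55 Hz) and fast
#' gamma (55-100 Hz).
#'
#' @param name Band label, e.g. `"theta"`.
#' @param f_lo,f_hi Lower and upper band edges in Hz; `0 < f_lo < f_hi`.
#' @return An object of class `band_definition`.
#' @examples
#' band_definition("theta", 4, 10)
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  stopifnot_scalar_pos(f_lo, "f_lo")
  stopifnot_scalar_pos(f_hi, "f_hi")
  if (f_lo >= f_hi) stop("`f_lo` must be strictly below `f_hi`", call. = FALSE)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band_definition> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Canonical analysis bands
#'
#' Theta (4-10 Hz), slow gamma (30-55 Hz) and fast gamma (55-100 Hz).
#'
#' @return Named list of [band_definition()] objects.
#' @export
canonical_bands <- function() {
  list(
    theta      = band_definition("theta", 4, 10),
    slow_gamma = band_definition("slow_gamma", 30, 55),
    fast_gamma = band_definition("fast_gamma", 55, 100)
  )
}

#' FIR bandpass filter tolerance scheme
#'
#' Tolerances for the linear-phase FIR bandpass designs: minimum stopband
#' attenuation, maximum passband ripple, and the width of each transition
#' region between a passband edge and the adjacent stopband edge.
#'
#' @param stopband_atten_db Minimum stopband attenuation in dB (default 80).
#' @param passband_ripple_db Maximum peak-to-peak passband ripple in dB
#'   (default 1).
#' @param transition_width_hz Transition width in Hz on each side of the
#'   passband (default 0.5).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(stopband_atten_db = 80,
                        passband_ripple_db = 1,
                        transition_width_hz = 0.5) {
  stopifnot_scalar_pos(stopband_atten_db, "stopband_atten_db")
  stopifnot_scalar_pos(passband_ripple_db, "passband_ripple_db")
  stopifnot_scalar_pos(transition_width_hz, "transition_width_hz")
  structure(list(stopband_atten_db = stopband_atten_db,
                 passband_ripple_db = passband_ripple_db,
                 transition_width_hz = transition_width_hz),
            class = "filter_spec")
}

#' Artifact exclusion policy
#'
#' A trial is excluded when the broadband signal's robust z-score (deviation
#' from the median in units of 1.4826 x MAD) stays above `zscore_threshold`
#' continuously for at least `min_duration_ms` anywhere in the trial's pre-CS
#' or CS analysis window.
#'
#' @param zscore_threshold Robust z-score threshold (default 6).
#' @param min_duration_ms Minimum continuous supra-threshold duration in ms
#'   (default 50).
#' @return An object of class `artifact_policy`.
#' @export
artifact_policy <- function(zscore_threshold = 6, min_duration_ms = 50) {
  stopifnot_scalar_pos(zscore_threshold, "zscore_threshold")
  stopifnot_scalar_pos(min_duration_ms, "min_duration_ms")
  structure(list(zscore_threshold = zscore_threshold,
                 min_duration_ms = min_duration_ms,
                 action = "exclude-trial"),
            class = "artifact_policy")
}
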