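#' Normalized cross-correlation coefficient over lags
#'
#' Computes the raw-moment cross-correlation
#' \deqn{\hat{R}_{xy}(m) = \sum_{n=0}^{N-m-1} x_{n+m}\, y_n, \quad m \ge 0,}
#' with \eqn{\hat{R}_{xy}(-m) = \hat{R}_{yx}(m)}, normalized by
#' \eqn{\sqrt{\hat{R}_{xx}(0)\,\hat{R}_{yy}(0)}} so the value at any lag lies
#' in \eqn{[-1, 1]}. No mean subtraction and no per-lag rescaling is applied
#' (the biased raw-moment convention). The computation uses FFTs and matches
#' the direct double-loop sum to numerical precision.
#'
#' @param x,y Equal-length real sequences.
#' @param max_lag Maximum lag in samples (`< length(x)`).
#' @param sampling_rate_hz Optional; when given, lag times in ms are attached.
#' @return Object of class `coupling_result`: list with `lags` (samples,
#'   `-max_lag:max_lag`), `coefficients`, and `lag_ms` when the sampling rate
#'   is known.
#' @examples
#' r <- xcorr_coeff(sin(1:100), sin(1:100), 10)
#' max(r$coefficients)  # 1 at lag 0
#' @export
xcorr_coeff <- function(x, y, max_lag, sampling_rate_hz = NULL) {
  n <- length(x)
  if (length(y) != n) {
    stop(sprintf("length mismatch: x has %d samples, y has %d", n, length(y)),
         call. = FALSE)
  }
  if (max_lag >= n) {
    stop(sprintf("max_lag (%d) must be below the sequence length (%d)",
                 max_lag, n), call. = FALSE)
  }
  max_lag <- as.integer(max_lag)
  m <- next_pow2(n + max_lag)
  X <- fft(c(x, rep(0, m - n)))
  Y <- fft(c(y, rep(0, m - n)))
  cc <- Re(fft(X * Conj(Y), inverse = TRUE)) / m
  # cc[k + 1] = sum_n x[n + k] y[n] for k = 0..max_lag;
  # negative lags wrap to the tail: cc[m - k + 1] = sum_n x[n - k] y[n].
  pos <- cc[1:(max_lag + 1L)]
  neg <- cc[(m - max_lag + 1L):m]
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) {
    stop("zero-energy input: normalization undefined", call. = FALSE)
  }
  coeff <- c(neg, pos) / denom
  lags <- (-max_lag):max_lag
  res <- list(lags = lags, coefficients = coeff)
  if (!is.null(sampling_rate_hz)) {
    res$lag_ms <- lags * 1000 / sampling_rate_hz
    res$sampling_rate_hz <- sampling_rate_hz
  }
  structure(res, class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  pk <- peak_coupling(x)
  cat(sprintf("<coupling_result> lags %d..%d samples; peak %.3f at lag %d%s\n",
              min(x$lags), max(x$lags), pk$peak_coeff, pk$peak_lag,
              if (!is.null(x$lag_ms)) sprintf(" (%.1f ms)",
                pk$peak_lag * 1000 / x$sampling_rate_hz) else ""))
  invisible(x)
}

#' Peak of a lag-resolved coupling result
#'
#' Signed mode (default) returns the maximum coefficient; absolute mode
#' returns the coefficient of maximal magnitude with its sign retained. Ties
#' are broken by smallest `|lag|`, then by the negative lag.
#'
#' @param result A `coupling_result` from [xcorr_coeff()].
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return List with `peak_coeff`, `peak_lag` (samples) and, when the
#'   sampling rate is known, `peak_lag_ms`.
#' @export
peak_coupling <- function(result, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  co <- result$coefficients
  if (length(co) == 0) stop("empty coefficient sequence", call. = FALSE)
  key <- if (mode == "signed") co else abs(co)
  best <- max(key)
  cand <- which(key >= best - 1e-15)
  # tie-break: smallest |lag|, then negative lag first
  lag <- result$lags[cand]
  ord <- order(abs(lag), lag)
  pick <- cand[ord[1]]
  out <- list(peak_coeff = co[pick], peak_lag = result$lags[pick])
  if (!is.null(result$sampling_rate_hz)) {
    out$peak_lag_ms <- result$lags[pick] * 1000 / result$sampling_rate_hz
  }
  out
}

#' Per-trial PL-IL coupling
#'
#' Band-filters both region channels of a recording (zero net delay), extracts
#' the 15-s analysis window of each trial (CS window by default, pre-CS
#' optionally), and computes the normalized cross-correlation
#' ([xcorr_coeff()], x = PL, y = IL) and its peak. Trials listed in
#' `excluded` are skipped.
#'
#' @param rec An [recording()] with both PL and IL channels.
#' @param events Event table rows for this recording's session.
#' @param taps FIR taps from [design_bandpass()], or NULL for broadband.
#' @param window `"CS"` (default) or `"pre-CS"`.
#' @param max_lag_ms Maximum lag in ms (default 500).
#' @param mode Peak mode, `"signed"` (default) or `"absolute"`.
#' @param amplitude_mode `"filtered"` (default) correlates the band-filtered
#'   samples; `"envelope"` correlates their Hilbert-style instantaneous
#'   amplitude envelopes.
#' @param window_s Window length in seconds (default 15).
#' @param excluded Optional data.frame of exclusions (`session`,
#'   `trial_index`, `stimulus`) as from [detect_artifacts()].
#' @return data.frame with one row per analyzable trial: `session`,
#'   `trial_index`, `stimulus`, `peak_coeff`, `peak_lag_ms`.
#' @export
trial_coupling <- function(rec, events, taps, window = c("CS", "pre-CS"),
                           max_lag_ms = 500, mode = "signed",
                           amplitude_mode = c("filtered", "envelope"),
                           window_s = 15, excluded = NULL) {
  window <- match.arg(window)
  amplitude_mode <- match.arg(amplitude_mode)
  fs <- rec$sampling_rate_hz
  pl <- region_signal(rec, "PL")
  il <- region_signal(rec, "IL")
  if (!is.null(taps)) {
    pl <- apply_zero_phase(pl, taps)
    il <- apply_zero_phase(il, taps)
  }
  if (amplitude_mode == "envelope") {
    pl <- amplitude_envelope(pl)
    il <- amplitude_envelope(il)
  }
  max_lag <- round(max_lag_ms / 1000 * fs)
  w <- as.integer(floor(window_s * fs))
  out <- list()
  for (i in seq_len(nrow(events))) {
    if (!is.null(excluded) && nrow(excluded) > 0) {
      hit <- excluded$session == events$session[i] &
        excluded$trial_index == events$trial_index[i] &
        excluded$stimulus == events$stimulus[i]
      if (any(hit)) next
    }
    i_on <- floor(events$onset_s[i] * fs)
    idx <- if (window == "CS") (i_on + 1L):(i_on + w)
           else (i_on - w + 1L):i_on
    if (min(idx) < 1L || max(idx) > length(pl)) {
      stop(sprintf("trial at onset %g s falls outside the recording",
                   events$onset_s[i]), call. = FALSE)
    }
    r <- xcorr_coeff(pl[idx], il[idx], max_lag, sampling_rate_hz = fs)
    pk <- peak_coupling(r, mode)
    out[[length(out) + 1L]] <- data.frame(
      session = events$session[i], trial_index = events$trial_index[i],
      stimulus = events$stimulus[i], peak_coeff = pk$peak_coeff,
      peak_lag_ms = pk$peak_lag_ms, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(session = character(), trial_index = integer(),
               stimulus = character(), peak_coeff = numeric(),
               peak_lag_ms = numeric(), stringsAsFactors = FALSE)
}

#' Trial-averaged cross-correlation curve of a session
#'
#' Averages the lag-resolved normalized cross-correlation over a session's
#' analyzable trials. Averaging the curves (rather than per-trial peaks)
#' suppresses the lag jitter of single-trial peak estimates, making this the
#' preferred estimator of the inter-region lag.
#'
#' @inheritParams trial_coupling
#' @return A `coupling_result` whose `coefficients` are the trial mean, with
#'   an extra field `n_trials`.
#' @export
session_coupling_curve <- function(rec, events, taps, window = c("CS", "pre-CS"),
                                   max_lag_ms = 500,
                                   amplitude_mode = c("filtered", "envelope"),
                                   window_s = 15, excluded = NULL) {
  window <- match.arg(window)
  amplitude_mode <- match.arg(amplitude_mode)
  fs <- rec$sampling_rate_hz
  pl <- region_signal(rec, "PL")
  il <- region_signal(rec, "IL")
  if (!is.null(taps)) {
    pl <- apply_zero_phase(pl, taps)
    il <- apply_zero_phase(il, taps)
  }
  if (amplitude_mode == "envelope") {
    pl <- amplitude_envelope(pl)
    il <- amplitude_envelope(il)
  }
  max_lag <- round(max_lag_ms / 1000 * fs)
  w <- as.integer(floor(window_s * fs))
  acc <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(events))) {
    if (!is.null(excluded) && nrow(excluded) > 0) {
      hit <- excluded$session == events$session[i] &
        excluded$trial_index == events$trial_index[i] &
        excluded$stimulus == events$stimulus[i]
      if (any(hit)) next
    }
    i_on <- floor(events$onset_s[i] * fs)
    idx <- if (window == "CS") (i_on + 1L):(i_on + w)
           else (i_on - w + 1L):i_on
    r <- xcorr_coeff(pl[idx], il[idx], max_lag, sampling_rate_hz = fs)
    acc <- if (is.null(acc)) r$coefficients else acc + r$coefficients
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no analyzable trials in session", call. = FALSE)
  lags <- (-max_lag):max_lag
  structure(list(lags = lags, coefficients = acc / n_used,
                 lag_ms = lags * 1000 / fs, sampling_rate_hz = fs,
                 n_trials = n_used),
            class = "coupling_result")
}

# Instantaneous amplitude via the analytic signal (FFT Hilbert transform).
amplitude_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Session-block averages of peak coupling
#'
#' [block_average()] applied to the `peak_coeff` column of a
#' [trial_coupling()] table.
#'
#' @param results Per-trial coupling table.
#' @param blocks Block definition (default [default_session_blocks()]).
#' @return data.frame with `block`, `session`, `stimulus`, `n`, `mean`, `sem`.
#' @export
session_coupling_average <- function(results,
                                     blocks = default_session_blocks()) {
  block_average(results, blocks, value = "peak_coeff", by = character())
}
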