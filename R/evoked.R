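#' Normalized CS-evoked power ratio for one trial
#'
#' Band-filters the region's signal (zero net delay), then divides the summed
#' Welch PSD of the 15-s CS window `[onset, onset + 15 s)` by the summed PSD
#' of the 15-s pre-CS window `[onset - 15 s, onset)`. Both windows use the
#' same segmentation (length/16 non-overlapping Hann segments), so the ratio
#' is dimensionless and scale-invariant.
#'
#' @param x Broadband signal of one region (microvolts), or an
#'   `lfp_recording` together with `region`.
#' @param sampling_rate_hz Sampling rate in Hz (ignored when `x` is a
#'   recording).
#' @param onset_s CS onset in seconds from session start.
#' @param taps FIR taps from [design_bandpass()], or NULL if `x` is already
#'   band-filtered.
#' @param region Region to extract when `x` is an `lfp_recording`.
#' @param window_s Analysis window length in seconds (default 15).
#' @param n_segments Welch segment count (default 16).
#' @return The power ratio (positive scalar).
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 7 * seq(0, 60, by = 1 / fs))
#' evoked_power_ratio(x, fs, onset_s = 30, taps = NULL)  # 1: identical windows
#' @export
evoked_power_ratio <- function(x, sampling_rate_hz = NULL, onset_s,
                               taps = NULL, region = NULL,
                               window_s = 15, n_segments = 16) {
  if (inherits(x, "lfp_recording")) {
    sampling_rate_hz <- x$sampling_rate_hz
    x <- region_signal(x, region %||% "PL")
  }
  fs <- sampling_rate_hz
  stopifnot_scalar_pos(fs, "sampling_rate_hz")
  if (onset_s < window_s) {
    stop(sprintf("onset at %g s leaves less than %g s of baseline",
                 onset_s, window_s), call. = FALSE)
  }
  if ((onset_s + window_s) * fs > length(x)) {
    stop(sprintf("onset at %g s leaves less than %g s of signal after it",
                 onset_s, window_s), call. = FALSE)
  }
  if (!is.null(taps)) x <- apply_zero_phase(x, taps)
  i_on <- floor(onset_s * fs)
  w <- as.integer(floor(window_s * fs))
  cs <- x[(i_on + 1L):(i_on + w)]
  pre <- x[(i_on - w + 1L):i_on]
  p_cs <- welch_psd(cs, fs, n_segments)
  p_pre <- welch_psd(pre, fs, n_segments)
  den <- sum(p_pre$density)
  if (den == 0) {
    stop("pre-CS window has zero power; ratio undefined", call. = FALSE)
  }
  sum(p_cs$density) / den
}

#' Default session blocks for quantification
#'
#' The trial subsets averaged per behavioural state: all 5 habituation trials
#' (Hab), the last 3 acquisition trials (ACQ), the first 3 trials of
#' extinction day 1 (Early EXT), the last 3 trials of extinction day 2
#' (Late EXT), both extinction-recall trials and both renewal trials. The same
#' index rule applies to CS+ and CS-.
#'
#' @return data.frame with columns `block`, `session`, `trial_index`.
#' @export
default_session_blocks <- function() {
  rbind(
    data.frame(block = "Hab", session = "Hab", trial_index = 1:5),
    data.frame(block = "ACQ", session = "ACQ", trial_index = 3:5),
    data.frame(block = "EarlyEXT", session = "EXT1", trial_index = 1:3),
    data.frame(block = "LateEXT", session = "EXT2", trial_index = 10:12),
    data.frame(block = "EXTrecall", session = "EXT_recall", trial_index = 1:2),
    data.frame(block = "Renewal", session = "Renewal", trial_index = 1:2))
}

#' Average per-trial results over session blocks
#'
#' Computes mean, SEM and n of a per-trial measure over each block's trials,
#' separately per stimulus and per grouping column (`region`/`band` for power
#' ratios, none for coupling). Excluded (missing) trials reduce n; a block
#' left empty yields a row of NAs with a warning.
#'
#' @param results data.frame with at least `session`, `trial_index`,
#'   `stimulus` and the `value` column.
#' @param blocks Block definition as from [default_session_blocks()].
#' @param value Name of the measured column (e.g. `"ratio"`, `"peak_coeff"`).
#' @param by Extra grouping columns present in `results` (default
#'   `intersect(c("region", "band"), names(results))`).
#' @return data.frame with `block`, `session`, grouping columns, `stimulus`,
#'   `n`, `mean`, `sem`.
#' @export
block_average <- function(results, blocks = default_session_blocks(),
                          value = "ratio", by = NULL) {
  if (is.null(by)) by <- intersect(c("region", "band"), names(results))
  if (!value %in% names(results)) {
    stop(sprintf("column '%s' not found in results", value), call. = FALSE)
  }
  groups <- unique(results[, c(by, "stimulus"), drop = FALSE])
  out <- list()
  for (bl in unique(blocks$block)) {
    bdef <- blocks[blocks$block == bl, ]
    for (gi in seq_len(nrow(groups))) {
      sel <- results$session %in% bdef$session &
        results$trial_index %in% bdef$trial_index &
        results$stimulus == groups$stimulus[gi]
      for (col in by) sel <- sel & results[[col]] == groups[[col]][gi]
      v <- results[[value]][sel]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        warning(sprintf("block '%s' (%s) is empty after exclusions", bl,
                        paste(unlist(groups[gi, ]), collapse = "/")))
      }
      row <- data.frame(block = bl, session = bdef$session[1],
                        stringsAsFactors = FALSE)
      for (col in by) row[[col]] <- groups[[col]][gi]
      row$stimulus <- groups$stimulus[gi]
      row$n <- length(v)
      row$mean <- if (length(v)) mean(v) else NA_real_
      row$sem <- sem(v)
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
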