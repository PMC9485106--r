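#' Construct a two-region LFP recording
#'
#' Container for one session's continuous signals: a named list of equal-length
#' numeric channels (microvolts), a sampling rate, and region labels.
#'
#' @param samples Named list of numeric vectors, one per channel.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channels data.frame with columns `name`, `region` (region in
#'   `c("PL", "IL")`). Defaults to channel names doubling as regions.
#' @param session Session label.
#' @return Object of class `lfp_recording`. Sample index 1 corresponds to
#'   session time 0; analysis windows `[t0, t1)` in seconds map to samples
#'   `floor(t0 * fs) + 1` to `floor(t1 * fs)`.
#' @export
recording <- function(samples, sampling_rate_hz, channels = NULL,
                      session = "session") {
  if (!is.list(samples) || is.null(names(samples)) ||
      any(!nzchar(names(samples)))) {
    stop("`samples` must be a named list of numeric vectors", call. = FALSE)
  }
  lens <- lengths(samples)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("channels differ in length: %s",
                 paste(sprintf("%s=%d", names(samples), lens), collapse = ", ")),
         call. = FALSE)
  }
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  if (is.null(channels)) {
    channels <- data.frame(name = names(samples), region = names(samples),
                           stringsAsFactors = FALSE)
  }
  if (!all(channels$region %in% c("PL", "IL"))) {
    stop("channel regions must be 'PL' or 'IL'", call. = FALSE)
  }
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 channels = channels, session = session),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> session '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$session, length(x$samples), length(x$samples[[1]]),
              x$sampling_rate_hz,
              length(x$samples[[1]]) / x$sampling_rate_hz))
  invisible(x)
}

#' Extract the signal of one region from a recording
#'
#' @param rec An `lfp_recording`.
#' @param region `"PL"` or `"IL"`.
#' @return Numeric vector.
#' @export
region_signal <- function(rec, region) {
  stopifnot(inherits(rec, "lfp_recording"))
  idx <- which(rec$channels$region == region)
  if (length(idx) == 0) {
    stop(sprintf("recording '%s' has no channel for region '%s'",
                 rec$session, region), call. = FALSE)
  }
  rec$samples[[rec$channels$name[idx[1]]]]
}

write_events_tsv <- function(events, path) {
  out <- events
  out$us_onset_s <- ifelse(is.na(out$us_onset_s), "",
                           format(out$us_onset_s, digits = 15, trim = TRUE,
                                  scientific = FALSE))
  out$onset_s <- format(out$onset_s, digits = 15, trim = TRUE,
                        scientific = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read and validate a dataset directory
#'
#' Expects the layout written by [simulate_dafc_dataset()]: `dataset.json`
#' (metadata), `signals/<session>__<region>.f32` (little-endian float32 raw
#' samples) and `events.tsv`. Validates structural invariants and raises an
#' error naming the offending file or row on any violation: missing files,
#' channel length mismatches, non-monotone onsets, onsets with less than 15 s
#' of preceding baseline or extending past the end of the recording.
#'
#' @param dir Dataset directory.
#' @param min_baseline_s Required pre-onset baseline in seconds (default 15).
#' @return List with `recordings` (named list of [recording()] objects, one
#'   per session), `events` (data.frame), `metadata` (list), and
#'   `ground_truth` (list or NULL if absent).
#' @export
read_dataset <- function(dir, min_baseline_s = 15) {
  meta_path <- file.path(dir, "dataset.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("missing file: %s", meta_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  fs <- meta$sampling_rate_hz
  stopifnot_scalar_pos(fs, "sampling_rate_hz")
  cs_dur <- meta$cs_duration_s %||% 30

  ev_path <- file.path(dir, "events.tsv")
  if (!file.exists(ev_path)) {
    stop(sprintf("missing file: %s", ev_path), call. = FALSE)
  }
  events <- utils::read.table(ev_path, sep = "\t", header = TRUE,
                              colClasses = c("character", "integer",
                                             "character", "numeric",
                                             "character"),
                              stringsAsFactors = FALSE)
  events$us_onset_s <- suppressWarnings(as.numeric(events$us_onset_s))

  channels <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
  recs <- list()
  for (sess in meta$sessions) {
    sig <- list()
    for (ci in seq_len(nrow(channels))) {
      path <- file.path(dir, "signals",
                        sprintf("%s__%s.f32", sess, channels$name[ci]))
      if (!file.exists(path)) {
        stop(sprintf("missing file: %s", path), call. = FALSE)
      }
      nbytes <- file.info(path)$size
      if (nbytes %% 4 != 0) {
        stop(sprintf("truncated signal file (size %d not a multiple of 4): %s",
                     nbytes, path), call. = FALSE)
      }
      con <- file(path, "rb")
      sig[[channels$name[ci]]] <- readBin(con, "numeric", n = nbytes / 4,
                                          size = 4, endian = "little")
      close(con)
    }
    lens <- lengths(sig)
    if (length(unique(lens)) != 1L) {
      stop(sprintf("channel length mismatch in session '%s': %s", sess,
                   paste(sprintf("%s=%d", names(sig), lens), collapse = ", ")),
           call. = FALSE)
    }
    recs[[sess]] <- recording(sig, fs, channels, session = sess)

    ev <- events[events$session == sess, ]
    if (nrow(ev)) {
      if (is.unsorted(ev$onset_s, strictly = TRUE)) {
        bad <- which(diff(ev$onset_s) <= 0)[1] + 1L
        stop(sprintf("events.tsv: non-increasing onset in session '%s' at row %d (onset_s = %g)",
                     sess, which(events$session == sess)[bad], ev$onset_s[bad]),
             call. = FALSE)
      }
      for (i in seq_len(nrow(ev))) {
        row_id <- which(events$session == sess)[i]
        if (ev$onset_s[i] < min_baseline_s) {
          stop(sprintf("events.tsv row %d: onset_s = %g has less than %g s baseline (session '%s')",
                       row_id, ev$onset_s[i], min_baseline_s, sess),
               call. = FALSE)
        }
        if ((ev$onset_s[i] + cs_dur) * fs > lens[1]) {
          stop(sprintf("events.tsv row %d: onset_s = %g extends past end of recording (session '%s')",
                       row_id, ev$onset_s[i], sess), call. = FALSE)
        }
      }
      for (st in unique(ev$stimulus)) {
        ti <- sort(ev$trial_index[ev$stimulus == st])
        if (!identical(ti, seq_along(ti))) {
          stop(sprintf("events.tsv: trial_index not contiguous from 1 for (%s, %s)",
                       sess, st), call. = FALSE)
        }
      }
    }
  }

  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  } else NULL

  list(recordings = recs, events = events, metadata = meta, ground_truth = gt)
}

#' Write result tables as CSV files
#'
#' Writes `evoked_power.csv` (per-trial power ratios), `coupling.csv`
#' (per-trial peak coupling) and `session_summary.csv` (block means +/- SEM)
#' into `out_dir`. UTF-8, header row, '.' decimal separator. Empty input is a
#' warning no-op.
#'
#' @param tables Named list with any of `evoked_power`, `coupling`,
#'   `session_summary` data.frames.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  nonempty <- Filter(function(t) !is.null(t) && nrow(t) > 0, tables)
  if (length(nonempty) == 0) {
    warning("no result tables to write; nothing done")
    return(invisible(character()))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(nonempty)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(nonempty[[nm]], path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  invisible(paths)
}
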