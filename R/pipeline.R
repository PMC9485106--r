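#' Analysis configuration
#'
#' Validated container for every analysis knob. Unknown fields are rejected,
#' and the full configuration is serialized into the run log.
#'
#' @param bands Character vector of canonical band names to analyze
#'   (default all three).
#' @param filter A [filter_spec()].
#' @param artifact An [artifact_policy()].
#' @param n_segments Welch segment count (default 16).
#' @param window_s Analysis window length in seconds (default 15).
#' @param blocks Session block definition (default
#'   [default_session_blocks()]).
#' @param max_lag_ms Coupling lag window in ms (default 500).
#' @param peak_mode `"signed"` or `"absolute"`.
#' @param amplitude_mode `"filtered"` or `"envelope"`.
#' @param coupling_band Band used for coupling (default `"theta"`).
#' @param seed Seed for any resampling (default 1).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(bands = c("theta", "slow_gamma", "fast_gamma"),
                            filter = filter_spec(),
                            artifact = artifact_policy(),
                            n_segments = 16,
                            window_s = 15,
                            blocks = default_session_blocks(),
                            max_lag_ms = 500,
                            peak_mode = "signed",
                            amplitude_mode = "filtered",
                            coupling_band = "theta",
                            seed = 1) {
  unknown <- setdiff(bands, names(canonical_bands()))
  if (length(unknown)) {
    stop(sprintf("unknown band '%s' in config", unknown[1]), call. = FALSE)
  }
  if (!coupling_band %in% bands) {
    stop("`coupling_band` must be among the analyzed bands", call. = FALSE)
  }
  stopifnot(inherits(filter, "filter_spec"),
            inherits(artifact, "artifact_policy"))
  if (!peak_mode %in% c("signed", "absolute")) {
    stop("`peak_mode` must be 'signed' or 'absolute'", call. = FALSE)
  }
  if (!amplitude_mode %in% c("filtered", "envelope")) {
    stop("`amplitude_mode` must be 'filtered' or 'envelope'", call. = FALSE)
  }
  structure(list(bands = bands, filter = filter, artifact = artifact,
                 n_segments = n_segments, window_s = window_s,
                 blocks = blocks, max_lag_ms = max_lag_ms,
                 peak_mode = peak_mode, amplitude_mode = amplitude_mode,
                 coupling_band = coupling_band, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Accepts the keys of [analysis_config()] (with `filter` and `artifact` as
#' nested maps and `blocks` as a list of `{block, session, trial_index}`
#' entries); unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("bands", "filter", "artifact", "n_segments", "window_s",
             "blocks", "max_lag_ms", "peak_mode", "amplitude_mode",
             "coupling_band", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key '%s' in %s", unknown[1], path),
         call. = FALSE)
  }
  args <- y
  if (!is.null(y$filter)) args$filter <- do.call(filter_spec, y$filter)
  if (!is.null(y$artifact)) args$artifact <- do.call(artifact_policy, y$artifact)
  if (!is.null(y$blocks)) {
    args$blocks <- do.call(rbind, lapply(y$blocks, function(b)
      data.frame(block = b$block, session = b$session,
                 trial_index = unlist(b$trial_index))))
  }
  do.call(analysis_config, args)
}

#' Run the full analysis on a dataset directory
#'
#' Orchestrates read -> filter design -> artifact detection -> evoked power ->
#' coupling -> block averages, and writes `evoked_power.csv`, `coupling.csv`,
#' `session_summary.csv` plus a JSON run log (config snapshot, achieved filter
#' characteristics, exclusions with reasons, per-stage timings, dropped Welch
#' samples). If ground truth is present in the dataset, a recovery report
#' comparing measured block means against injected values is added. Outputs
#' are written atomically: on any stage error partial outputs are removed.
#'
#' @param dataset_dir Dataset directory (layout of [read_dataset()]).
#' @param config An [analysis_config()].
#' @param out_dir Results directory.
#' @return Invisibly, a list with the result tables, exclusions, and the run
#'   log.
#' @export
run_analysis <- function(dataset_dir, config = analysis_config(), out_dir) {
  t_all <- proc.time()[["elapsed"]]
  stage <- "read"
  timings <- list()
  ok <- FALSE
  tmp <- paste0(out_dir, ".partial")
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  on.exit(if (!ok) unlink(tmp, recursive = TRUE), add = TRUE)

  res <- tryCatch({
    t0 <- proc.time()[["elapsed"]]
    ds <- read_dataset(dataset_dir, min_baseline_s = config$window_s)
    fs <- ds$metadata$sampling_rate_hz
    timings$read <- proc.time()[["elapsed"]] - t0

    stage <- "filter-design"
    t0 <- proc.time()[["elapsed"]]
    bands <- canonical_bands()[config$bands]
    taps <- lapply(bands, design_bandpass, spec = config$filter,
                   sampling_rate_hz = fs)
    filter_report <- lapply(taps, function(h) attr(h, "achieved"))
    timings$filter_design <- proc.time()[["elapsed"]] - t0

    stage <- "artifacts"
    t0 <- proc.time()[["elapsed"]]
    exclusions <- list()
    for (sess in names(ds$recordings)) {
      rec <- ds$recordings[[sess]]
      ev <- ds$events[ds$events$session == sess, ]
      for (region in c("PL", "IL")) {
        ex <- detect_artifacts(region_signal(rec, region), fs, ev,
                               config$artifact,
                               baseline_s = config$window_s,
                               window_s = config$window_s)
        if (nrow(ex)) {
          ex$region <- region
          ex$reason <- "robust z-score artifact"
          exclusions[[length(exclusions) + 1L]] <- ex
        }
      }
    }
    exclusions <- if (length(exclusions)) {
      e <- do.call(rbind, exclusions)
      # a trial contaminated in either region is excluded everywhere
      unique(e[, c("session", "trial_index", "stimulus", "trigger_time_s",
                   "reason")])
    } else {
      data.frame(session = character(), trial_index = integer(),
                 stimulus = character(), trigger_time_s = numeric(),
                 reason = character(), stringsAsFactors = FALSE)
    }
    timings$artifacts <- proc.time()[["elapsed"]] - t0

    stage <- "evoked-power"
    t0 <- proc.time()[["elapsed"]]
    t_coupling <- 0
    power_rows <- list()
    coupling_rows <- list()
    for (sess in names(ds$recordings)) {
      rec <- ds$recordings[[sess]]
      ev <- ds$events[ds$events$session == sess, ]
      if (nrow(ev) == 0) next
      for (bname in config$bands) {
        # filter each region once per band; coupling reuses the filtered
        # signals of the coupling band instead of re-filtering
        filt <- list(
          PL = apply_zero_phase(region_signal(rec, "PL"), taps[[bname]]),
          IL = apply_zero_phase(region_signal(rec, "IL"), taps[[bname]]))
        for (region in c("PL", "IL")) {
          for (i in seq_len(nrow(ev))) {
            skip <- nrow(exclusions) > 0 &&
              any(exclusions$session == sess &
                    exclusions$trial_index == ev$trial_index[i] &
                    exclusions$stimulus == ev$stimulus[i])
            if (skip) next
            ratio <- evoked_power_ratio(filt[[region]], fs, ev$onset_s[i],
                                        taps = NULL,
                                        window_s = config$window_s,
                                        n_segments = config$n_segments)
            power_rows[[length(power_rows) + 1L]] <- data.frame(
              session = sess, region = region, band = bname,
              stimulus = ev$stimulus[i], trial_index = ev$trial_index[i],
              ratio = ratio, stringsAsFactors = FALSE)
          }
        }
        if (bname == config$coupling_band) {
          tc0 <- proc.time()[["elapsed"]]
          frec <- recording(filt, fs, rec$channels, session = sess)
          coupling_rows[[length(coupling_rows) + 1L]] <- trial_coupling(
            frec, ev, taps = NULL, window = "CS",
            max_lag_ms = config$max_lag_ms, mode = config$peak_mode,
            amplitude_mode = config$amplitude_mode,
            window_s = config$window_s, excluded = exclusions)
          t_coupling <- t_coupling + (proc.time()[["elapsed"]] - tc0)
        }
      }
    }
    evoked_power <- do.call(rbind, power_rows)
    coupling <- do.call(rbind, coupling_rows)
    rownames(coupling) <- NULL
    timings$coupling <- t_coupling
    timings$evoked_power <- proc.time()[["elapsed"]] - t0 - t_coupling

    stage <- "aggregate"
    t0 <- proc.time()[["elapsed"]]
    power_summary <- block_average(evoked_power, config$blocks,
                                   value = "ratio")
    power_summary$measure <- "evoked_power_ratio"
    names(power_summary)[names(power_summary) == "region"] <- "region_or_pair"
    coupling_summary <- session_coupling_average(coupling, config$blocks)
    coupling_summary$region_or_pair <- "PL-IL"
    coupling_summary$band <- config$coupling_band
    coupling_summary$measure <- "peak_xcorr_coeff"
    cols <- c("block", "session", "region_or_pair", "band", "stimulus",
              "measure", "n", "mean", "sem")
    session_summary <- rbind(power_summary[, cols], coupling_summary[, cols])
    timings$aggregate <- proc.time()[["elapsed"]] - t0

    stage <- "write"
    write_results(list(evoked_power = evoked_power, coupling = coupling,
                       session_summary = session_summary), tmp)

    recovery <- NULL
    if (!is.null(ds$ground_truth)) {
      recovery <- recovery_report(evoked_power, coupling, ds$ground_truth)
      utils::write.csv(recovery, file.path(tmp, "recovery_report.csv"),
                       row.names = FALSE, quote = FALSE)
    }

    run_log <- list(
      package_version = as.character(utils::packageVersion("fearlfp")),
      config = serialize_config(config),
      sampling_rate_hz = fs,
      achieved_filters = filter_report,
      welch_dropped_samples =
        floor(config$window_s * fs) %% config$n_segments,
      excluded_trials = exclusions,
      stage_seconds = timings,
      total_seconds = proc.time()[["elapsed"]] - t_all)
    jsonlite::write_json(run_log, file.path(tmp, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)

    list(evoked_power = evoked_power, coupling = coupling,
         session_summary = session_summary, exclusions = exclusions,
         recovery = recovery, run_log = run_log)
  }, error = function(e) {
    stop(sprintf("analysis failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  # atomic publish
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  ok <- file.rename(tmp, out_dir)
  if (!ok) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(tmp, full.names = TRUE), out_dir, recursive = TRUE)
    unlink(tmp, recursive = TRUE)
    ok <- TRUE
  }
  invisible(res)
}

serialize_config <- function(config) {
  list(bands = config$bands,
       filter = unclass(config$filter),
       artifact = unclass(config$artifact),
       n_segments = config$n_segments,
       window_s = config$window_s,
       blocks = config$blocks,
       max_lag_ms = config$max_lag_ms,
       peak_mode = config$peak_mode,
       amplitude_mode = config$amplitude_mode,
       coupling_band = config$coupling_band,
       seed = config$seed)
}

# Compare measured block means to injected ground truth: the injected
# amplitude gain g should be recovered as a power ratio of g^2, and the
# injected coupling coefficient as the mean peak cross-correlation.
recovery_report <- function(evoked_power, coupling, ground_truth) {
  gt_tr <- as.data.frame(ground_truth$trials)
  key <- c("session", "stimulus", "trial_index", "region", "band")
  m <- merge(evoked_power, gt_tr[, c(key, "gain")], by = key)
  pr <- stats::aggregate(cbind(ratio, gain) ~ session + stimulus + region + band,
                         data = m, FUN = mean)
  pr <- data.frame(measure = "evoked_power_ratio", session = pr$session,
                   stimulus = pr$stimulus, region_or_pair = pr$region,
                   band = pr$band, measured = pr$ratio,
                   injected = pr$gain^2, stringsAsFactors = FALSE)
  gt_se <- as.data.frame(ground_truth$sessions)
  cm <- stats::aggregate(peak_coeff ~ session + stimulus, data = coupling,
                         FUN = mean)
  cm <- merge(cm, gt_se, by = c("session", "stimulus"))
  cr <- data.frame(measure = "peak_xcorr_coeff", session = cm$session,
                   stimulus = cm$stimulus, region_or_pair = "PL-IL",
                   band = "theta", measured = cm$peak_coeff,
                   injected = cm$coupling, stringsAsFactors = FALSE)
  out <- rbind(pr, cr)
  out$error <- out$measured - out$injected
  out
}

#' Permutation contrast between two groups of values
#'
#' Two-sided label-shuffle permutation test of the mean difference:
#' `p = (1 + #{|perm diff| >= |observed diff|}) / (n_perm + 1)`. When every
#' value is identical across both groups the difference is degenerate and
#' p = 1 by convention. This is the package's self-contained alternative to
#' parametric session contrasts.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `observed` (mean(a) - mean(b)) and `p_value`.
#' @examples
#' permutation_contrast(c(10, 11, 12), c(0, 1, 2), n_perm = 199, seed = 1)
#' @export
permutation_contrast <- function(values_a, values_b, n_perm = 1000, seed = 1) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  obs <- mean(values_a) - mean(values_b)
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    return(list(observed = 0, p_value = 1))
  }
  na <- length(values_a)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), na)
      d <- mean(pooled[idx]) - mean(pooled[-idx])
      if (abs(d) >= abs(obs) - 1e-12) hits <- hits + 1L
    }
    list(observed = obs, p_value = (1 + hits) / (n_perm + 1))
  })
}
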