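#' Simulation configuration for synthetic two-region LFP datasets
#'
#' Collects every knob of the synthetic-data generator: sampling rate, 1/f
#' background noise, band-limited oscillatory components, the multiplicative
#' CS-evoked gain table, the inter-region theta coupling table, and trial
#' timing. Defaults emulate the study conditions of a five-day discriminative
#' auditory fear conditioning (DAFC) protocol: 1 kHz sampling, pink (1/f)
#' background, a dominant theta oscillation with weaker gamma components,
#' inter-trial intervals of 90-120 s and a 3-minute pre-session period.
#'
#' @param sampling_rate_hz Sampling rate in Hz (default 1000).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1, i.e. pink noise).
#' @param noise_rms_uV RMS of the background noise in microvolts (default 15).
#' @param band_components Named numeric vector of oscillation amplitudes in
#'   microvolts per canonical band; an oscillation of amplitude A has RMS
#'   A/sqrt(2). Default `c(theta = 60, slow_gamma = 10, fast_gamma = 8)`,
#'   a theta-dominated spectrum typical of rodent prefrontal LFP.
#' @param cs_gain_table data.frame with columns `region`, `session`,
#'   `stimulus`, `band`, `gain` giving the multiplicative amplitude gain
#'   applied to that band's component during CS windows. Pairs not listed
#'   default to gain 1. See [default_gain_table()].
#' @param coupling_table data.frame with columns `session`, `stimulus`,
#'   `coupling`: the fraction (in \[0, 1\]) of the IL theta component shared
#'   with the (lag-shifted) PL theta component during that stimulus's CS
#'   windows. See [default_coupling_table()].
#' @param baseline_coupling Coupling coefficient outside CS windows
#'   (default 0.2).
#' @param coupling_lag_ms Lag of the shared theta component in ms
#'   (default 25). Positive lag means the PL-vs-IL cross-correlation peaks at
#'   a positive lag.
#' @param iti_range_s Length-2 vector, inter-trial interval range in seconds
#'   (offset to next onset; default `c(90, 120)`).
#' @param pre_session_s Silence before the first CS onset in seconds
#'   (default 180, the pre-session exploration period; must be >= 15).
#' @param mains_amplitude_uV Amplitude of an optional 50 Hz mains component
#'   (default 0 = off).
#' @param mains_hz Mains frequency in Hz (default 50).
#' @param seed Integer seed; a fixed seed gives a byte-identical dataset.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate_hz = 1000,
                              noise_exponent = 1,
                              noise_rms_uV = 15,
                              band_components = c(theta = 60, slow_gamma = 10,
                                                  fast_gamma = 8),
                              cs_gain_table = default_gain_table(),
                              coupling_table = default_coupling_table(),
                              baseline_coupling = 0.2,
                              coupling_lag_ms = 25,
                              iti_range_s = c(90, 120),
                              pre_session_s = 180,
                              mains_amplitude_uV = 0,
                              mains_hz = 50,
                              seed = 1) {
  stopifnot_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  if (!is.numeric(noise_rms_uV) || noise_rms_uV < 0) {
    stop("`noise_rms_uV` must be >= 0 (0 disables background noise)",
         call. = FALSE)
  }
  if (any(band_components < 0)) stop("band amplitudes must be >= 0", call. = FALSE)
  if (is.null(names(band_components)) || any(!nzchar(names(band_components)))) {
    stop("`band_components` must be a named vector", call. = FALSE)
  }
  need <- c("region", "session", "stimulus", "band", "gain")
  if (!all(need %in% names(cs_gain_table))) {
    stop("`cs_gain_table` needs columns region, session, stimulus, band, gain",
         call. = FALSE)
  }
  if (any(cs_gain_table$gain < 0)) stop("all CS gains must be >= 0", call. = FALSE)
  if (!all(c("session", "stimulus", "coupling") %in% names(coupling_table))) {
    stop("`coupling_table` needs columns session, stimulus, coupling",
         call. = FALSE)
  }
  if (any(coupling_table$coupling < 0 | coupling_table$coupling > 1)) {
    stop("coupling coefficients must lie in [0, 1]", call. = FALSE)
  }
  if (baseline_coupling < 0 || baseline_coupling > 1) {
    stop("`baseline_coupling` must lie in [0, 1]", call. = FALSE)
  }
  if (length(iti_range_s) != 2 || iti_range_s[1] > iti_range_s[2]) {
    stop("`iti_range_s` must be c(low, high) with low <= high", call. = FALSE)
  }
  if (iti_range_s[1] < 15.5) {
    stop("`iti_range_s` low end must be >= 15.5 s to keep a clean 15-s pre-CS baseline",
         call. = FALSE)
  }
  if (pre_session_s < 15) stop("`pre_session_s` must be >= 15 s", call. = FALSE)
  structure(list(
    sampling_rate_hz = sampling_rate_hz,
    noise_exponent = noise_exponent,
    noise_rms_uV = noise_rms_uV,
    band_components = band_components,
    cs_gain_table = cs_gain_table,
    coupling_table = coupling_table,
    baseline_coupling = baseline_coupling,
    coupling_lag_ms = coupling_lag_ms,
    iti_range_s = as.numeric(iti_range_s),
    pre_session_s = pre_session_s,
    mains_amplitude_uV = mains_amplitude_uV,
    mains_hz = mains_hz,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Five-day DAFC session plan
#'
#' The default plan is the canonical protocol: habituation (5 CS+ / 5 CS-),
#' acquisition (5/5, US paired with CS+), two extinction days (12/12 each),
#' extinction recall (2/2) and renewal (2/2); 30-s CSs composed of 500-ms pips
#' at 1.5 Hz.
#'
#' @param sessions data.frame with columns `session`, `context`, `n_cs_plus`,
#'   `n_cs_minus`, `us_paired`.
#' @param cs_duration_s CS duration in seconds (default 30).
#' @param pip_rate_hz,pip_duration_ms,n_pips Pip structure metadata (defaults
#'   1.5 Hz, 500 ms, 20). Pips are protocol metadata and are not rendered into
#'   the signal.
#' @return Object of class `session_plan`.
#' @export
session_plan <- function(sessions,
                         cs_duration_s = 30,
                         pip_rate_hz = 1.5,
                         pip_duration_ms = 500,
                         n_pips = 20) {
  need <- c("session", "context", "n_cs_plus", "n_cs_minus", "us_paired")
  if (!all(need %in% names(sessions))) {
    stop("`sessions` needs columns session, context, n_cs_plus, n_cs_minus, us_paired",
         call. = FALSE)
  }
  if (anyDuplicated(sessions$session)) {
    stop("session names must be unique", call. = FALSE)
  }
  if (n_pips * (1 / pip_rate_hz) > cs_duration_s) {
    stop("pip train (n_pips / pip_rate_hz) does not fit into cs_duration_s",
         call. = FALSE)
  }
  structure(list(sessions = sessions, cs_duration_s = cs_duration_s,
                 pip_rate_hz = pip_rate_hz, pip_duration_ms = pip_duration_ms,
                 n_pips = n_pips),
            class = "session_plan")
}

#' @rdname session_plan
#' @export
default_session_plan <- function() {
  session_plan(data.frame(
    session   = c("Hab", "ACQ", "EXT1", "EXT2", "EXT_recall", "Renewal"),
    context   = c("A", "A", "B", "B", "B", "A"),
    n_cs_plus = c(5L, 5L, 12L, 12L, 2L, 2L),
    n_cs_minus = c(5L, 5L, 12L, 12L, 2L, 2L),
    us_paired = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE))
}

#' Default CS-evoked gain table
#'
#' Theta amplitude gains emulating the fear-state pattern: PL theta up during
#' acquisition and renewal (high-fear states), IL theta up in late extinction
#' and down in renewal; all effects CS+-specific; gamma bands unchanged.
#' Pairs not listed have gain 1.
#'
#' @return data.frame with columns `region`, `session`, `stimulus`, `band`,
#'   `gain`.
#' @export
default_gain_table <- function() {
  data.frame(
    region   = c("PL", "PL", "IL", "IL"),
    session  = c("ACQ", "Renewal", "EXT2", "Renewal"),
    stimulus = "CS_PLUS",
    band     = "theta",
    gain     = c(1.5, 1.5, 1.4, 0.8),
    stringsAsFactors = FALSE)
}

#' Default PL-IL theta coupling table
#'
#' Coupling coefficients per (session, stimulus) emulating the fear-state
#' pattern: CS+ coupling elevated throughout fear and extinction learning and
#' extinction recall, but reduced during renewal; CS- coupling flat except a
#' moderate rise in early extinction. The recall/renewal values (0.52 / 0.30)
#' sit in the empirically representative 0.3-0.5 range for prefrontal LFP
#' pairs. Pairs not listed fall back to the baseline coupling.
#'
#' @return data.frame with columns `session`, `stimulus`, `coupling`.
#' @export
default_coupling_table <- function() {
  rbind(
    data.frame(session = c("Hab", "ACQ", "EXT1", "EXT2", "EXT_recall", "Renewal"),
               stimulus = "CS_PLUS",
               coupling = c(0.20, 0.45, 0.45, 0.50, 0.52, 0.30),
               stringsAsFactors = FALSE),
    data.frame(session = c("Hab", "ACQ", "EXT1", "EXT2", "EXT_recall", "Renewal"),
               stimulus = "CS_MINUS",
               coupling = c(0.20, 0.20, 0.40, 0.20, 0.20, 0.20),
               stringsAsFactors = FALSE))
}

#' Generate 1/f^beta background noise
#'
#' Gaussian noise shaped in the frequency domain so its spectral density
#' follows 1/f^exponent, scaled to an exact sample RMS. `exponent = 0` gives
#' white noise, `exponent = 1` pink noise.
#'
#' @param n_samples Number of samples (> 0).
#' @param exponent Spectral slope beta.
#' @param rms Target RMS (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_pink_noise <- function(n_samples, exponent = 1, rms = 1, seed = 1) {
  if (!is.numeric(n_samples) || n_samples <= 0) {
    stop("`n_samples` must be positive", call. = FALSE)
  }
  stopifnot_scalar_pos(rms, "rms")
  n <- as.integer(n_samples)
  # Build at a power-of-two length (mixed-radix FFTs on awkward lengths are
  # prohibitively slow) and keep the first n samples of the stationary result.
  ng <- next_pow2(n)
  with_seed(seed, {
    m <- ng %/% 2
    # Hermitian spectrum: random complex Gaussians with 1/f^(beta/2) magnitude.
    f_idx <- seq_len(m)
    amp <- f_idx^(-exponent / 2)
    re <- rnorm(m) * amp
    im <- rnorm(m) * amp
    spec <- complex(real = re, imaginary = im)
    spec[m] <- complex(real = re[m], imaginary = 0)
    full <- c(0, spec, Conj(rev(spec[-m])))
    x <- Re(fft(full, inverse = TRUE))[seq_len(n)] / ng
    x <- x - mean(x)
    x * rms / sqrt(mean(x^2))
  })
}

#' Generate a band-limited stochastic oscillation
#'
#' Narrowband Gaussian noise constructed in the frequency domain: random
#' complex coefficients restricted to `[f_lo, f_hi]` with short cosine tapers
#' just inside the edges, inverse-transformed and scaled so the sample RMS is
#' `amplitude / sqrt(2)` (the RMS of a sinusoid of that amplitude). All of its
#' power lies inside the band by construction.
#'
#' @param band A [band_definition()].
#' @param n_samples Number of samples.
#' @param sampling_rate_hz Sampling rate in Hz; band edges must be below
#'   Nyquist.
#' @param amplitude Peak-equivalent amplitude; `0` gives an all-zero signal.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_band_oscillation <- function(band, n_samples, sampling_rate_hz,
                                      amplitude = 1, seed = 1) {
  stopifnot(inherits(band, "band_definition"))
  if (!is.numeric(n_samples) || n_samples <= 0) {
    stop("`n_samples` must be positive", call. = FALSE)
  }
  if (band$f_hi >= sampling_rate_hz / 2) {
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 band$f_hi, sampling_rate_hz / 2), call. = FALSE)
  }
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  n <- as.integer(n_samples)
  if (amplitude == 0) return(numeric(n))
  ng <- next_pow2(n)   # power-of-two FFT length; first n samples are kept
  with_seed(seed, {
    m <- ng %/% 2
    f <- seq_len(m) * sampling_rate_hz / ng
    # cosine taper over 5% of the bandwidth inside each edge
    tw <- 0.05 * (band$f_hi - band$f_lo)
    env <- numeric(m)
    inb <- f >= band$f_lo & f <= band$f_hi
    env[inb] <- 1
    lo_t <- f >= band$f_lo & f < band$f_lo + tw
    hi_t <- f > band$f_hi - tw & f <= band$f_hi
    env[lo_t] <- 0.5 - 0.5 * cos(pi * (f[lo_t] - band$f_lo) / tw)
    env[hi_t] <- 0.5 - 0.5 * cos(pi * (band$f_hi - f[hi_t]) / tw)
    re <- rnorm(m) * env
    im <- rnorm(m) * env
    spec <- complex(real = re, imaginary = im)
    spec[m] <- complex(real = re[m], imaginary = 0)
    full <- c(0, spec, Conj(rev(spec[-m])))
    x <- Re(fft(full, inverse = TRUE))[seq_len(n)] / ng
    r <- sqrt(mean(x^2))
    if (r == 0) return(numeric(n))
    x * (amplitude / sqrt(2)) / r
  })
}

# Constrained pseudorandom interleaving of CS+ and CS- with at most
# `max_run` consecutive same-type trials.
pseudorandom_order <- function(n_plus, n_minus, max_run = 3) {
  types <- c(rep("CS_PLUS", n_plus), rep("CS_MINUS", n_minus))
  if (n_plus == 0L || n_minus == 0L || length(types) <= 1) return(types)
  for (i in seq_len(1000)) {
    cand <- sample(types)
    if (max(rle(cand)$lengths) <= max_run) return(cand)
  }
  stop("could not draw a constrained stimulus order", call. = FALSE)
}

# Multiplicative envelope: 1 outside windows, `gain` inside, with
# `ramp_s`-long raised-cosine ramps just inside each window edge.
gain_envelope <- function(n, fs, onsets_s, duration_s, gains, ramp_s = 0.2) {
  env <- rep(1, n)
  for (i in seq_along(onsets_s)) {
    g <- gains[i]
    if (g == 1) next
    i0 <- floor(onsets_s[i] * fs) + 1L
    i1 <- min(floor((onsets_s[i] + duration_s) * fs), n)
    if (i0 > n) next
    seg <- i0:i1
    t_rel <- (seg - i0) / fs
    t_end <- (i1 - seg) / fs
    r <- pmin(1, t_rel / ramp_s, t_end / ramp_s)
    w <- 0.5 - 0.5 * cos(pi * pmax(0, pmin(1, r)))
    env[seg] <- 1 + (g - 1) * w
  }
  env
}

lookup_gain <- function(tab, region, session, stimulus, band) {
  hit <- tab$region == region & tab$session == session &
    tab$stimulus == stimulus & tab$band == band
  if (any(hit)) tab$gain[which(hit)[1]] else 1
}

lookup_coupling <- function(tab, session, stimulus, fallback) {
  hit <- tab$session == session & tab$stimulus == stimulus
  if (any(hit)) tab$coupling[which(hit)[1]] else fallback
}

#' Simulate a complete DAFC dataset
#'
#' Generates, for every session of the plan, a two-channel (PL, IL) recording
#' and an event table, and writes them in the on-disk dataset layout (see
#' [read_dataset()]), together with a ground-truth file recording every
#' injected gain and coupling coefficient.
#'
#' Signal model, per region: 1/f^beta background noise plus one band-limited
#' Gaussian oscillation per configured band. During each CS window the
#' designated region/band component is multiplied by the configured gain
#' (raised-cosine 200-ms ramps at window edges). The IL theta component is
#' `c(t) * [lag-shifted PL theta] + sqrt(1 - c(t)^2) * [independent theta]`
#' with the mixing coefficient `c(t)` set per (session, stimulus) inside CS
#' windows and to the baseline coupling elsewhere, so the theoretical peak
#' correlation of the two theta components during a CS equals the configured
#' coupling coefficient. Gamma components are independent between regions.
#'
#' @param config A [simulation_config()].
#' @param plan A [session_plan()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `dir`, `ground_truth` (list with `trials`
#'   and `sessions` data.frames and `seed`), and `events` (the event table).
#' @examples
#' \donttest{
#' d <- simulate_dafc_dataset(simulation_config(seed = 7),
#'                            default_session_plan(), tempfile("dafc"))
#' nrow(d$events)  # 76 = 38 CS+ + 38 CS-
#' }
#' @export
simulate_dafc_dataset <- function(config, plan = default_session_plan(),
                                  out_dir) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(plan, "session_plan"))
  known_sessions <- plan$sessions$session
  known_bands <- names(config$band_components)
  gt <- config$cs_gain_table
  bad <- !(gt$session %in% known_sessions)
  if (any(bad)) {
    stop(sprintf("cs_gain_table references unknown session '%s'",
                 gt$session[which(bad)[1]]), call. = FALSE)
  }
  bad <- !(gt$region %in% c("PL", "IL"))
  if (any(bad)) {
    stop(sprintf("cs_gain_table references unknown region '%s'",
                 gt$region[which(bad)[1]]), call. = FALSE)
  }
  bad <- !(gt$band %in% known_bands)
  if (any(bad)) {
    stop(sprintf("cs_gain_table references unknown band '%s'",
                 gt$band[which(bad)[1]]), call. = FALSE)
  }
  bad <- !(config$coupling_table$session %in% known_sessions)
  if (any(bad)) {
    stop(sprintf("coupling_table references unknown session '%s'",
                 config$coupling_table$session[which(bad)[1]]), call. = FALSE)
  }

  fs <- config$sampling_rate_hz
  dir.create(file.path(out_dir, "signals"), recursive = TRUE,
             showWarnings = FALSE)

  all_events <- list()
  gt_trials <- list()
  gt_sessions <- list()
  bands <- canonical_bands()[known_bands]
  if (any(vapply(bands, is.null, logical(1)))) {
    extra <- setdiff(known_bands, names(canonical_bands()))
    stop(sprintf("unknown band component '%s' (canonical: %s)", extra[1],
                 paste(names(canonical_bands()), collapse = ", ")),
         call. = FALSE)
  }
  lag_samples <- round(config$coupling_lag_ms / 1000 * fs)

  for (si in seq_len(nrow(plan$sessions))) {
    sess <- plan$sessions$session[si]
    n_plus <- plan$sessions$n_cs_plus[si]
    n_minus <- plan$sessions$n_cs_minus[si]
    us_paired <- plan$sessions$us_paired[si]

    ev_seed <- child_seed(config$seed, paste0("events/", sess))
    ev <- with_seed(ev_seed, {
      stim <- pseudorandom_order(n_plus, n_minus)
      iti <- runif(length(stim), config$iti_range_s[1], config$iti_range_s[2])
      onset <- config$pre_session_s +
        cumsum(c(0, head(plan$cs_duration_s + iti, -1)))
      data.frame(session = sess, stimulus = stim, onset_s = onset,
                 stringsAsFactors = FALSE)
    })
    ev$trial_index <- stats::ave(seq_len(nrow(ev)), ev$stimulus,
                                 FUN = seq_along)
    ev$us_onset_s <- ifelse(us_paired & ev$stimulus == "CS_PLUS",
                            ev$onset_s + plan$cs_duration_s, NA_real_)

    n <- ceiling((max(ev$onset_s) + plan$cs_duration_s + 30) * fs)

    # unit-RMS band component shapes
    shape <- function(region, bname) {
      generate_band_oscillation(bands[[bname]], n, fs, amplitude = sqrt(2),
                                seed = child_seed(config$seed,
                                                  paste0(sess, "/", region, "/", bname)))
    }

    sig <- list(PL = numeric(n), IL = numeric(n))
    for (region in c("PL", "IL")) {
      if (config$noise_rms_uV > 0) {
        sig[[region]] <- generate_pink_noise(
          n, config$noise_exponent, config$noise_rms_uV,
          seed = child_seed(config$seed, paste0(sess, "/", region, "/noise")))
      }
      if (config$mains_amplitude_uV > 0) {
        tt <- (seq_len(n) - 1) / fs
        sig[[region]] <- sig[[region]] +
          config$mains_amplitude_uV * sin(2 * pi * config$mains_hz * tt)
      }
    }

    for (bname in known_bands) {
      amp <- config$band_components[[bname]]
      if (bname == "theta") {
        p_hat <- shape("PL", "theta")
        q_hat <- shape("IL", "theta")
        # time-varying mixing coefficient, per-stimulus CS coupling
        cpl <- vapply(c("CS_PLUS", "CS_MINUS"), function(st)
          lookup_coupling(config$coupling_table, sess, st,
                          config$baseline_coupling), numeric(1))
        cvec <- rep(config$baseline_coupling, n)
        for (st in c("CS_PLUS", "CS_MINUS")) {
          for (o in ev$onset_s[ev$stimulus == st]) {
            i0 <- floor(o * fs) + 1L
            i1 <- min(floor((o + plan$cs_duration_s) * fs), n)
            if (i0 > n) next
            seg <- i0:i1
            t_rel <- (seg - i0) / fs
            t_end <- (i1 - seg) / fs
            r <- pmax(0, pmin(1, t_rel / 0.2, t_end / 0.2))
            w <- 0.5 - 0.5 * cos(pi * r)
            cvec[seg] <- config$baseline_coupling +
              (cpl[[st]] - config$baseline_coupling) * w
          }
        }
        cvec <- pmax(0, pmin(1, cvec))
        p_shift <- if (lag_samples == 0) p_hat else {
          k <- ((lag_samples %% n) + n) %% n
          c(p_hat[(k + 1):n], p_hat[seq_len(k)])
        }
        i_hat <- cvec * p_shift + sqrt(1 - cvec^2) * q_hat
        comp <- list(PL = p_hat, IL = i_hat)
      } else {
        comp <- list(PL = shape("PL", bname), IL = shape("IL", bname))
      }
      for (region in c("PL", "IL")) {
        gains <- vapply(seq_len(nrow(ev)), function(i)
          lookup_gain(config$cs_gain_table, region, sess, ev$stimulus[i],
                      bname), numeric(1))
        env <- gain_envelope(n, fs, ev$onset_s, plan$cs_duration_s, gains)
        sig[[region]] <- sig[[region]] +
          (amp / sqrt(2)) * comp[[region]] * env
      }
    }

    for (region in c("PL", "IL")) {
      path <- file.path(out_dir, "signals",
                        sprintf("%s__%s.f32", sess, region))
      con <- file(path, "wb")
      writeBin(as.numeric(sig[[region]]), con, size = 4, endian = "little")
      close(con)
    }

    all_events[[sess]] <- ev[, c("session", "trial_index", "stimulus",
                                 "onset_s", "us_onset_s")]
    for (region in c("PL", "IL")) {
      for (bname in known_bands) {
        gt_trials[[length(gt_trials) + 1L]] <- data.frame(
          session = sess, trial_index = ev$trial_index,
          stimulus = ev$stimulus, region = region, band = bname,
          gain = vapply(seq_len(nrow(ev)), function(i)
            lookup_gain(config$cs_gain_table, region, sess, ev$stimulus[i],
                        bname), numeric(1)),
          stringsAsFactors = FALSE)
      }
    }
    for (st in c("CS_PLUS", "CS_MINUS")) {
      gt_sessions[[length(gt_sessions) + 1L]] <- data.frame(
        session = sess, stimulus = st,
        coupling = lookup_coupling(config$coupling_table, sess, st,
                                   config$baseline_coupling),
        lag_ms = config$coupling_lag_ms, stringsAsFactors = FALSE)
    }
  }

  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  write_events_tsv(events, file.path(out_dir, "events.tsv"))

  meta <- list(
    sampling_rate_hz = fs,
    units = "uV",
    channels = list(list(name = "PL", region = "PL"),
                    list(name = "IL", region = "IL")),
    sessions = plan$sessions$session,
    cs_duration_s = plan$cs_duration_s)
  jsonlite::write_json(meta, file.path(out_dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ground_truth <- list(trials = do.call(rbind, gt_trials),
                       sessions = do.call(rbind, gt_sessions),
                       seed = config$seed)
  jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)

  invisible(list(dir = out_dir, ground_truth = ground_truth, events = events))
}

#' Synthetic per-trial freezing percentages
#'
#' Produces plausible freezing scores for demonstration tables: a noisy
#' increasing function of the injected PL theta gain of each trial, clipped to
#' \[0, 100\]. With all gains at 1 the expected freezing sits at a low
#' baseline (~8%).
#'
#' @param ground_truth Ground-truth list from [simulate_dafc_dataset()].
#' @param plan The [session_plan()] used.
#' @param seed Integer seed.
#' @param baseline Baseline freezing percentage (default 8).
#' @param slope Increase in freezing percentage per unit amplitude-gain excess
#'   (default 55).
#' @param noise_sd SD of the additive noise (default 5).
#' @return data.frame with `session`, `trial_index`, `stimulus`,
#'   `freezing_pct`.
#' @export
generate_freezing <- function(ground_truth, plan, seed = 1,
                              baseline = 8, slope = 55, noise_sd = 5) {
  tr <- ground_truth$trials
  tr <- tr[tr$region == "PL" & tr$band == "theta", ]
  if (nrow(tr) == 0) stop("ground truth has no PL theta entries", call. = FALSE)
  with_seed(seed, {
    f <- baseline + slope * (tr$gain - 1) + rnorm(nrow(tr), 0, noise_sd)
    data.frame(session = tr$session, trial_index = tr$trial_index,
               stimulus = tr$stimulus,
               freezing_pct = pmin(100, pmax(0, f)),
               stringsAsFactors = FALSE)
  })
}
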