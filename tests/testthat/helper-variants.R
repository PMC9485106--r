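# Desk-scale study variants used by the recovery tests: short ITIs and
# pre-session periods keep runtimes tractable while preserving the 15-s
# baseline / 15-s CS analysis windows and the protocol structure.

# One session, n CS+ and n CS- trials, PL theta CS+ amplitude gain `g`,
# all three band components present.
gain_recovery_config <- function(g, fs = 1000, seed = 1) {
  simulation_config(
    sampling_rate_hz = fs,
    iti_range_s = c(16, 18), pre_session_s = 20,
    cs_gain_table = data.frame(region = "PL", session = "S1",
                               stimulus = "CS_PLUS", band = "theta",
                               gain = g),
    coupling_table = data.frame(session = "S1", stimulus = "CS_PLUS",
                                coupling = 0.45),
    seed = seed)
}

# One session per coupling level, 20 CS+ trials each, theta-only components.
coupling_recovery_setup <- function(levels, fs = 1000, seed = 1,
                                    n_trials = 20L, lag_ms = 25) {
  sess <- sprintf("C%02.0f", levels * 100)
  plan <- session_plan(data.frame(
    session = sess, context = "A", n_cs_plus = n_trials, n_cs_minus = 0L,
    us_paired = FALSE, stringsAsFactors = FALSE))
  cfg <- simulation_config(
    sampling_rate_hz = fs,
    band_components = c(theta = 60),
    iti_range_s = c(16, 18), pre_session_s = 20,
    cs_gain_table = default_gain_table()[0, ],
    coupling_table = data.frame(session = sess, stimulus = "CS_PLUS",
                                coupling = levels),
    coupling_lag_ms = lag_ms,
    seed = seed)
  list(plan = plan, config = cfg, sessions = sess)
}

# Six-session pattern variant: default gain/coupling tables, 20 trials per
# stimulus per session, theta-only components.
pattern_variant <- function(seed, fs = 250, n_trials = 20L) {
  sess <- default_session_plan()$sessions
  sess$n_cs_plus <- n_trials
  sess$n_cs_minus <- n_trials
  plan <- session_plan(sess)
  cfg <- simulation_config(
    sampling_rate_hz = fs,
    band_components = c(theta = 60),
    iti_range_s = c(16, 18), pre_session_s = 20,
    seed = seed)
  list(plan = plan, config = cfg)
}

# Session-mean table (one row per session) for one measure/stimulus.
session_means <- function(df, value, stimulus) {
  d <- df[df$stimulus == stimulus, ]
  stats::aggregate(stats::setNames(d[value], "m"),
                   by = list(session = d$session), FUN = mean)
}

# Do measured session means respect every injected strict inequality?
# Pairs whose injected values differ by no more than the recovery tolerance
# (`min_sep`) cannot be ordered reliably and are not compared.
ordering_respected <- function(measured, injected, min_sep) {
  stopifnot(identical(names(measured), names(injected)))
  ok <- TRUE
  nm <- names(injected)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (injected[i] - injected[j] > min_sep &&
          measured[i] <= measured[j]) ok <- FALSE
    }
  }
  ok
}
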