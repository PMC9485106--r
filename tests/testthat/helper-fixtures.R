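# Shared fixtures: small simulation configurations and independent oracles.

# Desk-scale simulation config: short ITIs and pre-session period, default
# tables restricted to the plan's sessions.
small_sim_config <- function(plan, fs = 500, seed = 1, ...) {
  keep <- plan$sessions$session
  gt <- default_gain_table()
  ct <- default_coupling_table()
  simulation_config(
    sampling_rate_hz = fs,
    iti_range_s = c(16, 18),
    pre_session_s = 20,
    cs_gain_table = gt[gt$session %in% keep, ],
    coupling_table = ct[ct$session %in% keep, ],
    seed = seed, ...)
}

one_session_plan <- function(n_plus = 3L, n_minus = 3L, name = "S1") {
  session_plan(data.frame(session = name, context = "A",
                          n_cs_plus = n_plus, n_cs_minus = n_minus,
                          us_paired = FALSE, stringsAsFactors = FALSE))
}

# --- independent oracles -------------------------------------------------

# Naive Welch PSD: split / demean / Hann / |DFT|^2 / average / scale,
# written with an explicit DFT double loop on the first segment sizes we use
# would be O(n^2); use R's fft but through an entirely separate scaling path.
naive_welch <- function(x, fs, n_segments = 16) {
  seg_len <- length(x) %/% n_segments
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  n_freq <- seg_len %/% 2 + 1
  psum <- numeric(n_freq)
  for (s in seq_len(n_segments)) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    seg <- seg - mean(seg)
    X <- fft(seg * w)
    psum <- psum + Mod(X[1:n_freq])^2
  }
  dens <- psum / n_segments / sum(w^2) / fs
  mult <- rep(2, n_freq); mult[1] <- 1
  if (seg_len %% 2 == 0) mult[n_freq] <- 1
  list(frequencies = (0:(n_freq - 1)) * fs / seg_len, density = dens * mult)
}

# Brute-force raw-moment cross-correlation coefficient (double loop).
brute_xcorr_coeff <- function(x, y, max_lag) {
  n <- length(x)
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(m) {
    if (m >= 0) {
      s <- 0
      for (k in 0:(n - m - 1)) s <- s + x[k + m + 1] * y[k + 1]
    } else {
      s <- 0
      for (k in 0:(n + m - 1)) s <- s + y[k - m + 1] * x[k + 1]
    }
    s
  }, numeric(1))
  r / sqrt(sum(x^2) * sum(y^2))
}

# Periodogram band-power fraction via direct DFT of the full signal.
band_power_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  half <- 2:(n %/% 2)          # skip DC; one-sided
  inband <- half[f[half] >= f_lo & f[half] <= f_hi]
  sum(X[inband]) / sum(X[half])
}

# Least-squares log-log periodogram slope over [f_min, f_max] Hz.
periodogram_slope <- function(x, fs, f_min = 1, f_max = 100) {
  n <- length(x)
  X <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  idx <- which(f >= f_min & f <= f_max & seq_along(f) <= n %/% 2)
  fit <- stats::lm(log10(X[idx]) ~ log10(f[idx]))
  unname(stats::coef(fit)[2])
}
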