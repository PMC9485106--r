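test_that("pink noise generator hits the requested RMS and spectral slope", {
  # exponent 0 is white noise; the generator scales to the exact RMS
  x <- generate_pink_noise(10000, exponent = 0, rms = 1, seed = 1)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-12)

  # 1/f noise: log-log periodogram slope near -1 (independent DFT oracle)
  y <- generate_pink_noise(2^14, exponent = 1, rms = 1, seed = 2)
  sl <- periodogram_slope(y, fs = 1000, f_min = 1, f_max = 100)
  expect_gt(sl, -1.3)
  expect_lt(sl, -0.7)

  # determinism and argument validation
  expect_identical(generate_pink_noise(500, 1, 2, seed = 7),
                   generate_pink_noise(500, 1, 2, seed = 7))
  expect_error(generate_pink_noise(0, 1, 1, 1), "positive")
  expect_error(generate_pink_noise(100, 1, 0, 1), "positive")
})

test_that("band oscillation is narrowband, scaled, and seeded", {
  b <- band_definition("theta", 4, 10)
  x <- generate_band_oscillation(b, 2^15, 1000, amplitude = 1, seed = 3)
  expect_gte(band_power_fraction(x, 1000, 4, 10), 0.90)
  expect_equal(sqrt(mean(x^2)), 1 / sqrt(2), tolerance = 1e-12)

  expect_identical(generate_band_oscillation(b, 4096, 1000, 1, seed = 5),
                   generate_band_oscillation(b, 4096, 1000, 1, seed = 5))
  x1 <- generate_band_oscillation(b, 4096, 1000, 1, seed = 5)
  x2 <- generate_band_oscillation(b, 4096, 1000, 1, seed = 6)
  expect_false(isTRUE(all.equal(x1, x2)))
  expect_equal(sqrt(mean(x1^2)), sqrt(mean(x2^2)), tolerance = 0.05)

  expect_identical(generate_band_oscillation(b, 1000, 1000, 0, seed = 1),
                   numeric(1000))
  expect_error(
    generate_band_oscillation(band_definition("bad", 100, 300), 1000, 500),
    "Nyquist")
})

test_that("simulated datasets are deterministic and structurally valid", {
  plan <- one_session_plan(3L, 3L)
  cfg <- small_sim_config(plan, fs = 250, seed = 9)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  simulate_dafc_dataset(cfg, plan, d1)
  simulate_dafc_dataset(cfg, plan, d2)
  for (f in c("events.tsv", "ground_truth.json", "signals/S1__PL.f32",
              "signals/S1__IL.f32")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }

  ds <- read_dataset(d1)
  ev <- ds$events
  # >= 15 s artifact-free baseline before every onset, ITIs in range
  expect_true(all(ev$onset_s >= 15))
  gaps <- diff(ev$onset_s) - 30
  expect_true(all(gaps >= 16 - 1e-9 & gaps <= 18 + 1e-9))
})

test_that("degenerate coupling makes the two theta channels identical", {
  plan <- one_session_plan(2L, 0L)
  ct <- data.frame(session = "S1", stimulus = "CS_PLUS", coupling = 1)
  cfg <- simulation_config(
    sampling_rate_hz = 250, noise_rms_uV = 0,
    band_components = c(theta = 60),
    cs_gain_table = default_gain_table()[0, ],
    coupling_table = ct, baseline_coupling = 1, coupling_lag_ms = 0,
    iti_range_s = c(16, 18), pre_session_s = 20, seed = 4)
  d <- file.path(tempdir(), "degen")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  simulate_dafc_dataset(cfg, plan, d)
  ds <- read_dataset(d)
  expect_equal(region_signal(ds$recordings$S1, "PL"),
               region_signal(ds$recordings$S1, "IL"), tolerance = 1e-6)
})

test_that("gain table referencing unknown sessions or regions is rejected", {
  plan <- one_session_plan(2L, 2L)
  bad_sess <- simulation_config(
    cs_gain_table = data.frame(region = "PL", session = "Nope",
                               stimulus = "CS_PLUS", band = "theta",
                               gain = 2),
    iti_range_s = c(16, 18), pre_session_s = 20)
  expect_error(simulate_dafc_dataset(bad_sess, plan, tempfile()),
               "unknown session 'Nope'")
  bad_reg <- simulation_config(
    cs_gain_table = data.frame(region = "HPC", session = "S1",
                               stimulus = "CS_PLUS", band = "theta",
                               gain = 2),
    iti_range_s = c(16, 18), pre_session_s = 20)
  expect_error(simulate_dafc_dataset(bad_reg, plan, tempfile()),
               "unknown region 'HPC'")
})

test_that("config validation enforces the documented invariants", {
  expect_error(simulation_config(iti_range_s = c(120, 90)), "low <= high")
  expect_error(simulation_config(baseline_coupling = 1.2), "\\[0, 1\\]")
  expect_error(
    simulation_config(coupling_table = data.frame(
      session = "Hab", stimulus = "CS_PLUS", coupling = -0.1)),
    "\\[0, 1\\]")
  expect_error(
    simulation_config(cs_gain_table = data.frame(
      region = "PL", session = "Hab", stimulus = "CS_PLUS", band = "theta",
      gain = -1)),
    ">= 0")
  expect_error(
    session_plan(data.frame(session = "A", context = "A", n_cs_plus = 1L,
                            n_cs_minus = 1L, us_paired = FALSE),
                 cs_duration_s = 10, n_pips = 20, pip_rate_hz = 1.5),
    "does not fit")
})

test_that("synthetic freezing tracks the injected PL theta gain", {
  # construct ground truth directly; no signal simulation needed
  mk_gt <- function(gain_acq) {
    list(trials = rbind(
      data.frame(session = "Hab", trial_index = 1:10, stimulus = "CS_PLUS",
                 region = "PL", band = "theta", gain = 1),
      data.frame(session = "ACQ", trial_index = 1:10, stimulus = "CS_PLUS",
                 region = "PL", band = "theta", gain = gain_acq)))
  }
  plan <- one_session_plan()
  fz <- generate_freezing(mk_gt(1), plan, seed = 1)
  expect_true(all(fz$freezing_pct >= 0 & fz$freezing_pct <= 100))
  expect_lt(mean(fz$freezing_pct), 15)  # all gains 1: low-fear baseline
  expect_identical(fz, generate_freezing(mk_gt(1), plan, seed = 1))

  # ACQ freezing exceeds Hab freezing in expectation (Monte-Carlo over seeds)
  diffs <- vapply(1:100, function(s) {
    f <- generate_freezing(mk_gt(1.5), plan, seed = s)
    mean(f$freezing_pct[f$session == "ACQ"]) -
      mean(f$freezing_pct[f$session == "Hab"])
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.95)
})
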