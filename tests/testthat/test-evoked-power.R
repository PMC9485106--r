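test_that("identical CS and pre-CS windows give a ratio of exactly 1", {
  fs <- 500
  t <- (0:(80 * fs - 1)) / fs
  x <- sin(2 * pi * 7 * t)              # periodic: windows identical
  expect_equal(evoked_power_ratio(x, fs, onset_s = 30, taps = NULL), 1,
               tolerance = 1e-9)
})

test_that("an amplitude step of g yields a power ratio of g^2", {
  fs <- 1000
  h <- design_bandpass(band_definition("theta", 4, 10), filter_spec(), fs)
  t <- (0:(120 * fs - 1)) / fs
  onset <- 60
  for (g in c(2, 3)) {
    amp <- ifelse(t < onset, 1, g)
    x <- amp * sin(2 * pi * 7 * t)
    r <- evoked_power_ratio(x, fs, onset_s = onset, taps = h)
    expect_equal(r, g^2, tolerance = 0.02)
  }
})

test_that("the ratio equals a brute-force periodogram computation", {
  fs <- 1000
  set.seed(21)
  x <- rnorm(60 * fs)
  x[(30 * fs + 1):(45 * fs)] <- x[(30 * fs + 1):(45 * fs)] +
    0.8 * sin(2 * pi * 7 * (1:(15 * fs)) / fs)
  ours <- evoked_power_ratio(x, fs, onset_s = 30, taps = NULL)
  i_on <- 30 * fs
  ref <- sum(naive_welch(x[(i_on + 1):(i_on + 15 * fs)], fs)$density) /
    sum(naive_welch(x[(i_on - 15 * fs + 1):i_on], fs)$density)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("ratios are invariant to rescaling the whole recording", {
  fs <- 500
  set.seed(5)
  x <- rnorm(60 * fs)
  r1 <- evoked_power_ratio(x, fs, onset_s = 30, taps = NULL)
  r2 <- evoked_power_ratio(137.5 * x, fs, onset_s = 30, taps = NULL)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("insufficient baseline or tail is a hard error", {
  fs <- 500
  x <- rnorm(40 * fs)
  expect_error(evoked_power_ratio(x, fs, onset_s = 10, taps = NULL),
               "baseline")
  expect_error(evoked_power_ratio(x, fs, onset_s = 30, taps = NULL),
               "after it")
})

test_that("block averaging reproduces hand-computed means and SEMs", {
  res <- data.frame(
    session = "ACQ", trial_index = c(1, 2, 3, 1, 2, 3),
    stimulus = rep(c("CS_PLUS", "CS_MINUS"), each = 3),
    region = "PL", band = "theta",
    ratio = c(2, 2, 2, 1, 2, 3))
  blocks <- data.frame(block = "ACQ", session = "ACQ", trial_index = 1:3)
  out <- block_average(res, blocks)
  plus <- out[out$stimulus == "CS_PLUS", ]
  minus <- out[out$stimulus == "CS_MINUS", ]
  expect_equal(plus$mean, 2)
  expect_equal(plus$sem, 0)
  expect_equal(minus$mean, 2)
  expect_equal(minus$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_identical(plus$n, 3L)
})

test_that("the default ACQ block selects trials 3-5", {
  blocks <- default_session_blocks()
  acq <- blocks[blocks$block == "ACQ", ]
  expect_identical(sort(acq$trial_index), 3:5)
  expect_identical(unique(acq$session), "ACQ")
  # Late EXT takes the last 3 trials of extinction day 2
  late <- blocks[blocks$block == "LateEXT", ]
  expect_identical(sort(late$trial_index), 10:12)
  expect_identical(unique(late$session), "EXT2")
})

test_that("empty blocks warn and report NA", {
  res <- data.frame(session = "ACQ", trial_index = 1, stimulus = "CS_PLUS",
                    region = "PL", band = "theta", ratio = 2)
  blocks <- data.frame(block = "Hab", session = "Hab", trial_index = 1:5)
  expect_warning(out <- block_average(res, blocks), "empty")
  expect_true(is.na(out$mean))
  expect_identical(out$n, 0L)
})
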