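test_that("self- and anti-correlation reach +/-1 at lag 0", {
  set.seed(3)
  x <- rnorm(256)
  r <- xcorr_coeff(x, x, 20)
  expect_equal(max(r$coefficients), 1, tolerance = 1e-12)
  expect_identical(r$lags[which.max(r$coefficients)], 0L)
  rn <- xcorr_coeff(x, -x, 20)
  expect_equal(min(rn$coefficients), -1, tolerance = 1e-12)
  expect_identical(rn$lags[which.min(rn$coefficients)], 0L)
})

test_that("the coefficient sequence matches the brute-force double loop", {
  # tiny hand-checkable case
  x <- c(1, 2, 3, 4); y <- c(4, 3, 2, 1)
  r <- xcorr_coeff(x, y, 3)
  expect_equal(r$coefficients, brute_xcorr_coeff(x, y, 3), tolerance = 1e-12)

  # random inputs, lags up to N-1
  set.seed(13)
  for (n in c(17, 64, 200)) {
    x <- rnorm(n); y <- rnorm(n)
    ml <- n - 1
    expect_equal(xcorr_coeff(x, y, ml)$coefficients,
                 brute_xcorr_coeff(x, y, ml), tolerance = 1e-10)
  }
})

test_that("cross-correlation is antisymmetric under argument swap", {
  set.seed(17)
  x <- rnorm(300); y <- rnorm(300)
  rxy <- xcorr_coeff(x, y, 50)$coefficients
  ryx <- xcorr_coeff(y, x, 50)$coefficients
  expect_equal(rxy, rev(ryx), tolerance = 1e-12)
})

test_that("coefficients are bounded by 1 for arbitrary inputs", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(20:500, 1)
    x <- rnorm(n) * 10^runif(1, -3, 3)
    y <- rnorm(n) * 10^runif(1, -3, 3)
    r <- xcorr_coeff(x, y, sample.int(n - 1, 1))
    expect_lte(max(abs(r$coefficients)), 1 + 1e-12)
  }
})

test_that("length mismatch and excessive lag are rejected", {
  expect_error(xcorr_coeff(rnorm(10), rnorm(11), 2), "length mismatch")
  expect_error(xcorr_coeff(rnorm(10), rnorm(10), 10), "below the sequence length")
})

test_that("peak extraction honours mode and tie-breaks", {
  res <- structure(list(lags = -2:2,
                        coefficients = c(0.1, 0.3, 0.2, 0.3, -0.9)),
                   class = "coupling_result")
  pk <- peak_coupling(res)                       # signed: max 0.3, tie -1 vs 1
  expect_equal(pk$peak_coeff, 0.3)
  expect_identical(pk$peak_lag, -1L)
  pka <- peak_coupling(res, mode = "absolute")   # |-0.9| wins, sign kept
  expect_equal(pka$peak_coeff, -0.9)
  expect_identical(pka$peak_lag, 2L)

  sym <- structure(list(lags = -2:2, coefficients = c(0.5, 0.1, 0, 0.1, 0.5)),
                   class = "coupling_result")
  expect_identical(peak_coupling(sym)$peak_lag, -2L)  # negative lag first
})

test_that("identical channels give per-trial peak 1 at lag 0", {
  fs <- 250
  set.seed(23)
  x <- rnorm(60 * fs)
  rec <- recording(list(PL = x, IL = x), fs, session = "S1")
  events <- data.frame(session = "S1", trial_index = 1L,
                       stimulus = "CS_PLUS", onset_s = 20)
  tc <- trial_coupling(rec, events, taps = NULL, max_lag_ms = 100)
  expect_equal(tc$peak_coeff, 1, tolerance = 1e-12)
  expect_equal(tc$peak_lag_ms, 0)
})

test_that("uncoupled channels stay below a trial-shuffled null", {
  fs <- 250
  b <- band_definition("theta", 4, 10)
  n <- 40 * fs
  mk <- function(seed) generate_band_oscillation(b, n, fs, 1, seed)
  # 20 independent trial pairs -> observed mean peak
  peaks <- vapply(1:20, function(i) {
    r <- xcorr_coeff(mk(i), mk(100 + i), round(0.5 * fs), fs)
    peak_coupling(r)$peak_coeff
  }, numeric(1))
  # null: mean peak across shuffled (mismatched) pairings
  null_means <- vapply(1:40, function(s) {
    set.seed(s)
    perm <- sample(1:20)
    mean(vapply(1:20, function(i) {
      r <- xcorr_coeff(mk(i), mk(100 + perm[i]), round(0.5 * fs), fs)
      peak_coupling(r)$peak_coeff
    }, numeric(1)))
  }, numeric(1))
  expect_lte(mean(peaks), stats::quantile(null_means, 0.95) + 0.02)
})

test_that("session coupling averages match hand computations", {
  res <- data.frame(session = "EXT_recall", trial_index = c(1, 2),
                    stimulus = "CS_PLUS", peak_coeff = c(0.5, 0.5),
                    peak_lag_ms = 0)
  blocks <- data.frame(block = "EXTrecall", session = "EXT_recall",
                       trial_index = 1:2)
  out <- session_coupling_average(res, blocks)
  out <- out[out$stimulus == "CS_PLUS", ]
  expect_equal(out$mean, 0.5)
  expect_equal(out$sem, 0)

  res2 <- data.frame(session = "EXT_recall", trial_index = 1:3,
                     stimulus = "CS_PLUS", peak_coeff = c(0.2, 0.4, 0.6),
                     peak_lag_ms = 0)
  blocks2 <- data.frame(block = "EXTrecall", session = "EXT_recall",
                        trial_index = 1:3)
  out2 <- session_coupling_average(res2, blocks2)
  expect_equal(out2$mean[out2$stimulus == "CS_PLUS"], 0.4)
  expect_equal(out2$sem[out2$stimulus == "CS_PLUS"], 0.2 / sqrt(3),
               tolerance = 1e-9)
})
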