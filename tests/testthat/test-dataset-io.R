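make_small_dataset <- function(dir, seed = 2) {
  plan <- one_session_plan(2L, 2L)
  cfg <- small_sim_config(plan, fs = 250, seed = seed)
  simulate_dafc_dataset(cfg, plan, dir)
  dir
}

test_that("datasets round-trip losslessly through write -> read -> write", {
  d1 <- file.path(tempdir(), "rt1"); d2 <- file.path(tempdir(), "rt2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  make_small_dataset(d1)
  ds <- read_dataset(d1)

  dir.create(file.path(d2, "signals"), recursive = TRUE)
  for (sess in names(ds$recordings)) {
    rec <- ds$recordings[[sess]]
    for (ch in names(rec$samples)) {
      con <- file(file.path(d2, "signals", sprintf("%s__%s.f32", sess, ch)), "wb")
      writeBin(rec$samples[[ch]], con, size = 4, endian = "little")
      close(con)
    }
  }
  for (f in list.files(file.path(d1, "signals"))) {
    p1 <- file.path(d1, "signals", f); p2 <- file.path(d2, "signals", f)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)), label = f)
  }
})

test_that("validation errors carry file and row provenance", {
  d <- file.path(tempdir(), "bad1")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  make_small_dataset(d)

  # onset with only 5 s of baseline
  ev_path <- file.path(d, "events.tsv")
  ev <- read.delim(ev_path, colClasses = "character")
  ev$onset_s[1] <- "5.0"
  ev$onset_s[2] <- "40.0"; ev$onset_s[3] <- "80.0"; ev$onset_s[4] <- "120.0"
  write.table(ev, ev_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(d), "row 1.*baseline|baseline.*row 1")
})

test_that("truncated signal files and non-monotone onsets are caught", {
  d <- file.path(tempdir(), "bad2")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  make_small_dataset(d)

  # chop bytes so channel lengths disagree
  p <- file.path(d, "signals", "S1__PL.f32")
  raw <- readBin(p, "raw", file.size(p))
  writeBin(raw[1:(length(raw) - 400)], p)
  expect_error(read_dataset(d), "length mismatch")

  # restore, then scramble onset order
  writeBin(raw, p)
  ev_path <- file.path(d, "events.tsv")
  ev <- read.delim(ev_path, colClasses = "character")
  ev$onset_s <- rev(ev$onset_s)
  write.table(ev, ev_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(d), "non-increasing")
})

test_that("missing files are reported by name", {
  d <- file.path(tempdir(), "bad3")
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  make_small_dataset(d)
  file.remove(file.path(d, "signals", "S1__IL.f32"))
  expect_error(read_dataset(d), "S1__IL\\.f32")
  expect_error(read_dataset(file.path(tempdir(), "no-such-dir")),
               "dataset\\.json")
})

test_that("write_results emits well-formed, deterministic CSVs", {
  out1 <- file.path(tempdir(), "res1"); out2 <- file.path(tempdir(), "res2")
  on.exit(unlink(c(out1, out2), recursive = TRUE), add = TRUE)
  tabs <- list(
    evoked_power = data.frame(session = "S1", region = "PL", band = "theta",
                              stimulus = "CS_PLUS", trial_index = 1L,
                              ratio = 2.25),
    coupling = data.frame(session = "S1", stimulus = "CS_PLUS",
                          trial_index = 1L, peak_coeff = 0.52,
                          peak_lag_ms = 24),
    session_summary = data.frame(block = "ACQ", session = "S1",
                                 region_or_pair = "PL", band = "theta",
                                 stimulus = "CS_PLUS",
                                 measure = "evoked_power_ratio",
                                 n = 1L, mean = 2.25, sem = NA_real_))
  write_results(tabs, out1)
  write_results(tabs, out2)
  for (f in c("evoked_power.csv", "coupling.csv", "session_summary.csv")) {
    expect_true(file.exists(file.path(out1, f)))
    tab <- read.csv(file.path(out1, f))
    expect_identical(nrow(tab), 1L)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  ep <- read.csv(file.path(out1, "evoked_power.csv"))
  expect_true(is.finite(ep$ratio) && ep$ratio > 0)

  expect_warning(write_results(list(), file.path(tempdir(), "resempty")),
                 "nothing done")
})
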