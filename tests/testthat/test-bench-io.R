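# Benchmark container I/O and the synthetic SEP fixture.

test_that("RAT containers round-trip bit-identically through MAT-files", {
  rec <- generate_synthetic_sep(n_trials = 4, seed = 1)
  path <- tempfile(fileext = ".mat")
  write_rat_mat(rec, path)
  r2 <- read_rat_mat(path)
  expect_identical(r2$data, rec$data)
  expect_equal(as.numeric(r2$times), as.numeric(rec$times))
  expect_equal(r2$fs, rec$fs)
  expect_identical(r2$dimord, rec$dimord)
  # the file holds exactly the documented field set
  vars <- read_mat(path)
  expect_named(vars, "RAT")
  expect_setequal(names(vars$RAT), c("data", "dimord", "times", "Fs"))
})

test_that("malformed containers are rejected with descriptive errors", {
  path <- tempfile(fileext = ".mat")
  write_mat(list(OTHER = list(a = 1)), path)
  expect_error(read_rat_mat(path), "RAT")
  write_mat(list(RAT = list(data = array(0, c(4, 2, 1)), Fs = 100)), path)
  expect_error(read_rat_mat(path), "times")
  write_mat(list(RAT = list(data = array(0, c(4, 2, 1)),
                            dimord = "time_chan_trial",
                            times = c(0, 10, 20), Fs = 100)), path)
  expect_error(read_rat_mat(path), "does not match")
  # an empty-trial recording cannot be constructed or written
  expect_error(rat_recording(array(0, c(4, 2, 0)), fs = 100,
                             times = c(0, 10, 20, 30)), "finite|trials")
  # v7.3 files are HDF5 and refused with guidance
  fake <- tempfile(fileext = ".mat")
  con <- file(fake, "wb")
  writeBin(c(charToRaw(sprintf("MATLAB 7.3 MAT-file%s", strrep(" ", 200)))),
           con)
  close(con)
  expect_error(read_mat(fake), "7.3")
})

test_that("MAT-files interoperate with an independent reader/writer", {
  has_scipy <- nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import scipy.io")),
            stdout = FALSE, stderr = FALSE) == 0
  expect_true(has_scipy)   # part of the supported toolchain
  rec <- generate_synthetic_sep(n_trials = 3, seed = 2)
  ours <- tempfile(fileext = ".mat")
  theirs <- tempfile(fileext = ".mat")
  write_rat_mat(rec, ours)
  script <- sprintf(paste0(
    "import scipy.io as sio\n",
    "m = sio.loadmat('%s')\n",
    "r = m['RAT']\n",
    "d = r['data'][0,0]\n",
    "assert d.shape == (601, 15, 3), d.shape\n",
    "assert abs(float(r['Fs'][0,0].squeeze()) - 2000.0) < 1e-9\n",
    "sio.savemat('%s', {'RAT': {'data': d, 'dimord': 'time_chan_trial',\n",
    "  'times': r['times'][0,0].squeeze(), 'Fs': 2000.0}},\n",
    "  do_compression=True)\n"), ours, theirs)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  expect_equal(system2("python", sf, stdout = FALSE, stderr = FALSE), 0)
  # read back the compressed file written by the independent implementation
  r3 <- read_rat_mat(theirs)
  expect_identical(r3$data, rec$data)
  expect_equal(as.numeric(r3$times), as.numeric(rec$times))
})

test_that("the synthetic SEP fixture has the documented layout", {
  rec <- generate_synthetic_sep(n_trials = 65, seed = 3)
  d <- dim(rec$data)
  expect_equal(d, c(601L, 15L, 65L))
  expect_equal(rec$fs, 2000)
  expect_equal(range(rec$times), c(-100, 200))
  expect_identical(generate_synthetic_sep(n_trials = 5, seed = 4)$data,
                   generate_synthetic_sep(n_trials = 5, seed = 4)$data)
  expect_error(generate_synthetic_sep(onset_ms = 500), "epoch")
  expect_error(generate_synthetic_sep(driver_channel = 16), "1..15")
})

test_that("the driver leads its targets by the construction lag", {
  rec <- generate_synthetic_sep(n_trials = 10, seed = 5)
  win <- which(rec$times >= 0 & rec$times <= 60)
  lags <- vapply(c(10, 14), function(tc) {
    cc <- ccf(rec$data[win, 12, 1], rec$data[win, tc, 1], lag.max = 10,
              plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }, numeric(1))
  # cross-correlation peaks where the driver past predicts the target
  expect_true(all(lags < 0))
  expect_true(all(abs(lags + 4) <= 2))     # 2 ms at 2000 Hz = 4 samples
})

test_that("gamma-band outflow ranks the driver first across seeds", {
  hits <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    rec <- generate_synthetic_sep(n_trials = 30, seed = 200 + s)
    out <- channel_outflow(rec, window = c(5, 50), band = c(40, 100))
    if (which.max(out) == 12) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
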