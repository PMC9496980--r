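test_that("recording construction validates shape, names and finiteness", {
  d <- matrix(rnorm(19 * 2000), 19)
  rec <- eeg_recording(d, 1000, montage_1020()$label)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(duration_s(rec), 2)
  expect_identical(rec$data[5, ], d[5, ], ignore_attr = TRUE)

  d2 <- d; d2[7, 100] <- NaN
  expect_error(eeg_recording(d2, 1000, montage_1020()$label), "F8")
  expect_error(eeg_recording(d, 1000, rep("Cz", 19)), "duplicate")
  expect_error(eeg_recording(d[1, , drop = FALSE], 1000), "2 channels")
  expect_error(eeg_recording(d[, 1:500], 1000, montage_1020()$label),
               "shorter than 1 s")

  rec2 <- eeg_recording(matrix(rnorm(4000), 2), 1000, c("src", "res"))
  expect_equal(nrow(rec2$data), 2)
})

test_that("constraint windows follow the 4 ms pre-apex convention", {
  m <- spike_markers(1.0)
  expect_equal(constraint_windows(m, 1000, 2000), list(c(996L, 1000L)))
  # boundary clip at recording start
  m0 <- spike_markers(0.004)
  expect_equal(constraint_windows(m0, 1000, 2000), list(c(0L, 4L)))
  # reduced sampling rate: 4 ms is a single sample at 250 Hz
  expect_equal(constraint_windows(m, 250, 500), list(c(249L, 250L)))
  # symmetric window includes samples after the apex
  ms <- spike_markers(1.0, window_before_s = 0.004, window_after_s = 0.002)
  expect_equal(constraint_windows(ms, 1000, 2000), list(c(996L, 1002L)))
})

test_that("marker validation rejects disorder and empty windows", {
  expect_error(spike_markers(c(1, 1)), "strictly increasing")
  expect_error(spike_markers(c(2, 1)), "strictly increasing")
  expect_error(spike_markers(1, window_before_s = 0, window_after_s = 0),
               "positive total")
  expect_error(constraint_windows(spike_markers(5), 1000, 2000), "beyond")
  # marker so early that the whole window clips away
  m <- spike_markers(0.0001)
  expect_error(constraint_windows(m, 100, 1000), "empty")
})

test_that("constraint windows are translation-equivariant", {
  set.seed(42)
  for (fs in c(250, 1000)) {
    t <- sort(runif(10, 1, 50))
    delta <- 817 / fs                 # whole-sample shift
    w0 <- constraint_windows(spike_markers(t), fs, 100 * fs)
    w1 <- constraint_windows(spike_markers(t + delta), fs, 100 * fs)
    shift <- 817
    for (i in seq_along(w0))
      expect_equal(w1[[i]], w0[[i]] + as.integer(shift))
  }
})

test_that("marker files and interchange CSV round-trip", {
  m <- spike_markers(c(0.5, 1.25, 7.008), window_after_s = 0.002)
  f <- withr::local_tempfile(fileext = ".txt")
  write_markers(m, f)
  m2 <- read_markers(f, window_before_s = 0.004, window_after_s = 0.002)
  expect_equal(m2$times_s, m$times_s)

  set.seed(8)
  rec <- eeg_recording(matrix(rnorm(3 * 1500, sd = 40), 3), 500,
                       c("C3", "Cz", "C4"), reference = "FCz",
                       condition_tag = "pre_real")
  g <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(rec, g)
  rec2 <- read_eeg(g)
  expect_equal(rec2$fs, rec$fs)
  expect_identical(rec2$channel_names, rec$channel_names)
  expect_identical(rec2$reference, "FCz")
  expect_identical(rec2$condition_tag, "pre_real")
  expect_equal(rec2$data, rec$data, tolerance = 1e-8)

  expect_error(read_eeg(file.path(tempdir(), "nope.csv")), "not found")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3"), bad)
  expect_error(read_eeg(bad), "header")
})
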