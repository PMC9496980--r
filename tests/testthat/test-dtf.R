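test_that("decimation preserves DC and passband tones", {
  expect_equal(downsample(rep(2.5, 4000), 1000, 250), rep(2.5, 1000),
               tolerance = 1e-6)
  # 10 Hz tone survives 1000 -> 250 Hz with < 1% amplitude error
  t <- seq(0, 60, by = 1e-3)[-1]
  x <- sin(2 * pi * 10 * t)
  y <- downsample(x, 1000, 250)
  expect_length(y, 15000)
  mid <- y[2000:13000]
  amp <- (max(mid) - min(mid)) / 2
  expect_equal(amp, 1, tolerance = 0.01)
  # frequency content: dominant DFT bin still at 10 Hz
  sp <- Mod(fft(mid - mean(mid)))[1:(length(mid) / 2)]
  f_peak <- (which.max(sp) - 1) * 250 / length(mid)
  expect_equal(f_peak, 10, tolerance = 0.05)
  expect_error(downsample(x, 1000, 300), "integer multiple")
  expect_length(downsample(rnorm(60000), 1000, 250), 15000)
})

test_that("segmentation counts and centers are right", {
  x <- matrix(rnorm(2 * 250 * 900), 2)      # 15 min at 250 Hz
  segs <- segment(x, 250, 20)
  expect_length(segs, 45)
  expect_true(all(vapply(segs, ncol, integer(1)) == 5000))
  expect_lt(max(abs(vapply(segs, rowMeans, numeric(2)))), 1e-10)
  expect_length(segment(matrix(rnorm(2 * 250 * 59), 2), 250, 20), 2)
  expect_error(segment(matrix(rnorm(2 * 100), 2), 250, 20), "one")
})

test_that("MVAR least squares recovers known coefficients", {
  g <- gen_coupled_ar(5000, 250, 20, 0.5, seed = 31)
  m <- fit_mvar(g$x, p_max = 20, fs = 250)
  expect_s3_class(m, "mvar")
  expect_true(m$stable)
  expect_true(!is.unsorted(m$criterion_trace$order))
  expect_equal(m$order_p, 2)
  expect_lt(max(abs(m$coeffs[[1]] - g$A[[1]])), 0.05)
  expect_lt(max(abs(m$coeffs[[2]] - g$A[[2]])), 0.05)
})

test_that("independent noise fits a near-null model", {
  set.seed(32)
  x <- rbind(rnorm(5000), rnorm(5000))
  m <- fit_mvar(x, p_max = 20, fs = 250)
  expect_lte(m$order_p, 3)
  expect_lt(max(abs(unlist(m$coeffs))), 0.05)
  m2 <- fit_mvar(x, p_max = 20, fs = 250)
  expect_identical(m$coeffs, m2$coeffs)    # deterministic
})

test_that("identical signals are rejected as singular", {
  set.seed(33)
  s <- rnorm(5000)
  expect_error(fit_mvar(rbind(s, s), p_max = 10, fs = 250), "singular")
})

test_that("DTF of a diagonal system has zero cross-flow and unit rows", {
  g1 <- gen_coupled_ar(5000, 250, 15, 0, seed = 34)   # strength 0: diagonal
  # build an exactly diagonal model from the true coefficients
  m <- structure(list(order_p = 2,
                      coeffs = list(diag(diag(g1$A[[1]])), diag(diag(g1$A[[2]]))),
                      noise_cov = diag(2), fs = 250, stable = TRUE,
                      spectral_radius = 0.95), class = "mvar")
  sp <- dtf_spectrum(m)
  expect_true(all(abs(sp$gamma2[1, 2, ]) < 1e-12))
  expect_true(all(abs(sp$gamma2[2, 1, ]) < 1e-12))
  expect_true(all(abs(sp$gamma2[1, 1, ] - 1) < 1e-12))
  rs <- apply(sp$gamma2, c(1, 3), sum)
  expect_lt(max(abs(rs - 1)), 1e-10)
})

test_that("unidirectional coupling is recovered in the right direction", {
  g <- gen_coupled_ar(5000, 250, 20, 0.5, seed = 35)
  m <- fit_mvar(g$x, 20, 250)
  sp <- dtf_spectrum(m, labels = c("x1", "x2"))
  fwd <- max(sp$gamma2[2, 1, ])
  rev <- max(sp$gamma2[1, 2, ])
  expect_gte(fwd, 0.5)
  expect_lte(rev, 0.1)
  pk <- sp$freqs[which.max(sp$gamma2[2, 1, ])]
  expect_lt(abs(pk - 20), 2)
  # swapping the coupled pair flips the dominant direction
  gr <- gen_coupled_ar(5000, 250, 20, 0.5, seed = 35, reverse = TRUE)
  spr <- dtf_spectrum(fit_mvar(gr$x, 20, 250), labels = c("x1", "x2"))
  expect_gt(max(spr$gamma2[1, 2, ]), max(spr$gamma2[2, 1, ]))
})

test_that("gamma2 is scale-invariant and rows stay normalized end to end", {
  set.seed(36)
  g <- gen_coupled_ar(250 * 60, 250, 12, 0.4, seed = 36)
  d1 <- dtf(g$x[1, ], g$x[2, ], fs = 250, seg_s = 20, p_max = 10)
  d2 <- dtf(1000 * g$x[1, ], 1e-3 * g$x[2, ], fs = 250, seg_s = 20, p_max = 10)
  expect_equal(d1$gamma2, d2$gamma2, tolerance = 1e-8)
  rs <- apply(d1$gamma2, c(1, 3), sum)
  expect_lt(max(abs(rs - 1)), 1e-10)
  for (ps in d1$per_segment) {
    rs <- apply(ps, c(1, 3), sum)
    expect_lt(max(abs(rs - 1)), 1e-10)
  }
  expect_true(all(d1$gamma2 >= 0 & d1$gamma2 <= 1))
  # band summary covers the named bands for both directions
  expect_setequal(unique(d1$band_summary$band), names(eeg_bands()))
})

test_that("null off-diagonal inflow stays small across seeded replicates", {
  set.seed(37)
  q <- replicate(50, {
    x <- rbind(rnorm(5000), rnorm(5000))
    sp <- dtf_spectrum(fit_mvar(x, p_max = 5, fs = 250))
    max(sp$gamma2[1, 2, ], sp$gamma2[2, 1, ])
  })
  expect_lt(quantile(q, 0.95), 0.15)
})
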