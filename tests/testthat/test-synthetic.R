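test_that("spike-and-wave source generation is calibrated and deterministic", {
  cfg <- sw_config(duration_s = 120, seed = 41)
  sw1 <- local({ set.seed(cfg$seed); gen_sw_source(cfg) })
  sw2 <- local({ set.seed(cfg$seed); gen_sw_source(cfg) })
  expect_identical(sw1, sw2)                         # pure function of seed
  # ~ rate * duration events, all inside the recording
  expect_gt(length(sw1$times_s), 0.8 * 0.5 * 120)
  expect_true(all(sw1$times_s > 0 & sw1$times_s < 120))
  expect_true(!is.unsorted(sw1$times_s, strictly = TRUE))
  expect_equal(var(sw1$s), 1, tolerance = 1e-9)
  # apex amplitude >= 3 x baseline s.d. (in normalized units the apex values
  # must stand out at least 3x the off-event s.d.)
  apex_idx <- round(sw1$times_s * cfg$fs)
  off <- sw1$s[-unlist(lapply(apex_idx, function(i) (i - 500):(i + 500)))]
  expect_gt(min(abs(sw1$s[apex_idx])), 3 * sd(off))
  # on a near-noiseless source the apexes are exact peaks
  clean <- local({
    set.seed(7)
    gen_sw_source(sw_config(duration_s = 60, seed = 7, baseline_sd = 1e-9))
  })
  for (tt in clean$times_s) {
    i <- round(tt * 1000)
    expect_identical(which.max(clean$s[(i - 20):(i + 20)]), 21L)
  }
})

test_that("mixture embeds the source through the focus topography", {
  mix <- gen_mixture(sw_config(duration_s = 30, seed = 42))
  rec <- mix$recording
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$data), 19)
  expect_identical(rec$channel_names, montage_1020()$label)
  # spike-locked average is largest at the focus channel
  apex <- round(mix$markers$times_s * rec$fs)
  sl <- vapply(seq_len(19), function(ch) {
    mean(abs(rec$data[ch, apex] - mean(rec$data[ch, ])))
  }, numeric(1))
  expect_identical(rec$channel_names[which.max(sl)], "T4")
  # truth bundle suffices for recovery metrics
  expect_named(mix$truth, c("a_true", "s_true", "b_alpha", "g_alpha",
                            "b_bb", "g_bb", "noise_amp"))
  expect_length(mix$truth$a_true, 19)
  expect_identical(which.max(mix$truth$a_true), which(montage_1020()$label == "T4"))
})

test_that("noise-free two-source mixture has rank 2", {
  cfg <- sw_config(duration_s = 30, seed = 43, noise_amp = 0,
                   background_alpha_amp = 0)
  mix <- gen_mixture(cfg)
  sv <- svd(mix$recording$data - rowMeans(mix$recording$data))$d
  expect_gt(sv[2], 1e-6 * sv[1])
  expect_lt(sv[3], 1e-8 * sv[1])
})

test_that("coupled AR pair behaves as specified", {
  g <- gen_coupled_ar(4000, 250, 20, 0.5, seed = 44)
  expect_equal(dim(g$x), c(2, 4000))
  expect_length(g$A, 2)
  # resonance of the driver near 20 Hz
  sp <- Mod(fft(g$x[1, ]))[2:2000]
  f <- (2:2000 - 1) * 250 / 4000
  expect_lt(abs(f[which.max(sp)] - 20), 2)
  # zero coupling: second row of A2 is zero
  g0 <- gen_coupled_ar(1000, 250, 20, 0, seed = 44)
  expect_identical(g0$A[[2]][2, 1], 0)
  expect_identical(gen_coupled_ar(1000, 250, 20, 0.5, seed = 44)$x,
                   gen_coupled_ar(1000, 250, 20, 0.5, seed = 44)$x)
})

test_that("known-dimension oracles carry their analytic tags", {
  expect_identical(gen_known_fd("line", n = 1000)$dimension, 1)
  expect_identical(gen_known_fd("white", n = 1000, seed = 4)$dimension, 2)
  expect_identical(gen_known_fd("weierstrass", H = 0.3, n = 2000)$dimension, 1.7)
  expect_error(gen_known_fd("weierstrass", H = 1.2), "H")
  expect_error(gen_known_fd("weierstrass", gamma = 1.1), "gamma")
})

test_that("four-condition set shares topography and thins post-real spikes", {
  cfg <- sw_config(duration_s = 60, seed = 45)
  four <- gen_four_conditions(cfg)
  expect_named(four, c("pre_real", "post_real", "pre_sham", "post_sham"))
  n_pre <- length(four$pre_real$markers$times_s)
  n_post <- length(four$post_real$markers$times_s)
  expect_equal(n_post / n_pre, 0.1, tolerance = 0.5)
  for (cond in names(four))
    expect_equal(four[[cond]]$truth$a_true / max(four[[cond]]$truth$a_true),
                 four$pre_real$truth$a_true / max(four$pre_real$truth$a_true),
                 tolerance = 1e-9)
})
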