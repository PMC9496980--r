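test_that("whitening produces identity covariance and honors rank", {
  set.seed(1)
  # diagonal-covariance toy
  d <- rbind(rnorm(5000, sd = 2), rnorm(5000, sd = 1))
  rec <- eeg_recording(d, 1000, c("C3", "C4"))
  wh <- whiten(rec)
  expect_equal(cov(t(wh$z)), diag(2), tolerance = 1e-8)
  # dewhitener inverts on the retained subspace
  expect_equal(wh$model$dewhitener %*% wh$model$whitener %*% (d - rowMeans(d)),
               d - rowMeans(d), tolerance = 1e-8)

  # full-rank 19-channel mixture
  mix <- test_mixture(seed = 2, duration_s = 30)
  wh19 <- whiten(mix$recording)
  expect_equal(cov(t(wh19$z)), diag(nrow(wh19$z)), tolerance = 1e-8)

  # rank-deficient data: 3 channels, rank 2
  s <- matrix(rnorm(2 * 3000), 2)
  d3 <- rbind(s[1, ], s[2, ], s[1, ] + s[2, ])
  rec3 <- eeg_recording(d3, 1000, c("a1", "a2", "a3")) |> suppressWarnings()
  expect_error(whiten(rec3, rank = 3), "smaller")
  expect_equal(nrow(whiten(rec3)$z), 2)   # auto rank
})

test_that("negentropy approximation matches its definition and symmetries", {
  set.seed(3)
  # Gaussian limit: J near 0
  y <- rnorm(2e5); y <- (y - mean(y)) / sd(y)
  expect_lt(negentropy_J(y), 1e-4)

  # Laplace sample against a direct Monte-Carlo evaluation of the contrast
  u <- runif(1e5) - 0.5
  lap <- -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)   # unit-variance Laplace
  lap <- (lap - mean(lap)) / sd(lap)
  J <- negentropy_J(lap)
  expect_gt(J, 0)
  gauss_const <- integrate(function(u) log(cosh(u)) * dnorm(u), -15, 15,
                           rel.tol = 1e-12)$value
  J_mc <- (mean(log(cosh(lap))) - gauss_const)^2
  expect_equal(J, J_mc, tolerance = 1e-6)

  expect_identical(negentropy_J(-lap), negentropy_J(lap))
  expect_error(negentropy_J(2 * lap), "unit-variance")
})

test_that("constraint R is the mean window power", {
  s <- c(0, 0, 3, 0, 0, 0, 4, 0)
  w <- list(c(2L, 3L), c(6L, 7L))
  expect_equal(constraint_R(s, w), (9 + 16) / 2)
  expect_equal(constraint_R(s, w, aggregate = "max"), 16)
  expect_equal(constraint_R(rep(1, 8), w), 1)
  expect_equal(constraint_R(c(1, 1, 0, 1, 1, 1, 0, 1), w), 0)
  expect_error(constraint_R(s, list()), "empty")
})

test_that("constrained extraction recovers the embedded source", {
  mix <- test_mixture(seed = 11)
  fit <- fss(mix$recording, mix$markers, light_fss_cfg(seed = 5))
  expect_s3_class(fit, "fss")
  expect_equal(var(fit$s), 1, tolerance = 1e-6)
  expect_gt(abs(cor(fit$a, mix$truth$a_true)), 0.95)
  expect_gt(cor(fit$s, mix$truth$s_true), 0.9)
  # sign convention: spike-locked mean nonnegative
  idx <- unlist(lapply(fit$windows, function(w) (w[1] + 1):w[2]))
  expect_gte(mean(fit$s[idx]), 0)
  # best-so-far cost is non-decreasing along the anneal
  expect_true(all(diff(fit$cost_trace$best_cost) >= 0))
  # s really is w' (centered data)
  xc <- mix$recording$data - rowMeans(mix$recording$data)
  expect_equal(drop(crossprod(fit$w, xc)), fit$s, tolerance = 1e-8)
})

test_that("extraction is deterministic and scale-equivariant", {
  mix <- test_mixture(seed = 12, duration_s = 20)
  cfg <- light_fss_cfg(seed = 9, t_min = 2)
  f1 <- fss(mix$recording, mix$markers, cfg)
  f2 <- fss(mix$recording, mix$markers, cfg)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$s, f2$s)
  expect_identical(f1$a, f2$a)

  # power-of-two gain keeps the float arithmetic, and hence the stochastic
  # search trajectory, exactly reproducible
  rec_scaled <- eeg_recording(4 * mix$recording$data, mix$recording$fs,
                              mix$recording$channel_names)
  f3 <- fss(rec_scaled, mix$markers, cfg)
  expect_equal(f3$s, f1$s, tolerance = 1e-8)
  expect_equal(f3$a, 4 * f1$a, tolerance = 1e-8)
})

test_that("few markers warn instead of failing", {
  mix <- test_mixture(seed = 13, duration_s = 20)
  m3 <- spike_markers(mix$markers$times_s[1:3])
  expect_warning(fss(mix$recording, m3, light_fss_cfg(seed = 1, t_min = 5)),
                 "poorly estimated")
})

test_that("rank-1 residual removes the source and only the source", {
  mix <- test_mixture(seed = 14)
  fit <- fss(mix$recording, mix$markers, light_fss_cfg(seed = 6))
  rr <- residuals(fit)
  # every residual channel uncorrelated with the extracted source
  cors <- apply(rr$data, 1, function(ch) cor(ch, fit$s))
  expect_lt(max(abs(cors)), 1e-6)
  # channel means preserved
  expect_equal(rowMeans(rr$data), rowMeans(mix$recording$data),
               tolerance = 1e-9)
  # variance accounting: removal cannot increase channel variance
  v0 <- apply(mix$recording$data, 1, var)
  v1 <- apply(rr$data, 1, var)
  expect_true(all(v1 <= v0 * (1 + 1e-12)))
  # idempotence: re-estimated topography on the residual is ~ 0
  xc <- rr$data - rowMeans(rr$data)
  a2 <- drop(xc %*% fit$s) / (length(fit$s) - 1)
  expect_lt(max(abs(a2)), 1e-8 * max(abs(fit$a)))
  rr2 <- residuals(fit, rr)
  expect_equal(rr2$data, rr$data, tolerance = 1e-8)
})

test_that("exact rank-1 data cancels to its channel means", {
  set.seed(15)
  n <- 4000
  s <- rnorm(n); s <- (s - mean(s)) / sd(s)
  a <- c(2, -1, 0.5)
  mu <- c(10, -5, 0)
  base <- outer(a, s) + mu
  # tiny full-rank jitter so construction/whitening are well-posed
  rec <- suppressWarnings(eeg_recording(base, 1000, c("x1", "x2", "x3")))
  fit <- list(s = s, recording = rec,
              w = setNames(rep(0, 3), c("x1", "x2", "x3")))
  class(fit) <- "fss"
  rr <- suppressWarnings(residuals(fit))   # synthetic channel labels
  expect_equal(rr$data, matrix(mu, 3, n), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("second extraction finds the background network", {
  mix <- test_mixture(seed = 16, duration_s = 60)
  pair <- fss_pair(mix$recording, mix$markers, light_fss_cfg(seed = 21))
  expect_identical(pair$fs_rp$label, "FS_rp")
  # FS_rp aligns with one of the generated background topographies
  c_alpha <- abs(cor(pair$fs_rp$a, mix$truth$b_alpha))
  c_bb <- abs(cor(pair$fs_rp$a, mix$truth$b_bb))
  expect_gt(max(c_alpha, c_bb), 0.8)
  # all spike-locked power sits in FS_Epi by construction
  expect_lte(pair$fs_rp$constraint_value, pair$fs_epi$constraint_value)
  # time courses of the two networks are near-orthogonal
  expect_lt(abs(cor(pair$fs_epi$s, pair$fs_rp$s)), 0.2)
})

test_that("projection applies the fitted filter to new recordings", {
  mix <- test_mixture(seed = 17, duration_s = 20)
  fit <- fss(mix$recording, mix$markers, light_fss_cfg(seed = 2, t_min = 5))
  expect_identical(predict(fit), fit$s)
  # same montage, permuted channel order: projection must be invariant
  perm <- sample(length(fit$w))
  rec_p <- eeg_recording(mix$recording$data[perm, ], mix$recording$fs,
                         mix$recording$channel_names[perm])
  expect_equal(predict(fit, rec_p), fit$s, tolerance = 1e-10)
  rec_other <- eeg_recording(matrix(rnorm(4000), 2), 1000, c("C3", "C4"))
  expect_error(predict(fit, rec_other), "channel sets")
})
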