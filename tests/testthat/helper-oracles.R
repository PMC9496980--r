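# Independent oracles used across the suite. These deliberately share no code
# with the package implementations they check.

# Higuchi curve-length dimension, literal triple loop over (k, m, i)
naive_higuchi <- function(x, kmax) {
  N <- length(x)
  Lk <- numeric(kmax)
  for (k in 1:kmax) {
    Lm <- numeric(k)
    for (m in 1:k) {
      M <- floor((N - m) / k)
      s <- 0
      for (i in 1:M) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm[m] <- s * (N - 1) / (M * k) / k
    }
    Lk[k] <- mean(Lm)
  }
  fit <- stats::lm(log(Lk) ~ log(1 / (1:kmax)))
  unname(coef(fit)[2])
}

# one-unit deflationary FastICA (fixed-point, log-cosh nonlinearity) on
# pre-whitened data z (rank x n); returns unit-variance component series
fastica_deflate <- function(z, n_comp = nrow(z), max_iter = 200, tol = 1e-8) {
  rank <- nrow(z); n <- ncol(z)
  W <- matrix(0, n_comp, rank)
  for (p in seq_len(n_comp)) {
    w <- rnorm(rank); w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      s <- drop(w %*% z)
      g <- tanh(s); gp <- 1 - g^2
      w_new <- z %*% g / n - mean(gp) * w
      w_new <- drop(w_new)
      if (p > 1) {                      # deflation: orthogonalize
        proj <- W[1:(p - 1), , drop = FALSE]
        w_new <- w_new - drop(crossprod(proj %*% w_new, proj))
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      if (abs(abs(sum(w_new * w))  - 1) < tol) { w <- w_new; break }
      w <- w_new
    }
    W[p, ] <- w
  }
  W %*% z
}

# small but realistic mixture + light annealing settings for unit tests
test_mixture <- function(seed = 11, duration_s = 30) {
  gen_mixture(sw_config(duration_s = duration_s, seed = seed))
}

light_fss_cfg <- function(seed = 5, t_min = 0.5, ...) {
  fss_config(seed = seed, n_restarts = 2, iters_per_temp = 25,
             t_min = t_min, ...)
}
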