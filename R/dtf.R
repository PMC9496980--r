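# Directed Transfer Function between extracted sources.
#
# Pipeline per condition: downsample both source time courses to 250 Hz,
# cut into non-overlapping 20-s segments, fit an MVAR model per segment
# (least squares, order by minimum AIC), form the transfer matrix
# H(f) = (I - sum_k A_k e^{-i 2 pi f k / fs})^{-1}, and row-normalize
#   gamma2[i, j, f] = |H_ij(f)|^2 / sum_m |H_im(f)|^2,
# the directed inflow fraction from source j into sink i. Segment spectra
# from stable fits are averaged arithmetically.

#' Integer-factor downsampling with anti-alias filtering
#'
#' Classic decimation: zero-phase (forward-backward) 8th-order Chebyshev
#' type-I low-pass at 0.8 x the output Nyquist, then keep every
#' `fs_in/fs_out`-th sample.
#'
#' @param s numeric series.
#' @param fs_in,fs_out input and output sampling rates (Hz); `fs_in` must be
#'   an integer multiple of `fs_out`.
#' @return downsampled series of length `floor(length(s) / factor)` (the
#'   first retained sample is the first input sample).
#' @export
downsample <- function(s, fs_in, fs_out) {
  if (fs_in == fs_out) return(s)
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("fs_in must be an integer multiple of fs_out (got factor ",
         format(factor), "); rational resampling is out of scope")
  factor <- as.integer(round(factor))
  filt <- signal::cheby1(8, 0.05, 0.8 / factor)
  # normalize to exact unity DC gain (even-order Chebyshev-I otherwise
  # attenuates DC by the ripple) and damp edge transients by odd-reflection
  # padding before the forward-backward pass
  filt$b <- filt$b * (sum(filt$a) / sum(filt$b))
  n <- length(s)
  pad <- min(n - 1L, 600L)
  xp <- c(2 * s[1] - s[(pad + 1):2], s, 2 * s[n] - s[(n - 1):(n - pad)])
  sf <- signal::filtfilt(filt, xp)[(pad + 1):(pad + n)]
  sf[seq.int(1L, n, by = factor)][seq_len(n %/% factor)]
}

#' Cut multichannel signals into mean-removed segments
#'
#' @param x K x n numeric matrix (signals in rows).
#' @param fs sampling rate (Hz).
#' @param seg_s segment length in seconds (default 20); trailing partial
#'   segment discarded.
#' @return list of K x m matrices, each signal mean-removed per segment.
#' @export
segment <- function(x, fs, seg_s = 20) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  m <- as.integer(round_half_away(seg_s * fs))
  nseg <- ncol(x) %/% m
  if (nseg < 1) stop("signal shorter than one ", seg_s, "-s segment")
  lapply(seq_len(nseg), function(i) {
    seg <- x[, ((i - 1) * m + 1):(i * m), drop = FALSE]
    seg - rowMeans(seg)
  })
}

#' Fit a multivariate autoregressive model
#'
#' Multivariate least squares (regression of `x_t` on `p` lags), with the
#' order chosen by minimum AIC over `1..p_max`. All candidate orders condition
#' on the same first `p_max` samples so their AICs are comparable. Stability
#' (companion-matrix spectral radius < 1) is checked and recorded, never
#' silently ignored.
#'
#' @param x K x n matrix of signals (rows), or a list `segment()` element.
#' @param p_max maximum candidate order (default 20).
#' @param fs sampling rate (Hz), carried into the model.
#' @return object of class `"mvar"`: `order_p`, `coeffs` (list of K x K
#'   matrices), `noise_cov`, `fs`, `stable`, `spectral_radius`,
#'   `criterion_trace` (data.frame order/AIC).
#' @export
fit_mvar <- function(x, p_max = 20, fs = 1) {
  if (is.vector(x)) stop("need a K x n matrix with K >= 2 signals")
  K <- nrow(x); n <- ncol(x)
  if (n <= K * p_max * 10)
    stop("segment too short (", n, " samples) for p_max = ", p_max,
         " with K = ", K, " signals; need > ", K * p_max * 10)
  if (!all(is.finite(x))) stop("non-finite samples in segment")
  xc <- x - rowMeans(x)

  Tn <- n - p_max                      # common effective sample count
  Y <- t(xc[, (p_max + 1):n, drop = FALSE])          # Tn x K
  X <- matrix(0, Tn, K * p_max)                      # lag-stacked design
  for (k in seq_len(p_max))
    X[, ((k - 1) * K + 1):(k * K)] <- t(xc[, (p_max + 1 - k):(n - k),
                                           drop = FALSE])
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  YtY <- crossprod(Y)

  fits <- vector("list", p_max)
  aic <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    cols <- seq_len(K * p)
    ch <- tryCatch(chol(XtX[cols, cols, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) {
      if (p == 1)
        stop("singular lag covariance (collinear or identical signals); ",
             "cannot fit an MVAR model")
      next
    }
    B <- backsolve(ch, forwardsolve(t(ch), XtY[cols, , drop = FALSE]))
    Sigma <- (YtY - crossprod(XtY[cols, , drop = FALSE], B)) / Tn
    ld <- determinant(Sigma, logarithm = TRUE)
    if (ld$sign <= 0) next
    aic[p] <- as.numeric(ld$modulus) + 2 * p * K^2 / Tn
    fits[[p]] <- list(B = B, Sigma = Sigma)
  }
  if (all(is.na(aic))) stop("no admissible MVAR order in 1..", p_max)
  p <- which.min(aic)
  B <- fits[[p]]$B
  coeffs <- lapply(seq_len(p), function(k) {
    t(B[((k - 1) * K + 1):(k * K), , drop = FALSE])   # A_k: K x K
  })
  Sigma <- (fits[[p]]$Sigma + t(fits[[p]]$Sigma)) / 2

  # companion-matrix stability
  comp <- matrix(0, K * p, K * p)
  for (k in seq_len(p)) comp[1:K, ((k - 1) * K + 1):(k * K)] <- coeffs[[k]]
  if (p > 1) comp[(K + 1):(K * p), 1:(K * (p - 1))] <- diag(K * (p - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))

  structure(list(order_p = p, coeffs = coeffs, noise_cov = Sigma, fs = fs,
                 stable = rho < 1, spectral_radius = rho,
                 criterion_trace = data.frame(order = seq_len(p_max),
                                              AIC = aic)),
            class = "mvar")
}

#' @export
print.mvar <- function(x, ...) {
  cat(sprintf("<mvar> K = %d signals, order p = %d (AIC), fs = %g Hz\n",
              nrow(x$noise_cov), x$order_p, x$fs))
  cat(sprintf("  companion spectral radius = %.4f (%s)\n", x$spectral_radius,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' @export
coef.mvar <- function(object, ...) object$coeffs

#' Directed Transfer Function spectrum of one MVAR model
#'
#' @param model a stable `"mvar"` fit.
#' @param freqs frequency grid (Hz) within `[0, fs/2]`; default 0..125 in
#'   0.5-Hz steps (capped at Nyquist).
#' @param labels signal names.
#' @return object of class `"dtf_result"`: `freqs`, `gamma2`
#'   (K x K x n_freq, `gamma2[i, j, f]` = inflow fraction j -> i), `K`,
#'   `labels`, `fs`.
#' @export
dtf_spectrum <- function(model, freqs = NULL, labels = NULL) {
  stopifnot(inherits(model, "mvar"))
  fs <- model$fs
  if (is.null(freqs)) freqs <- seq(0, min(125, fs / 2), by = 0.5)
  if (any(freqs < 0 | freqs > fs / 2 + 1e-9))
    stop("frequencies outside [0, fs/2]")
  K <- nrow(model$noise_cov)
  p <- model$order_p
  if (is.null(labels)) labels <- paste0("sig", seq_len(K))
  g2 <- array(NA_real_, c(K, K, length(freqs)))
  for (fi in seq_along(freqs)) {
    Abar <- diag(K) + 0i
    for (k in seq_len(p))
      Abar <- Abar - model$coeffs[[k]] * exp(-2i * pi * freqs[fi] * k / fs)
    H <- tryCatch(solve(Abar), error = function(e)
      stop("transfer matrix singular at f = ", freqs[fi], " Hz"))
    P <- Mod(H)^2
    g2[, , fi] <- P / rowSums(P)
  }
  structure(list(freqs = freqs, gamma2 = g2, K = K, labels = labels,
                 fs = fs, order_p = p),
            class = "dtf_result")
}

# mean gamma2 per named band; bands are half-open [lo, hi) Hz
.band_summary <- function(freqs, gamma2, labels, bands) {
  rows <- list()
  for (b in names(bands)) {
    sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
    if (!any(sel)) next
    m <- apply(gamma2[, , sel, drop = FALSE], c(1, 2), mean)
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (i == j) next
      rows[[length(rows) + 1]] <- data.frame(
        sink = labels[i], source = labels[j], band = b,
        mean_gamma2 = m[i, j], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default EEG frequency bands (Hz, half-open)
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), low_gamma = c(30, 45))
}

#' Directed connectivity between two source time courses
#'
#' The full per-condition connectivity analysis: downsample both sources to
#' `fs_out`, segment, fit an MVAR model per segment, compute the DTF spectrum
#' of every stable segment, and average `gamma2` arithmetically across them.
#' Unstable segments are dropped with a warning, never repaired.
#'
#' @param s1,s2 source time courses (equal length), conventionally the
#'   epileptogenic source and the residual-brain source.
#' @param fs input sampling rate (Hz).
#' @param fs_out analysis rate after decimation (default 250 Hz).
#' @param seg_s segment length (default 20 s).
#' @param p_max maximum MVAR order for AIC selection (default 20).
#' @param freq_step frequency-grid step (default 0.5 Hz); the grid spans 0 to
#'   `min(125, fs_out/2)` Hz.
#' @param bands named list of `c(lo, hi)` band edges for the band summary.
#' @param labels signal names (default `c("FS_Epi", "FS_rp")`).
#' @return `"dtf_result"` with segment-averaged `gamma2`, `per_segment`
#'   (list of per-segment `gamma2` arrays), `band_summary` (long data.frame),
#'   `orders` (per-segment selected order), `n_dropped` (unstable segments).
#' @export
dtf <- function(s1, s2, fs, fs_out = 250, seg_s = 20, p_max = 20,
                freq_step = 0.5, bands = eeg_bands(),
                labels = c("FS_Epi", "FS_rp")) {
  if (length(s1) != length(s2)) stop("sources differ in length")
  x <- rbind(downsample(s1, fs, fs_out), downsample(s2, fs, fs_out))
  # standardize each signal so gamma2 is invariant to channel gain
  x <- x / apply(x, 1, stats::sd)
  segs <- segment(x, fs_out, seg_s)
  freqs <- seq(0, min(125, fs_out / 2), by = freq_step)

  per_seg <- list(); orders <- integer(0); dropped <- 0L
  for (sg in segs) {
    m <- fit_mvar(sg, p_max = p_max, fs = fs_out)
    if (!m$stable) { dropped <- dropped + 1L; next }
    sp <- dtf_spectrum(m, freqs, labels)
    per_seg[[length(per_seg) + 1]] <- sp$gamma2
    orders <- c(orders, m$order_p)
  }
  if (dropped > 0)
    warning(dropped, " unstable segment(s) dropped from the DTF average")
  if (!length(per_seg)) stop("all segments gave unstable MVAR fits")

  g2 <- Reduce(`+`, per_seg) / length(per_seg)
  structure(list(freqs = freqs, gamma2 = g2, per_segment = per_seg,
                 band_summary = .band_summary(freqs, g2, labels, bands),
                 K = 2L, labels = labels, fs = fs_out,
                 orders = orders, n_dropped = dropped, n_segments = length(segs)),
            class = "dtf_result")
}

#' @export
print.dtf_result <- function(x, ...) {
  cat(sprintf("<dtf_result> K = %d, %d frequencies in [%g, %g] Hz\n",
              x$K, length(x$freqs), min(x$freqs), max(x$freqs)))
  if (!is.null(x$orders))
    cat(sprintf("  %d stable segment(s) averaged (orders %s)%s\n",
                length(x$orders), paste(range(x$orders), collapse = "-"),
                if (x$n_dropped) paste0(", ", x$n_dropped, " dropped") else ""))
  for (i in seq_len(x$K)) for (j in seq_len(x$K)) {
    if (i == j) next
    pk <- which.max(x$gamma2[i, j, ])
    cat(sprintf("  %s -> %s: peak gamma2 = %.3f at %g Hz\n",
                x$labels[j], x$labels[i], x$gamma2[i, j, pk], x$freqs[pk]))
  }
  invisible(x)
}

#' @describeIn dtf `plot()` draws the off-diagonal inflow spectra.
#' @param x a `dtf_result`.
#' @param ... unused.
#' @export
plot.dtf_result <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (i in seq_len(x$K)) for (j in seq_len(x$K)) {
    if (i == j) next
    plot(x$freqs, x$gamma2[i, j, ], type = "l", ylim = c(0, 1),
         xlab = "frequency (Hz)", ylab = expression(gamma^2),
         main = sprintf("%s %s %s", x$labels[j], "→", x$labels[i]))
  }
  invisible(x)
}

#' Long-format DTF table
#'
#' @param x a `dtf_result`.
#' @param condition condition label added as a column.
#' @return data.frame with columns condition, sink, source, freq_hz, gamma2.
#' @export
dtf_long <- function(x, condition = "") {
  stopifnot(inherits(x, "dtf_result"))
  rows <- list()
  for (i in seq_len(x$K)) for (j in seq_len(x$K)) {
    if (i == j) next
    rows[[length(rows) + 1]] <- data.frame(
      condition = condition, sink = x$labels[i], source = x$labels[j],
      freq_hz = x$freqs, gamma2 = x$gamma2[i, j, ], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
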