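# Functional Source Separation: constrained one-unit ICA.
#
# The extraction maximizes F(w) = J(w'z) + lambda * R(w'z) over unit vectors
# w in whitened space, where J is the log-cosh negentropy approximation and R
# the mean power of the candidate source inside the spike-locked constraint
# windows. Both terms are computed on the unit-variance source, which is what
# makes a fixed lambda transferable across recordings.

# E[log cosh(nu)] for standard Gaussian nu, by adaptive quadrature at load
# time (keep in sync with the constant compiled into the annealer).
.logcosh_gauss_mean <- local({
  g <- function(u) {
    a <- abs(u)
    (a + log1p(exp(-2 * a)) - log(2)) * stats::dnorm(u)
  }
  stats::integrate(g, -Inf, Inf, rel.tol = 1e-13)$value
})

#' FSS optimizer settings
#'
#' Defaults follow the reported operating point: constraint weight
#' `lambda = 1000` and initial annealing temperature `t0 = 1000`, with a
#' geometric cooling schedule.
#'
#' @param lambda nonnegative constraint weight balancing independence (J)
#'   against the spike-locked power constraint (R).
#' @param t0 initial annealing temperature.
#' @param cooling_alpha geometric cooling factor in (0, 1).
#' @param t_min stop temperature.
#' @param iters_per_temp Metropolis proposals per temperature level.
#' @param step_scale proposal step s.d. on the unit sphere at `t0`; shrinks
#'   with `sqrt(T / t0)`.
#' @param n_restarts independent annealing chains; the best final cost wins.
#' @param seed RNG seed used by [fss()] (`NULL` = leave RNG state alone).
#' @param pca_rank whitening rank; `NULL` keeps every eigenvalue above a
#'   relative tolerance (full rank for full-rank data).
#' @param aggregate how window powers combine into R: `"mean"` (default) or
#'   `"max"` over windows.
#' @param normalize_R `"none"` (R is mean window power of the unit-variance
#'   source) or `"by_total_power"` (divides by mean total power, identically 1
#'   for a unit-variance source; kept as an explicit switch).
#' @return list of class `"fss_config"`.
#' @export
fss_config <- function(lambda = 1000, t0 = 1000, cooling_alpha = 0.95,
                       t_min = 1e-4, iters_per_temp = 50, step_scale = 0.5,
                       n_restarts = 4, seed = NULL, pca_rank = NULL,
                       aggregate = c("mean", "max"),
                       normalize_R = c("none", "by_total_power")) {
  aggregate <- match.arg(aggregate)
  normalize_R <- match.arg(normalize_R)
  stopifnot(lambda >= 0, t0 > t_min, t_min > 0,
            cooling_alpha > 0, cooling_alpha < 1,
            iters_per_temp >= 1, n_restarts >= 1, step_scale > 0)
  structure(list(lambda = lambda, t0 = t0, cooling_alpha = cooling_alpha,
                 t_min = t_min, iters_per_temp = iters_per_temp,
                 step_scale = step_scale, n_restarts = n_restarts,
                 seed = seed, pca_rank = pca_rank, aggregate = aggregate,
                 normalize_R = normalize_R),
            class = "fss_config")
}

#' PCA whitening of an EEG recording
#'
#' @param rec an `eeg_recording`.
#' @param rank retained PCA rank; `NULL` keeps eigenvalues above
#'   `1e-10 * max(eigenvalue)`.
#' @return list with `model` (class `"whitening_model"`: `mean`, `whitener`
#'   (rank x K), `dewhitener` (K x rank), `eigenvalues`) and `z`, the
#'   rank x n whitened data with identity sample covariance.
#' @export
whiten <- function(rec, rank = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  mu <- rowMeans(x)
  xc <- x - mu
  C <- tcrossprod(xc) / (ncol(xc) - 1)
  e <- eigen(C, symmetric = TRUE)
  tol <- 1e-10 * e$values[1]
  avail <- sum(e$values > tol)
  if (is.null(rank)) rank <- avail
  if (rank > avail)
    stop("data covariance has rank ", avail, " < requested rank ", rank,
         "; use a smaller 'rank'")
  ev <- e$values[seq_len(rank)]
  E <- e$vectors[, seq_len(rank), drop = FALSE]
  whitener <- diag(1 / sqrt(ev), rank) %*% t(E)
  dewhitener <- E %*% diag(sqrt(ev), rank)
  model <- structure(list(mean = mu, whitener = whitener,
                          dewhitener = dewhitener, eigenvalues = ev),
                     class = "whitening_model")
  list(model = model, z = whitener %*% xc)
}

#' Negentropy approximation J
#'
#' One-unit FastICA contrast `J(y) = (mean(G(y)) - E[G(nu)])^2` with
#' `G(u) = log cosh(u)` and `nu` standard Gaussian (the Gaussian expectation
#' is computed by quadrature, about 0.3745672).
#'
#' @param y numeric series with sample variance within 1e-3 of 1.
#' @return nonnegative scalar.
#' @export
negentropy_J <- function(y) {
  if (!all(is.finite(y))) stop("'y' contains non-finite values")
  v <- stats::var(y)
  if (abs(v - 1) > 1e-3)
    stop("negentropy_J expects a unit-variance series (var = ",
         format(v), ")")
  a <- abs(y)
  (mean(a + log1p(exp(-2 * a)) - log(2)) - .logcosh_gauss_mean)^2
}

#' Spike-locked power constraint R
#'
#' Mean over constraint windows of the within-window mean of `s^2`.
#'
#' @param s numeric series (by construction unit variance in the extraction;
#'   treated as given here).
#' @param windows list of half-open 0-based `c(start, stop)` intervals, as
#'   returned by [constraint_windows()].
#' @param aggregate `"mean"` or `"max"` over the per-window means.
#' @return nonnegative scalar.
#' @export
constraint_R <- function(s, windows, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (!length(windows)) stop("empty window list")
  pw <- vapply(windows, function(w) mean(s[(w[1] + 1L):w[2]]^2), numeric(1))
  if (aggregate == "mean") mean(pw) else max(pw)
}

# shared internals ----------------------------------------------------------

.constraint_arrays <- function(windows) {
  len <- vapply(windows, function(w) w[2] - w[1], numeric(1))
  idx <- window_indices(windows) - 1L          # 0-based for C++
  wid <- rep.int(seq_along(windows) - 1L, len)
  wt <- 1 / (length(windows) * len)[wid + 1L]
  list(idx = idx, wt = wt, win_id = wid, win_len = len,
       n_win = length(windows))
}

.anneal_best <- function(zt, windows, cfg) {
  ca <- .constraint_arrays(windows)
  best <- NULL
  rank <- ncol(zt)
  for (r in seq_len(cfg$n_restarts)) {
    w0 <- stats::rnorm(rank)
    res <- fss_anneal_cpp(zt, ca$idx, ca$wt, ca$win_id, ca$win_len,
                          ca$n_win, cfg$aggregate == "max", cfg$lambda,
                          cfg$t0, cfg$cooling_alpha, cfg$t_min,
                          cfg$iters_per_temp, cfg$step_scale, w0)
    res$restart <- r
    if (is.null(best) || res$cost > best$cost) best <- res
  }
  best
}

#' Extract a functional source by constrained ICA
#'
#' Fits the spike-constrained source model: among unit-variance linear
#' combinations of the (whitened) EEG channels, finds the one maximizing
#' negentropy plus `lambda` times the mean signal power inside the
#' spike-locked constraint windows, by simulated annealing with restarts.
#'
#' The returned object carries the unwhitened spatial filter `w` (so that
#' `s = w' (data - channel means)`), the scalp topography `a = Cov(data, s)`
#' (the mixing column when sources are uncorrelated), and the unit-variance
#' time course `s`, sign-fixed so the mean of `s` over the constraint windows
#' is nonnegative (spikes point up).
#'
#' @param rec an `eeg_recording`.
#' @param markers a `spike_markers` object; fewer than 5 markers triggers a
#'   warning (constraint poorly estimated).
#' @param config an [fss_config()].
#' @param label source label, conventionally `"FS_Epi"` for the first
#'   extraction and `"FS_rp"` for the extraction from the residual.
#' @return object of class `"fss"` with elements `w`, `a`, `s`, `label`,
#'   `cost_trace`, `constraint_value`, `J`, `cost`, `config`, `windows`,
#'   `whitening`, `recording` (the training recording), `n_markers`.
#' @seealso [residuals.fss()], [predict.fss()], [fss_pair()]
#' @export
fss <- function(rec, markers, config = fss_config(), label = "FS_Epi") {
  stopifnot(inherits(rec, "eeg_recording"), inherits(markers, "spike_markers"),
            inherits(config, "fss_config"))
  windows <- constraint_windows(markers, rec$fs, ncol(rec$data))
  if (length(windows) < 5)
    warning("only ", length(windows),
            " constraint window(s); the functional constraint is poorly estimated")
  if (!is.null(config$seed)) set.seed(config$seed)

  wh <- whiten(rec, config$pca_rank)
  zt <- t(wh$z)                               # n x rank for BLAS gemv
  best <- .anneal_best(zt, windows, config)

  w_t <- as.numeric(best$w)
  s <- as.numeric(zt %*% w_t)
  # sign: spike-locked mean nonnegative
  if (mean(s[window_indices(windows)]) < 0) {
    w_t <- -w_t
    s <- -s
  }
  w <- as.numeric(crossprod(wh$model$whitener, w_t))
  xc <- rec$data - wh$model$mean
  a <- as.numeric(xc %*% s) / (length(s) - 1)   # Cov(data, s), var(s) = 1
  names(w) <- names(a) <- rec$channel_names

  R <- constraint_R(s, windows, config$aggregate)
  if (config$normalize_R == "by_total_power") R <- R / mean(s^2)

  structure(list(w = w, a = a, s = s, label = label,
                 cost_trace = best$trace, constraint_value = R,
                 J = negentropy_J(s), cost = best$cost,
                 restart = best$restart, config = config,
                 windows = windows, markers = markers,
                 whitening = wh$model, recording = rec,
                 n_markers = length(windows)),
            class = "fss")
}

#' @export
print.fss <- function(x, ...) {
  cat(sprintf("<fss> %s: constrained-ICA source from %d channels, %d samples\n",
              x$label, length(x$w), length(x$s)))
  cat(sprintf("  lambda = %g, %d constraint windows\n",
              x$config$lambda, x$n_markers))
  cat(sprintf("  cost = %.6g  (J = %.3g, R = %.4g)\n",
              x$cost, x$J, x$constraint_value))
  top <- names(sort(abs(x$a), decreasing = TRUE))[1:3]
  cat("  topography peaks at:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fss <- function(object, ...) {
  out <- list(label = object$label, lambda = object$config$lambda,
              n_markers = object$n_markers, J = object$J,
              constraint_value = object$constraint_value, cost = object$cost,
              topography = object$a, filter = object$w,
              var_explained = sum(object$a^2) /
                sum(apply(object$recording$data, 1, stats::var)))
  class(out) <- "summary.fss"
  out
}

#' @export
print.summary.fss <- function(x, ...) {
  cat(sprintf("Functional source %s\n", x$label))
  cat(sprintf("  constraint weight lambda : %g\n", x$lambda))
  cat(sprintf("  constraint windows       : %d\n", x$n_markers))
  cat(sprintf("  negentropy J             : %.4g\n", x$J))
  cat(sprintf("  constraint value R       : %.4g\n", x$constraint_value))
  cat(sprintf("  fraction of EEG variance : %.3f\n", x$var_explained))
  cat("  topography (a):\n")
  print(round(x$topography, 3))
  invisible(x)
}

#' @describeIn fss `coef()` returns the scalp topography `a` (set
#'   `which = "filter"` for the spatial filter `w`).
#' @param object,x an `fss` fit.
#' @param which `"topography"` (mixing column a) or `"filter"` (weights w).
#' @param ... unused.
#' @export
coef.fss <- function(object, which = c("topography", "filter"), ...) {
  which <- match.arg(which)
  if (which == "topography") object$a else object$w
}

#' Project the fitted spatial filter onto EEG
#'
#' Applies the time-invariant filter `w` learned on the reference condition to
#' any recording with the same montage, returning that condition's source time
#' course (centered projection, in the fitted source's scale).
#'
#' @param object an `fss` fit.
#' @param newdata an `eeg_recording` with the same channels (order may
#'   differ); default: the training recording.
#' @param rescale if `TRUE` (default) the projection is left in the fitted
#'   scale (unit variance on the training data); `FALSE` is identical since
#'   no rescaling is ever applied — argument kept for clarity.
#' @param ... unused.
#' @return numeric source time course, one value per sample of `newdata`.
#' @export
predict.fss <- function(object, newdata = NULL, rescale = TRUE, ...) {
  if (is.null(newdata)) return(object$s)
  stopifnot(inherits(newdata, "eeg_recording"))
  if (!setequal(newdata$channel_names, names(object$w)))
    stop("channel sets differ between fit and newdata")
  x <- newdata$data[names(object$w), , drop = FALSE]
  as.numeric(crossprod(object$w, x - rowMeans(x)))
}

#' Residual EEG after rank-1 removal of a fitted source
#'
#' Returns the recording with the fitted source's contribution regressed out
#' of the centered data (channel means preserved): the remaining-brain signal
#' once the extracted network is projected away. On the training recording
#' this subtracts `a * s'` exactly; on another condition's recording the
#' source time course is first obtained by [predict.fss()] and its per-channel
#' regression coefficients re-estimated there. Each residual channel is
#' exactly uncorrelated with the removed time course.
#'
#' @param object an `fss` fit.
#' @param rec recording to residualize; default the training recording.
#' @param ... unused.
#' @return an `eeg_recording` with `condition_tag` suffixed `"_rp"`.
#' @export
residuals.fss <- function(object, rec = NULL, ...) {
  if (is.null(rec)) {
    rec <- object$recording
    s <- object$s
  } else {
    stopifnot(inherits(rec, "eeg_recording"))
    s <- predict(object, rec)
  }
  mu <- rowMeans(rec$data)
  xc <- rec$data[names(object$w), , drop = FALSE] -
    mu[names(object$w)]
  # nothing to remove if the source has no energy in this recording
  # (e.g. residualizing twice): regressing on numerical noise would amplify it
  if (sum(s^2) <= 1e-12 * sum(xc[1, ]^2)) {
    b <- numeric(nrow(xc))
  } else {
    b <- as.numeric(xc %*% s) / sum(s^2)       # per-channel regression
  }
  out <- xc - outer(b, s) + mu[names(object$w)]
  eeg_recording(out, rec$fs, names(object$w), rec$reference,
                paste0(rec$condition_tag, "_rp"))
}

#' Sequential two-source extraction
#'
#' The standard analysis: extract the spike-constrained source `FS_Epi`, form
#' the rank-1 residual EEG, and run the same constrained extraction on the
#' residual to obtain the remaining-brain source `FS_rp`.
#'
#' @inheritParams fss
#' @return list with elements `fs_epi`, `fs_rp` (both `"fss"`), and
#'   `residual_recording`.
#' @export
fss_pair <- function(rec, markers, config = fss_config()) {
  fs_epi <- fss(rec, markers, config, label = "FS_Epi")
  rec_rp <- residuals(fs_epi)
  cfg_rp <- config
  if (!is.null(cfg_rp$seed)) cfg_rp$seed <- cfg_rp$seed + 1L
  fs_rp <- fss(rec_rp, markers, cfg_rp, label = "FS_rp")
  list(fs_epi = fs_epi, fs_rp = fs_rp, residual_recording = rec_rp)
}

#' @describeIn fss `plot()` shows the scalp topography as a labelled barplot
#'   and the annealing best-cost trace.
#' @export
plot.fss <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  barplot(x$a, las = 2, ylab = expression(paste("topography a (", mu, "V)")),
          main = x$label, cex.names = 0.7)
  tr <- x$cost_trace
  plot(tr$iteration, tr$best_cost, type = "l", log = "",
       xlab = "proposal", ylab = "best cost", main = "annealing")
  invisible(x)
}

#' Extraction report as a list (serializable to JSON)
#'
#' @param fit an `fss` fit.
#' @return list with label, settings, final cost decomposition, and the
#'   topography keyed by channel name.
#' @export
fss_report <- function(fit) {
  stopifnot(inherits(fit, "fss"))
  list(label = fit$label, lambda = fit$config$lambda, t0 = fit$config$t0,
       seed = fit$config$seed, final_cost = fit$cost, J = fit$J,
       R = fit$constraint_value, n_markers = fit$n_markers,
       topography = as.list(fit$a), filter = as.list(fit$w))
}
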