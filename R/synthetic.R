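# Ground-truthed synthetic EEG.
#
# The generator emulates the study conditions the analysis is built for:
# spike-and-wave (SW) interictal transients recurring tens of times, embedded
# through a fixed 19-channel scalp topography (peaked at the temporal focus)
# into ongoing background activity (posterior alpha + broadband) plus sensor
# noise. Everything is a pure function of (config, seed).

#' Configuration of the spike-and-wave EEG generator
#'
#' Defaults mirror the emulated recordings: 19-channel 10-20 montage at
#' 1000 Hz, SW transients with an 80-microvolt sharp spike and a slower
#' opposite-polarity wave, topography peaked at T4, posterior alpha plus
#' broadband background, 120 s per condition.
#'
#' @param n_channels number of channels (19 uses the standard montage).
#' @param fs sampling rate (Hz).
#' @param duration_s recording length (s); must allow at least 10 events.
#' @param spike_rate_hz SW events per second.
#' @param spike_amp sharp-spike amplitude (microvolt at the focus channel).
#' @param spike_width_s spike full width (s).
#' @param wave_amp slow-wave amplitude (microvolt).
#' @param wave_width_s slow-wave width (s).
#' @param topography_focus channel where the SW topography peaks.
#' @param background_alpha_amp posterior 10-Hz background amplitude
#'   (microvolt).
#' @param background_broadband_amp broadband background amplitude (microvolt).
#' @param noise_amp independent sensor-noise s.d. (microvolt).
#' @param baseline_sd source-level pink-noise s.d. (microvolt) under the SW
#'   transients.
#' @param propagation_amp amplitude (microvolt) of the delayed, broadened
#'   discharge remnant carried by the broadband background source — the
#'   wider network's participation in each discharge, which is what the
#'   second (residual) extraction converges to.
#' @param propagation_delay_s delay of that remnant after the apex (s).
#' @param coupling_strength lag coupling from the SW source's ongoing
#'   oscillation into the background source (used by
#'   [gen_four_conditions()]).
#' @param coupling_freq_hz resonance of that ongoing oscillation (Hz).
#' @param coupling_amp amplitude (microvolt) of the coupled oscillation pair.
#' @param seed RNG seed.
#' @return list of class `"sw_config"`.
#' @export
sw_config <- function(n_channels = 19, fs = 1000, duration_s = 120,
                      spike_rate_hz = 0.5, spike_amp = 80,
                      spike_width_s = 0.07, wave_amp = 40,
                      wave_width_s = 0.35, topography_focus = "T4",
                      background_alpha_amp = 20,
                      background_broadband_amp = 15, noise_amp = 5,
                      baseline_sd = 10, propagation_amp = 25,
                      propagation_delay_s = 0.004, coupling_strength = 0.5,
                      coupling_freq_hz = 20, coupling_amp = 6, seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, spike_rate_hz > 0, spike_amp > 0,
            spike_width_s > 0, wave_width_s > 0, n_channels >= 2)
  if (duration_s * spike_rate_hz < 10)
    stop("duration too short for 10 events at rate ", spike_rate_hz, " Hz")
  structure(as.list(environment()), class = "sw_config")
}

# 1/f-shaped noise via spectral shaping of white noise (deterministic in the
# RNG state); sd-normalized
.pink_noise <- function(n, sd = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                    # symmetric frequency index
  W <- W / sqrt(f)
  p <- Re(stats::fft(W, inverse = TRUE)) / n
  sd * (p - mean(p)) / stats::sd(p)
}

# fast biphasic transient carried by the wider network around each discharge:
# positive lobe just before the apex, negative lobe after. Being fast and
# zero-mean it is near-orthogonal to the broad spike-and-wave shape, so it
# survives the rank-1 removal of the primary source and anchors the residual
# extraction. apex_offset marks the apex sample within the template.
.propagation_template <- function(fs, amp, delay_s = 0.004) {
  tt <- seq(-0.015, 0.025, by = 1 / fs)
  lobe_sd <- 0.003
  shape <- amp * (exp(-0.5 * ((tt + 0.002) / lobe_sd)^2) -
                    exp(-0.5 * ((tt - delay_s - 0.002) / lobe_sd)^2))
  list(shape = shape, apex_offset = which.min(abs(tt)))
}

# biphasic SW template: sharp positive Gaussian spike (apex at its center)
# followed by a slower opposite-polarity half-sine wave
.sw_template <- function(fs, spike_amp, spike_width_s, wave_amp, wave_width_s) {
  half <- round_half_away(spike_width_s * fs / 2)
  tt <- (-half):half
  spike <- spike_amp * exp(-0.5 * (tt / (spike_width_s * fs / 6))^2)
  nw <- round_half_away(wave_width_s * fs)
  wave <- -wave_amp * sin(pi * seq_len(nw) / nw)
  list(shape = c(spike, wave), apex_offset = half + 1L)   # apex sample index
}

# event apex times: regular spacing 1/rate with +-20% uniform jitter
.event_times <- function(duration_s, rate_hz, fs) {
  gap <- 1 / rate_hz
  centers <- seq(gap, duration_s - gap / 2, by = gap)
  t <- centers + stats::runif(length(centers), -0.2 * gap, 0.2 * gap)
  round_half_away(t * fs) / fs               # snap apexes to the sample grid
}

#' Generate one spike-and-wave source time course
#'
#' Unit-variance series: pink-like baseline plus biphasic SW transients at
#' jittered event times. Exact apex times are returned as markers.
#'
#' @param cfg an [sw_config()].
#' @param rate_hz override of `cfg$spike_rate_hz` (used for the post-Real
#'   condition).
#' @return list with `s` (unit variance), `times_s` (apex times), and
#'   `scale` (the s.d. removed during normalization, microvolt).
#' @export
gen_sw_source <- function(cfg = sw_config(), rate_hz = cfg$spike_rate_hz) {
  n <- round_half_away(cfg$duration_s * cfg$fs)
  base <- .pink_noise(n, cfg$baseline_sd)
  tpl <- .sw_template(cfg$fs, cfg$spike_amp, cfg$spike_width_s,
                      cfg$wave_amp, cfg$wave_width_s)
  times <- .event_times(cfg$duration_s, rate_hz, cfg$fs)
  s <- base
  keep <- logical(length(times))
  for (i in seq_along(times)) {
    apex <- round_half_away(times[i] * cfg$fs)           # 1/fs units, 1-based ok
    start <- apex - tpl$apex_offset + 1L
    idx <- start:(start + length(tpl$shape) - 1L)
    ok <- idx >= 1 & idx <= n
    if (sum(ok) < length(tpl$shape)) next                # drop edge events
    s[idx] <- s[idx] + tpl$shape
    keep[i] <- TRUE
  }
  sc <- stats::sd(s)
  list(s = (s - mean(s)) / sc, times_s = times[keep], scale = sc)
}

# smooth scalp pattern peaked at a montage channel (unit peak)
.smooth_topography <- function(channel_names, focus, sigma = 0.55) {
  mon <- montage_1020()
  pos <- mon[match(tolower(channel_names), tolower(mon$label)), c("x", "y")]
  if (any(is.na(pos[, 1]))) {         # unknown labels: fall back to a ramp
    k <- match(focus, channel_names, nomatch = 1L)
    d <- abs(seq_along(channel_names) - k)
    return(exp(-0.5 * (d / 3)^2))
  }
  f <- pos[match(tolower(focus), tolower(channel_names)), ]
  d2 <- (pos$x - f$x)^2 + (pos$y - f$y)^2
  exp(-d2 / (2 * sigma^2))
}

#' Generate a ground-truthed multichannel SW mixture
#'
#' Forward model `EEG = a_true s_sw' + b_alpha g_alpha' + b_bb g_bb' + noise`:
#' the SW source is embedded through a smooth topography peaked at
#' `cfg$topography_focus`; background is a posterior-peaked 10-Hz alpha
#' source and a centrally peaked broadband source; sensor noise is i.i.d.
#'
#' @param cfg an [sw_config()].
#' @param rate_hz SW event rate override.
#' @param coupled_drive optional list `(x1, x2)` of unit-variance coupled
#'   oscillations added (scaled by `cfg$coupling_amp`) to the SW source and
#'   the broadband background respectively (see [gen_coupled_ar()]).
#' @param condition_tag condition label for the recording.
#' @return list with `recording` (`eeg_recording`), `markers`
#'   (`spike_markers`, 4 ms pre-apex window), and `truth` (a_true, s_true,
#'   background topographies/sources, noise_amp, scales).
#' @export
gen_mixture <- function(cfg = sw_config(), rate_hz = cfg$spike_rate_hz,
                        coupled_drive = NULL, condition_tag = "") {
  set.seed(cfg$seed)
  gen_mixture_unseeded(cfg, rate_hz, coupled_drive, condition_tag)
}

#' @rdname gen_mixture
#' @export
gen_mixture_unseeded <- function(cfg, rate_hz = cfg$spike_rate_hz,
                                 coupled_drive = NULL, condition_tag = "") {
  n <- round_half_away(cfg$duration_s * cfg$fs)
  ch <- if (cfg$n_channels == 19) montage_1020()$label
        else paste0("ch", seq_len(cfg$n_channels))

  sw <- gen_sw_source(cfg, rate_hz)
  s_raw <- sw$s * sw$scale                     # back to microvolt scale
  if (!is.null(coupled_drive))
    s_raw <- s_raw + cfg$coupling_amp * coupled_drive$x1
  sw_gain <- stats::sd(s_raw)
  s_true <- (s_raw - mean(s_raw)) / sw_gain

  a_true <- .smooth_topography(ch, cfg$topography_focus)
  b_alpha <- .smooth_topography(ch, "O1", sigma = 0.7)
  b_bb <- .smooth_topography(ch, "Cz", sigma = 0.9)

  # posterior alpha: amplitude-modulated 10 Hz
  tt <- seq_len(n) / cfg$fs
  env <- 1 + 0.5 * sin(2 * pi * 0.1 * tt + stats::runif(1, 0, 2 * pi))
  g_alpha <- sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi)) * env +
    0.3 * stats::rnorm(n)
  g_alpha <- (g_alpha - mean(g_alpha)) / stats::sd(g_alpha)

  # broadband background in microvolt, carrying the wider network's delayed,
  # broadened participation in each discharge (no remnant -> the residual
  # extraction would have nothing spike-locked to converge to)
  g_bb_raw <- .pink_noise(n, cfg$background_broadband_amp)
  if (cfg$propagation_amp > 0 && length(sw$times_s)) {
    tpl_p <- .propagation_template(cfg$fs, cfg$propagation_amp,
                                   cfg$propagation_delay_s)
    for (k in seq_along(sw$times_s)) {
      # alternating polarity: spike-locked *power* (the constraint) is
      # unaffected, but the correlation with the primary source cancels, so
      # the remnant neither tilts the first extraction nor vanishes with the
      # rank-1 removal
      pol <- if (k %% 2 == 0) 1 else -1
      apex <- round_half_away(sw$times_s[k] * cfg$fs)
      start <- apex - tpl_p$apex_offset + 1L
      idx <- start:(start + length(tpl_p$shape) - 1L)
      ok <- idx >= 1 & idx <= n
      g_bb_raw[idx[ok]] <- g_bb_raw[idx[ok]] + pol * tpl_p$shape[ok]
    }
  }
  if (!is.null(coupled_drive)) {
    # the received drive x2 lives in the whole non-epileptogenic background:
    # inject it into both background sources at coupling_amp microvolt
    g_alpha <- g_alpha + cfg$coupling_amp / cfg$background_alpha_amp *
      coupled_drive$x2
    g_alpha <- (g_alpha - mean(g_alpha)) / stats::sd(g_alpha)
    g_bb_raw <- g_bb_raw + cfg$coupling_amp * coupled_drive$x2
  }
  bb_gain <- stats::sd(g_bb_raw)
  g_bb <- (g_bb_raw - mean(g_bb_raw)) / bb_gain

  data <- outer(a_true * sw_gain, s_true) +
    outer(b_alpha * cfg$background_alpha_amp, g_alpha) +
    outer(b_bb * bb_gain, g_bb)
  if (cfg$noise_amp > 0)
    data <- data + matrix(stats::rnorm(length(data), sd = cfg$noise_amp),
                          nrow = length(ch))

  rec <- eeg_recording(data, cfg$fs, ch, reference = "FCz",
                       condition_tag = condition_tag)
  markers <- spike_markers(sw$times_s)
  list(recording = rec, markers = markers,
       truth = list(a_true = a_true * sw_gain, s_true = s_true,
                    b_alpha = b_alpha * cfg$background_alpha_amp,
                    g_alpha = g_alpha,
                    b_bb = b_bb * bb_gain, g_bb = g_bb,
                    noise_amp = cfg$noise_amp))
}

#' Coupled bivariate AR oracle system
#'
#' `x1` is an AR(2) resonant at `coupling_freq_hz` (poles at radius 0.95);
#' `x2` is a damped AR(1) receiving `coupling_strength * x1(t-2)`. The true
#' coefficient matrices are returned for recovery tests. Both series are
#' standardized to unit variance (DTF is scale-invariant).
#'
#' @param n samples.
#' @param fs sampling rate (Hz).
#' @param coupling_freq_hz resonance of the driver (must be `< fs/2`).
#' @param coupling_strength coupling coefficient at lag 2 (0 = independent).
#' @param seed RNG seed (`NULL` = current RNG state).
#' @param reverse if `TRUE` the coupling runs x2 -> x1 instead.
#' @param pole_radius driver pole radius (default 0.95, calibrated for
#'   250 Hz; at other rates pass `0.95^(250/fs)` to keep the resonance
#'   bandwidth in Hz unchanged).
#' @return list with `x` (2 x n matrix), `A` (list of two 2 x 2 lag
#'   matrices), `fs`.
#' @export
gen_coupled_ar <- function(n, fs = 250, coupling_freq_hz = 20,
                           coupling_strength = 0.5, seed = NULL,
                           reverse = FALSE, pole_radius = 0.95) {
  if (coupling_freq_hz >= fs / 2) stop("coupling frequency above Nyquist")
  if (!is.null(seed)) set.seed(seed)
  th <- 2 * pi * coupling_freq_hz / fs
  r <- pole_radius
  a1 <- 2 * r * cos(th); a2 <- -r^2
  d <- 0.5
  burn <- 200L
  N <- n + burn
  e1 <- stats::rnorm(N); e2 <- stats::rnorm(N)
  x1 <- x2 <- numeric(N)
  for (t in 3:N) {
    x1[t] <- a1 * x1[t - 1] + a2 * x1[t - 2] + e1[t]
    x2[t] <- d * x2[t - 1] + coupling_strength * x1[t - 2] + e2[t]
  }
  x1 <- x1[(burn + 1):N]; x2 <- x2[(burn + 1):N]
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  # coefficients of the *standardized* pair actually returned
  A1 <- matrix(c(a1, 0, 0, d), 2, 2, byrow = TRUE)
  A2 <- matrix(c(a2, 0, coupling_strength * s1 / s2, 0), 2, 2, byrow = TRUE)
  x <- rbind(x1 / s1, x2 / s2)
  if (reverse) {
    x <- x[2:1, , drop = FALSE]
    A1 <- A1[2:1, 2:1]; A2 <- A2[2:1, 2:1]
  }
  list(x = x, A = list(A1, A2), fs = fs)
}

#' Series with known fractal dimension (HFD oracles)
#'
#' @param kind `"line"` (D = 1), `"white"` (D = 2 asymptotically), or
#'   `"weierstrass"` (D = 2 - H).
#' @param n samples.
#' @param H Hurst-like exponent of the Weierstrass cosine sum, in (0, 1).
#' @param gamma frequency ratio of the Weierstrass sum (>= 1.5).
#' @param seed RNG seed for `"white"`.
#' @return list with `x` and `dimension` (the analytic target).
#' @export
gen_known_fd <- function(kind = c("line", "white", "weierstrass"),
                         n = 1000, H = 0.5, gamma = 2, seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    line = list(x = seq_len(n) * 1.0, dimension = 1.0),
    white = {
      if (!is.null(seed)) set.seed(seed)
      list(x = stats::rnorm(n), dimension = 2.0)
    },
    weierstrass = {
      if (H <= 0 || H >= 1) stop("'H' must be in (0, 1)")
      if (gamma < 1.5) stop("'gamma' must be >= 1.5")
      tt <- (seq_len(n) - 1) / n
      m_max <- floor(log(n / 2) / log(gamma))   # stay below Nyquist
      if (m_max < 4) stop("too few resolvable Weierstrass terms; increase n")
      x <- numeric(n)
      for (m in 0:m_max) x <- x + gamma^(-m * H) * cos(2 * pi * gamma^m * tt)
      list(x = x, dimension = 2 - H)
    })
}

#' Generate the four-condition comparison
#'
#' Four recordings ("pre_real", "post_real", "pre_sham", "post_sham") share
#' one SW topography. post_real differs by (i) a ~10x lower SW event rate and
#' (ii) the ongoing source-to-background drive moved from beta
#' (`coupling_freq_hz`, default 20 Hz) down to theta range (4 Hz); the other
#' three conditions are statistically identical up to seed. Each condition's
#' markers are returned; the pre_real markers are the extraction reference.
#'
#' @param cfg an [sw_config()].
#' @param post_real_rate_factor event-rate reduction factor for post_real.
#' @param post_real_coupling_hz drive frequency for post_real (Hz).
#' @return list of four elements keyed by condition, each with `recording`,
#'   `markers`, `truth`, plus attribute fields `a_true`.
#' @export
gen_four_conditions <- function(cfg = sw_config(),
                                post_real_rate_factor = 0.1,
                                post_real_coupling_hz = 4) {
  set.seed(cfg$seed)
  n <- round_half_away(cfg$duration_s * cfg$fs)
  conds <- c("pre_real", "post_real", "pre_sham", "post_sham")
  out <- list()
  for (cond in conds) {
    f_c <- if (cond == "post_real") post_real_coupling_hz else cfg$coupling_freq_hz
    rate <- if (cond == "post_real") cfg$spike_rate_hz * post_real_rate_factor
            else cfg$spike_rate_hz
    drive <- gen_coupled_ar(n, cfg$fs, f_c, cfg$coupling_strength,
                            pole_radius = 0.95^(250 / cfg$fs))
    out[[cond]] <- gen_mixture_unseeded(
      cfg, rate_hz = rate,
      coupled_drive = list(x1 = drive$x[1, ], x2 = drive$x[2, ]),
      condition_tag = cond)
  }
  out
}
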