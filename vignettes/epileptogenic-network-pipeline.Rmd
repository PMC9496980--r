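---
title: "Characterizing an epileptogenic network: constrained source extraction, complexity, and directed connectivity"
author: "epinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing an epileptogenic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinet)
```

## The problem

In focal epilepsy, a localized neuronal network generates stereotyped
interictal discharges — spike-and-wave (SW) complexes — that recur tens of
times in a resting EEG recording. `epinet` characterizes that network from
multichannel scalp EEG in three stages:

1. **Extraction** (`fss()`): a constrained variant of one-unit ICA isolates
   the source generating the SW activity, using the recurrence of the
   discharges as a functional fingerprint.
2. **Complexity** (`hfd_windowed()`): the Higuchi fractal dimension (HFD) of
   the extracted source time course quantifies its neurodynamics.
3. **Directed connectivity** (`dtf()`): the Directed Transfer Function (DTF)
   over a multivariate autoregressive (MVAR) model measures
   frequency-resolved directed influence between the epileptogenic source
   and the remaining brain network.

A ground-truthed synthetic-EEG generator makes every stage testable without
patient data, and `run_pipeline()` orchestrates the typical four-condition
neuromodulation comparison (before/after real and sham stimulation).

## Constrained extraction

The EEG is modelled as an instantaneous linear mixture `X = A S + noise`.
After PCA whitening (`whiten()`), the extraction searches the unit sphere of
whitened spatial filters for

$$F(\tilde w) \;=\; J(\tilde w^\top z) \;+\; \lambda\, R(\tilde w^\top z),$$

where `J` is the log-cosh negentropy approximation used by FastICA
(independence/non-Gaussianity) and `R` is the *functional constraint*: the
mean power of the candidate source inside short spike-locked windows. The
windows cover the 4 ms *preceding* each marked spike apex (rising phase;
half-open in sample indices, so with a zero-length post-apex window the apex
sample itself is excluded — a one-sample convention recorded here once). Both
terms are evaluated on the unit-variance source, which is the only
normalization under which a fixed balance weight transfers across
recordings; the default `lambda = 1000` reflects the method's reported
operating point on that scale.

`R` is read as "maximize the mean spike-locked power", the reading
consistent with an additive λ-weighted cost; a max-over-windows pooling is
available via `fss_config(aggregate = "max")` for sensitivity analysis, as
is a power-ratio normalization (`normalize_R = "by_total_power"`).

**Optimization.** The cost is multimodal on the sphere, so a fixed-point
scheme is not reliable; we use simulated annealing with Metropolis
acceptance, geometric cooling from the reported initial temperature
`t0 = 1000` (factor 0.95 per level, 50 proposals per level, stop at 1e-4),
Gaussian proposal steps whose s.d. shrinks as `sqrt(T/t0)` from 0.5, and 4
independent restarts keeping the best final cost. The annealer runs in
whitened space — required for the unit-sphere parameterization — and uses
R's RNG, so a seed makes the whole fit bit-reproducible. The inner cost
evaluation is compiled code; everything else is plain R.

**Outputs.** The fit reports the unwhitened filter `w` (so
`s = w' (X - means)`), the scalp topography `a = Cov(X, s)` — exact for the
true mixing column when sources are uncorrelated, and better behaved than
pseudo-inverting a one-row unmixing matrix — and the unit-variance time
course `s`, sign-fixed so the spike-locked mean is nonnegative (spikes point
up). `residuals()` removes the rank-1 contribution `a s'` (channel means
preserved; every residual channel exactly uncorrelated with `s`), and the
same constrained extraction on the residual yields the remaining-brain
source `FS_rp` (`fss_pair()`).

**Projection across conditions.** The filters are time-invariant, so the
reference-condition `W_Epi` is applied to every condition's EEG
(`predict()`); `W_rp` is applied to each condition's EEG *after* the
epileptogenic contribution is regressed out there. Without that
residualization the epileptogenic source leaks into the remaining-brain
trace and manifests as spurious low-frequency "connectivity" between the
two — the leakage is visible as near-unity low-frequency DTF inflow, and
projecting onto the residualized recording removes it. Per-condition
re-extraction (the consistency analysis) is available via
`run_pipeline(consistency = TRUE)`.

## Higuchi fractal dimension

For delays $k = 1..k_{max}$ and offsets $m \le k$, Higuchi's normalized
curve length is

$$L_m(k) = \frac{1}{k}\left[\sum_{i=1}^{\lfloor (N-m)/k\rfloor}
  |x(m+ik) - x(m+(i-1)k)|\;\frac{N-1}{\lfloor (N-m)/k\rfloor\,k}\right],$$

and the dimension is the least-squares slope of $\ln L(k)$ on $\ln(1/k)$,
with $L(k)$ the mean over offsets. Values run from 1 (smooth curve) to 2
(white noise). Choices recorded here: ordinary *unweighted* least squares
over every integer `k` (offset-count weighting is available via
`weighted = TRUE`; subsampled `k` grids are not used — at `kmax = 40` full
enumeration is cheap and unambiguous); no detrending or filtering inside
windows. HFD is computed in 1-s non-overlapping windows (trailing partial
window discarded) and averaged; `hfd_kmax_sweep()` reproduces the
HFD-vs-`kmax` diagnostic on a 2..100 grid (a single delay gives no slope,
hence the grid starts at 2), with 40 the default operating point. Windows
containing marked events are included by default
(`exclude_windows` drops them when that sensitivity matters).

Correctness is anchored on analytic cases: a straight line gives exactly 1
(curve lengths scale exactly as $1/k$); white noise approaches 2; and the
Weierstrass cosine sum $\sum_m \gamma^{-mH}\cos(2\pi\gamma^m t)$ has
dimension $2-H$. The generator samples the Weierstrass sum on a unit
interval with frequency ratio $\gamma = 2$ and keeps only terms below the
Nyquist frequency; with $n = 10^4$ samples this covers enough scale octaves
that the estimator lands within a few hundredths of $2-H$ across
$H \in \{0.3, 0.5, 0.7\}$.

## Directed Transfer Function

Both source time courses are decimated to 250 Hz (zero-phase 8th-order
Chebyshev-I anti-alias filter at 0.8× the output Nyquist, then every 4th
sample), cut into non-overlapping 20-s segments, and each segment fits an
MVAR model by multivariate least squares — deterministic and unbiased at
short orders; Yule-Walker and Burg variants are deliberately not mixed in.
The order is chosen per segment by minimum AIC over 1..20 (all candidate
orders conditioned on the same samples so the criterion is comparable);
stability is verified via the companion-matrix spectral radius, and unstable
segments are dropped from the average with a warning, never repaired. From
the transfer matrix $H(f) = (I - \sum_k A_k e^{-2\pi i f k/f_s})^{-1}$ the
classic row-normalized DTF is

$$\gamma^2_{ij}(f) = \frac{|H_{ij}(f)|^2}{\sum_m |H_{im}(f)|^2},$$

the fraction of inflow into sink $i$ originating from source $j$; rows sum
to 1 at every frequency by construction, and that identity is asserted after
every computation. Segment spectra are averaged arithmetically on the
$\gamma^2$ scale (bounded and normalized; averaging $H$ would mix phases).
The grid runs 0–125 Hz in 0.5-Hz steps (only the upper bound is fixed by the
method's operating point; the step is a resolution choice), and band
summaries use delta/theta/alpha/beta/low-gamma edges `eeg_bands()`.
Statistical surrogate testing of DTF significance and time-varying DTF are
out of scope.

## The synthetic generator

`gen_mixture()` builds `EEG = a_true s' + B g' + noise`: a stylized biphasic
SW template (sharp 80-µV positive Gaussian spike of 70 ms, then a slower
40-µV opposite-polarity half-sine of 350 ms) recurs at 0.5 events/s with
±20 % jitter around regular spacing — irregular but never starving a short
recording of events — on a 10-µV pink (1/f) baseline; the source enters
through a smooth scalp pattern peaked at T4 (the emulated case's temporal
focus), over a posterior 10-Hz alpha source (20 µV), a central broadband
source (15 µV), and 5-µV sensor noise, 19 channels at 1000 Hz, 120 s per
condition. The spike parameters put substantial energy in the 4-ms pre-apex
window, which is what makes the functional constraint well-posed; exact apex
times are returned as markers, and the truth bundle (topographies and source
time courses) supports every recovery metric directly.

The broadband background additionally carries a weak spike-locked remnant —
the wider network's participation in each discharge (25 µV, a fast biphasic
transient straddling the apex, polarity alternating across events). This is
what gives the *residual* extraction a genuine target: a residual with no
spike-locked structure at all would make the constrained second extraction
degenerate, because with a large constraint weight the optimum over a
residual of pure background is always a direction that overfits the
constraint windows (mean window power of order $(1+\sqrt{k/m})^2$ for $k$
whitened dimensions and $m$ window samples, exceeding any genuine
background's expected value of 1). The fast biphasic shape keeps the remnant
nearly orthogonal in time to the broad spike-and-wave, so the rank-1 removal
of the primary source does not strip it, and the alternating polarity keeps
the spike-locked *power* (what the constraint measures) while cancelling the
correlation with the primary source, so the remnant does not tilt the first
extraction either.

`gen_four_conditions()` emulates the four-condition comparison: all
conditions share the SW topography; *post-real* thins the event rate ~10×
and moves an ongoing source-to-background drive from beta (20 Hz) to theta
range (4 Hz); the other three are statistically identical to *pre-real* up
to seed. The drive is a unidirectional AR pair (`gen_coupled_ar()`): a
resonant AR(2) driver (poles at radius 0.95 at 250 Hz; at other rates the
radius is Q-matched as $0.95^{250/f_s}$ so the resonance bandwidth in Hz is
unchanged) coupled at lag 2 into a damped AR(1) receiver, injected at 6 µV
into the SW source and into both background sources respectively — the
received drive lives in the whole non-epileptogenic background, so it is
captured regardless of which background pattern the second extraction
converges to.

At these settings (chosen once as a realistic emulation and then left
alone), the pipeline exhibits the qualitative pattern the method is meant to
detect: the epileptogenic source's mean HFD rises selectively post-real
(sparse transients leave the broadband baseline exposed) while the
remaining-brain source's HFD stays flat across conditions, and the
epileptogenic-to-residual DTF peak sits in beta pre-real and below 8 Hz
post-real.

What the generator does *not* emulate: real scalp EEG's nonstationarity,
artifacts (the pipeline consumes cleaned EEG; artifact-removal ICA is
upstream and out of scope), volume-conduction geometry beyond a smooth
topography, electrode drift between sessions, and biophysics of stimulation.
Passing tests therefore demonstrate correctness of the algorithms and
recoverability under the stated mixture model, not clinical performance.

## Numerical and interface decisions

* Marker times are continuous seconds; sample `i` covers `[i/fs, (i+1)/fs)`;
  conversion rounds half away from zero; all intervals are half-open — one
  deterministic convention end to end.
* The Gaussian expectation in the negentropy contrast,
  `E[log cosh ν] ≈ 0.3745672`, is computed by adaptive quadrature, not
  hard-coded folklore.
* Whitening retains eigenvalues above `1e-10` of the largest by default
  (full rank for full-rank data); rank-reduced whitening handles
  average-referenced or residualized data.
* Degenerate inputs fail loudly: constant series in HFD, empty constraint
  windows, identical DTF inputs (singular lag covariance), non-finite
  samples — each names the offending object.
* Extraction determinism: identical inputs and seed give bit-identical
  `w`, `a`, `s`; the pipeline re-run is byte-identical including written
  reports (filenames carry a config hash).
* Problem sizes used by the test-bench: 120-s conditions for the
  pipeline-level checks (the generator default; tens of SW events per the
  emulated design), 30–60 s with a shortened cooling schedule for unit-level
  checks of the optimizer plumbing; the end-to-end suite check runs a
  mid-weight schedule (3 restarts, stop temperature 0.01), and the
  reproduction script runs the full default schedule. The sweep over λ uses the shortened
  schedule with shared seeds, with a 5 % slack absorbing optimizer jitter
  near the flat constrained optimum.
* Supported interchange formats are plain text: the metadata-headed EEG CSV
  and one-timestamp-per-line marker files. They round-trip exactly and keep
  the toolchain self-contained; no binary EEG container is read or written.
* Spike markers are an *input* (clinical practice marks them by review);
  the package ships no automatic spike detector.

## Limitations

* One source per extraction, two sources per analysis (the sequential
  design); no simultaneous multi-source unmixing.
* `lambda` is transferable only under the unit-variance normalization of
  both cost terms; feeding unnormalized constraints would silently change
  its meaning.
* The annealer is stochastic: different seeds can land on mirror-image or
  slightly different optima; restarts mitigate, determinism under a fixed
  seed makes it reproducible.
* DTF inherits MVAR assumptions (linearity, segment-stationarity); no
  significance testing of connectivity values is provided.
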