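# epinet

Characterization of an epileptogenic network from multichannel resting EEG:
constrained source extraction, complexity quantification, and directed
connectivity, with a ground-truthed synthetic-EEG test bench.

## Who this is for

Clinical neurophysiology and EEG-methods researchers who have a resting
multichannel recording (typically 19 channels, 10-20 montage) containing
recurrent interictal spike-and-wave (SW) discharges with marked spike-apex
times, and who want to (i) isolate the source generating those discharges,
(ii) track the complexity of its activity across experimental conditions
(e.g. before/after neuromodulation), and (iii) measure frequency-resolved
directed influence between that source and the rest of the brain.

## The methods

**Functional Source Separation (FSS).** One-unit ICA with a functional
fingerprint: over unit-norm spatial filters `w̃` in whitened space, maximize

    F(w̃) = J(w̃ᵀz) + λ · R(w̃ᵀz),        λ = 1000 by default

where `J` is the log-cosh negentropy approximation of FastICA and `R` is the
mean power of the candidate source in the 4 ms windows preceding each marked
spike apex. Optimization is by simulated annealing (T₀ = 1000, geometric
cooling, restarts), which makes the fit robust to the multimodal constrained
landscape and bit-reproducible under a seed. The fit yields the source time
course `FS(t)`, the spatial filter `W`, and the scalp topography `A`;
removing the rank-1 contribution `A·FS(t)` and re-running the same
extraction on the residual yields the remaining-brain source `FS_rp`.

**Higuchi fractal dimension (HFD).** Signal complexity in [1, 2] from the
scaling of Higuchi's mean curve length `L(k) ~ k^(-D)`, fitted over
`k = 1..kmax` (default `kmax = 40`, chosen via a 1–100 sweep diagnostic),
computed in 1-s non-overlapping windows and averaged.

**Directed Transfer Function (DTF).** Both sources are decimated to 250 Hz,
cut into 20-s segments, and each segment fits an MVAR model (least squares,
AIC order selection, stability checked). From the transfer matrix
`H(f) = (I − Σ A_k e^(−2πifk/fs))⁻¹`, the row-normalized inflow fraction

    γ²(i←j, f) = |H_ij(f)|² / Σ_m |H_im(f)|²

is averaged over stable segments on a 0–125 Hz grid, with EEG band
summaries.

## Worked example

Everything below is synthetic — the generator embeds a known SW source
through a known topography, so recovery can be verified exactly.

```r
library(epinet)

mix <- gen_mixture(sw_config(seed = 3))        # 19 ch, 1000 Hz, 120 s
fit <- fss(mix$recording, mix$markers, fss_config(seed = 7))
fit
#> <fss> FS_Epi: constrained-ICA source from 19 channels, 120000 samples
#>   lambda = 1000, 59 constraint windows
#>   cost = 22368.4  (J = 0.00144, R = 22.37)
#>   topography peaks at: T4, C4, F8
cor(coef(fit), mix$truth$a_true)               # topography recovery
#> [1] 0.999
cor(fit$s, mix$truth$s_true)                   # time-course recovery
#> [1] 0.964

h <- hfd_windowed(fit$s, fs = 1000, kmax = 40)
h
#> <hfd_result> mean HFD = 1.8482 over 120 windows of 1 s (kmax = 40)

rp <- fss(residuals(fit), mix$markers, fss_config(seed = 8), label = "FS_rp")
d <- dtf(fit$s, rp$s, fs = 1000)               # 250 Hz, 20-s segments
d$band_summary
```

The printed cost decomposition shows the constrained optimum: `R` is the
spike-locked window power of the unit-variance source (about 22 means the
4-ms pre-spike windows carry ~22× the average power), and `J` its
negentropy. The topography peaking at T4 matches the focal generator the
data were built with.

The four-condition comparison (before/after real and sham stimulation) runs
end to end with

```r
four <- gen_four_conditions(sw_config(seed = 1))
bundle <- run_pipeline(lapply(four, `[[`, "recording"),
                       four$pre_real$markers, reference = "pre_real",
                       fss_cfg = fss_config(seed = 2),
                       out_dir = "reports", seed = 2)
bundle$hfd$summary        # mean HFD per condition and source
bundle$dtf_band_summary   # directed inflow per band
```

which extracts the two sources on the reference condition, projects the
time-invariant filters onto every condition, and writes HFD/DTF tables plus
a provenance JSON (config hash, seeds, timings) to `reports/`.

A thin command-line front end (`inst/cli/epinet.R`) wraps the same
functions: `simulate`, `extract`, `hfd`, `dtf`, and `run` with a YAML
config.

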