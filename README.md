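# dnacurtains

Simulation and analysis of single-molecule **DNA curtain** experiments on
engineered bacteriophage λ substrates.

DNA curtains arrange hundreds of tethered, flow-aligned λ-DNA molecules
(48.5 kb ≈ 13 µm at ~80% extension) at microfabricated chromium barriers for
TIRF imaging of individual DNA-bound proteins. Experiments on *modified*
λ-DNA — recombineered insertion cassettes at three sites (21.3, 33.5 and
45.3 kb from *cosL*) and nicking-cassette oligo replacements carrying
extrahelical structures (5′-ssDNA flaps, (CAG)₁₃ repeats) — ask where
proteins load, how they slide, and how long they stay. This package provides
the full computational layer for such studies, aimed at single-molecule
biophysicists who need a tested, reproducible pipeline and a synthetic-data
generator for validating it:

* **Substrate modeling** — λ genome maps with cassettes and
  nicking/restriction sites; in-silico duplex digests and denaturing-gel
  strand-fragment predictions; packaging-limit checks (38–53 kb); motif
  scanning on both strands.
* **Synthetic data** — named presets encoding measured experimental
  parameters generate binding-position mixtures (site Gaussians broadened by
  tether-anchor jitter plus uniform background), 1D Brownian sliding
  trajectories with reflecting/trapping site interactions, censored
  exponential dwell times, and rendered 16-bit TIFF movies (pixel-integrated
  Gaussian PSFs, Poisson + read noise).
* **Tracking** — matched-filter spot detection, subpixel 2D Gaussian
  localization, greedy nearest-neighbor trajectory linking with gap closing,
  kymograph extraction.
* **Binding statistics** — µm→kb mapping, 1-kb-binned Gaussian peak fits,
  bootstrap errors, eight-window 5-kb fold-enrichment analysis with Welch
  t-tests and Pearson chi-squared tests.
* **Dynamics** — mean-squared-displacement diffusion estimation,

  MSD(nΔt) = (1/(N−n)) Σᵢ (yᵢ₊ₙ − yᵢ)²,  MSD(Δt) = 2DΔt,

  fitted over the first 10 intervals (Δt = 0.05–0.5 s) with a free intercept
  absorbing localization noise; salt-dependence slopes (sliding vs hopping);
  bypass/blocked/captured encounter classification; and censored
  maximum-likelihood exponential dwell-time fits (rate = events / total time
  on test, t½ = ln 2 · mean).

Everything is tidyverse-native: functions take data frames first, return
tibbles, and chain with the pipe; fitted objects have `tidy()`/`glance()`
methods and `autoplot()` ggplot2 methods.

## Worked example

```r
library(dnacurtains)

# Where does Lac repressor bind on a site-A operator substrate?
lac <- simulate_binding_positions(experiment_preset("LacI_siteA"),
                                  n = 558, seed = 1)
fit_peaks(lac, n_components = 1)
#> <peak_fit> 1 component(s), n = 558, method = binned
#>   center 21.7 kb, sd 1.3 kb, weight 1.00
```

The fitted center, 21.7 kb from *cosL*, is the engineered operator position;
the ~1.3 kb width is dominated by tether-anchor jitter across the ~1.25-µm
barrier, not by localization error.

```r
# Is clamp loading enriched at a 5'-flap relative to homoduplex DNA?
flap <- simulate_binding_positions(experiment_preset("yPCNA_flap"),
                                   n = 500, seed = 1)
homo <- simulate_binding_positions(experiment_preset("yPCNA_homoduplex"),
                                   n = 500, seed = 2)
glance(window_enrichment(flap, homo))$fold
#> [1] 2.20339
```

A fold of 2.2 means the 5-kb window centered on the cassette holds 2.2 times
the normalized molecule frequency on the flap substrate than the same window
on homoduplex DNA (single draws at n = 500 scatter around the preset's
design value of 2.7 with SD ≈ 0.4; `bootstrap_fold()` quantifies this).

```r
# How long does Lac repressor stay bound after IPTG injection?
d <- simulate_dwell_times(t_half = 21, n = 63, t_obs = 300, seed = 1)
tidy(fit_survival(d))
#> # A tibble: 1 × 4
#>   term     estimate conf.low conf.high
#> 1 t_half_s     20.3     15.8      25.1
```

The censored-MLE half-life (20.3 s, bootstrap 95% CI 15.8–25.1 s) recovers
the 21-s simulation input at n = 63.

```r
# Diffusion coefficient of a sliding clamp from one trajectory
tr <- simulate_trajectory(experiment_preset("yPCNA_homoduplex"), D = 0.3,
                          n_frames = 1200, start_um = 6.5, seed = 1)
estimate_D(compute_msd(tr, n_max = 10))
#> # A tibble: 1 × 6
#>   D_um2_s slope intercept se_slope n_max clamped
#> 1   0.261 0.521    0.0113  0.00481    10 FALSE
```

End-to-end runs (`simulate → analyze → report`) go through
`run_scenario(scenario_config("yPCNA_flap", seed = 1))`, which returns a
deterministic report embedding every parameter and per-stage seed;
`write_scenario_report()` writes a JSON + CSV bundle.

## Vignette

`vignettes/dnacurtains.Rmd` documents the models and their assumptions, the
preset parameters and where each comes from, what the synthetic-data
generator does and does not emulate, numerical choices, and known
limitations.
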