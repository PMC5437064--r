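---
title: "Models and methods behind dnacurtains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dnacurtains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnacurtains)
```

This vignette is the package's own account of its science: the models each
module implements, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices a maintainer would want to know about. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The experimental system

A DNA curtain tethers hundreds of bacteriophage λ genomes (48,502 bp) on a
fluid lipid bilayer, aligns them at a microfabricated chromium barrier, and
images fluorescently labeled DNA-bound proteins by TIRF microscopy at 50-ms
frames. In the double-tethered geometry, the DNA spans the ~13 µm between a
barrier and a pedestal (~80% of the B-form contour length), so proteins
diffuse in one dimension without flow bias. Engineered substrates carry
insertion cassettes at three sites (21.3, 33.5 and 45.3 kb from the *cosL*
end, inside dispensable segments of the phage genome) and, via a three-nick
nicking cassette, synthetic oligonucleotides bearing extrahelical structures
such as a 30-nt 5′-ssDNA flap or a (CAG)₁₃ triplet repeat.

## Substrate model

A `genome_map` is a total length plus a feature table in 0-based, half-open
bp coordinates from *cosL*; reported kb values are bp/1000 rounded to 0.1.
One coordinate convention is enforced everywhere because gel figures and
text in this field freely mix rounded kb values.

`insert_cassette()` replaces a native interval centered on a target site and
shifts downstream coordinates; substrates must stay within the λ packaging
limits of 38–53 kb (78–105% of wild type), and the check is monotone by
construction. `digest_duplex()` turns a boundary set
`{0} ∪ (cuts − abolished) ∪ {length}` into fragment lengths, which always sum
to the substrate length — the property the diagnostic NcoI assay exploits:
the flap insert abolishes the flap-proximal NcoI site at the cassette,
merging the 0.8- and 2.0-kb diagnostic fragments into one 2.8-kb band. Exact
genomic coordinates for that NcoI pair are not available; the default site-A
model places cut boundaries at 20,500/21,300/23,300 bp, which reproduces the
measured fragment sizes exactly.

`predict_strand_fragments()` models the denaturing-gel readout of nicked,
oligo-replaced substrates. The bottom strand is never nicked (one full-length
fragment). A mock insert (perfectly complementary, fully re-ligated) restores
a full-length top strand; a flap or gap insert leaves discontinuities at the
outer nicks, so the top strand runs as the two flanking fragments. With the
default site-A cassette (nicks at 21,300/21,319/21,339 bp; 39 nt excised)
the exact predictions are 21,300 and 27,163 bp. Gel-annotated values for the
second fragment round to ~26.7 kb, a ~0.5-kb discrepancy against the 48.5-kb
total that is inherent to gel sizing; the package always reports the exact
arithmetic values.

`scan_recognition_sites()` (Biostrings-backed) reports motif occurrences on
both strands in top-strand coordinates. Nickase site counts are reported both
ways — all-strand and nick-relevant-strand — because "number of sites" is
ambiguous for a nicking enzyme; IUPAC ambiguity codes are rejected so counts
are deterministic. Nt.BspQI nicks 1 nt 3′ of its GCTCTTC recognition
sequence on the motif-bearing strand; the offset is configurable since
different nickases differ.

## Synthetic-data generator

Named presets (`experiment_preset()`) encode one measured condition each.
The generator's role is to produce data with the statistical structure the
analyses assume, with known ground truth.

**Binding positions** are i.i.d. draws from a mixture: site components plus
a uniform background over the 48.5-kb substrate (out-of-range draws are
redrawn). Histograms assume every molecule is anchored at the barrier
*center*, but the true anchor is uniform across the ~1–1.5 µm barrier; this
anchor jitter is the dominant broadening of binding histograms and the
generator reproduces it explicitly. Each site component is

> center + Uniform(−j/2, +j/2) + Normal(0, s),

where the jitter width *j* defaults to 1.25 µm (the midpoint of the quoted
barrier range) converted to kb, and the residual *s* is chosen so the
component's **total** sd equals the preset's measured histogram width (e.g.
21.7 ± 1.0 kb for the site-A operator; 21.2 ± 1.4 kb for the flap). When the
measured total sd is below the jitter's own sd, the jitter width is shrunk
to match — the measured width is the ground truth, the jitter the mechanism.

The flap and (CAG)₁₃ presets' site weights are not directly measured;
what is measured is the **fold enrichment** in the 5-kb target window (2.7×
and 1.5× over homoduplex). The constructor solves the weight in closed form,
`w = u(f − 1)/(q − u)`, from the uniform window mass `u = 5/48.502` and the
site component's analytically integrated capture fraction `q` in the target
window. This is a calibration to published summary statistics, computed at
construction time, not a tuned constant.

**Trajectories** are discrete Brownian walks with per-step displacement
Normal(0, 2DΔt) at Δt = 0.05 s, folded into `[0, 13 µm]` by reflection.
Site interactions: `reflecting` confines the walker to its starting side of
the site (a structure too large to pass through the clamp's pore);
`trapping` pins it at the site. Independent Gaussian localization noise
(default sd 30 nm, typical of quantum-dot tracking; the true experimental
precision is unreported, so this is a declared default, not an inference) is
added per frame and re-reflected so positions never leave the tether.
Photobleaching and quantum-dot blinking are deliberately omitted.

**Dwell times** are exponential with mean t½/ln 2; values beyond the
observation window are right-censored at the window. The IPTG-chase presets
(t½ = 21 and 22 s at n = 63 and 56) use a 300-s window (≥10 half-lives,
negligible censoring); the no-IPTG control (t½ = 327 s, n = 49) uses 1800 s
(≈2% censoring). The windows are design choices — the original acquisition
lengths are unpublished — and both are configurable.

**Salt series.** The measured ionic-strength dependence of the sliding
clamp's diffusion coefficient is 0.25 µm² s⁻¹ mM⁻¹ (weak dependence, the
sliding signature). The preset encodes D(c) = D₀ + 0.25·(c − 50 mM) with
D₀ = 0.3 µm²/s and concentrations 50/51/52 mM: the narrow range keeps D
within the regime where a 13-µm tether still looks unconfined over the first
ten MSD intervals, so the recovered slope reflects the encoded slope rather
than boundary attenuation. Thirty molecules of 1200 frames per concentration
match the "≥30 molecules per concentration" design.

**Behavior fixtures** use exact category counts (flap: 36 blocked /
2 captured / 2 bypass of 40; (CAG)₁₃: 11 of 36 captured; homoduplex: mostly
bypass), not probabilistic draws, so classification percentages are
deterministic. Counts not published (the (CAG)₁₃ blocked/bypass split, the
homoduplex split) were fixed once at plausible values (23/2 and 38/1/1).
Paths are idealized shapes (approach-and-reverse, pinned, steady crossing)
plus i.i.d. localization noise, so the classifier's output on them is
unambiguous.

**Rendering.** Emitters are symmetric 2D Gaussian PSFs *integrated over
pixels* (σ = 1.1 px at 0.267 µm/px — a 60× / EMCCD scale; the 1.1-px width
reflects the finite quantum-dot size and modest defocus rather than the
diffraction limit alone), 1000 detected photons per 50-ms frame over a
10-photon background, Poisson shot noise plus Gaussian read noise (sd 2),
floored and rounded as 16-bit counts. Stacks write/read as uncompressed
multi-page TIFF.

What the generator does **not** emulate: flow-extension hydrodynamics and
DNA fluctuation dynamics, fluorophore photophysics, camera EM-gain noise
statistics, stage drift, and nonspecific surface binding. Passing tests
therefore validate the *estimators* against their assumed data structure;
they do not certify performance on real movies where those effects matter.

## Tracking

Detection smooths each frame with a Gaussian matched filter (the PSF sigma)
— the standard pre-step that suppresses single-pixel shot noise — then takes
strict 8-neighborhood local maxima above `median + k·MAD` of the smoothed
frame (default k = 6), with non-maximum suppression within one PSF radius.
Localization fits a pixel-integrated symmetric 2D Gaussian plus constant
offset by Levenberg–Marquardt least squares in an 11×11 ROI (roi_half = 5);
failures are returned flagged (`no_signal`, `no_convergence`), never
dropped silently. Because the fit model matches the renderer's pixel
integration, noiseless PSFs localize to machine precision and localization
is exactly translation-equivariant for whole-pixel shifts.

Linking is greedy nearest-neighbor (default gate 5 px per elapsed frame,
ties broken by smaller displacement then lower track id), bridging gaps up
to 1 frame without interpolating rows. Greedy linking was chosen over global
assignment for determinism and simplicity at curtain densities, where
molecules live on separate image rows; it will mislink at high densities.
The gating and gap defaults are declared choices — the original analysis
used an unpublished custom tracker.

## Binding statistics

Positions convert from µm to kb with the fixed scale 13 µm / 48.502 kb
(~0.268 µm/kb), assuming anchors at the barrier center; positions mapping
beyond the substrate plus 2 kb are flagged off-DNA. Peak fitting operates on
1-kb-binned histograms (the field's presentation) by least squares with one
or two Gaussians plus a constant background; bins are aligned so centers
fall on integer kb, and a raw-sample maximum-likelihood fit (mclust) is
available as an option. Degenerate zero-variance samples return the center
with sd flagged 0 and no fit. A capture-fraction report for any window can be
computed from the fitted component; the package deliberately does not
hard-code a "99% within 5 kb" claim because the sd multiple behind such
statements is convention-dependent.

The enrichment statistic divides the substrate into eight contiguous 5-kb
windows. A 48.5-kb substrate admits nine full windows, so the published
"eight windows" description is underdetermined; the default layout spans
3.8–43.8 kb with the target window re-centered on the site-A cassette
(18.8–23.8 kb), and both the layout and target are configurable. Per-window
frequencies are normalized by each substrate's total molecule count; the
fold is the target-window frequency ratio (modified / reference), undefined
(reported as such) if the reference window is empty. Errors come from
bootstrap resampling with replacement (`bootstrap_stat()`,
`bootstrap_fold()`, percentile CIs). Hypothesis tests: Welch's
unequal-variance two-tailed t-test ("two-tailed t test" alone does not pin
the variance assumption; Welch is the safer default) with an exact
permutation fallback when both groups are numerically zero-variance, and
Pearson's chi-squared without continuity correction for behavior-count
tables. No multiple-testing correction is applied: the target-window
comparison is a single pre-specified test.

## Dynamics

`compute_msd()` evaluates the time-averaged MSD with overlapping
displacements — the estimator's index range forces overlap — and
`estimate_D()` fits an ordinary least-squares line to the first 10 intervals
(0.05–0.5 s), with D = slope/2. The fit keeps a **free intercept** by
default: static localization noise adds a constant offset (~2σ²) to every
MSD point, and a free intercept absorbs it, leaving the slope unbiased; a
through-origin mode is provided since the original fitting convention is
unstated. Negative slopes clamp to D = 0 with a flag. No correction is made
for the correlation between overlapping MSD points in per-molecule errors;
as in practice, molecule-to-molecule spread is the error estimate, and
`salt_slope()` fits mean D vs concentration by weighted (1/SE²) least
squares.

Behavior classification uses a ±1.5-kb tolerance zone around the site and a
0.25-kb stationarity threshold (both configurable): `captured` if loaded
within the zone and stationary over the whole record; else `bypass` if both
flanks beyond the zone are visited; else `blocked` if the zone was entered;
else `no_encounter`. Precedence captured > bypass > blocked resolves
ambiguous records deterministically.

Dwell-time fitting is the censored exponential MLE: rate = events / total
observed time (the total-time-on-test estimator, exactly the
Kaplan-Meier-consistent exponential estimate), t½ = ln 2 / rate, with a
percentile bootstrap 95% CI over molecules; a least-squares fit to the
empirical survival curve is available for comparison. Records touching the
observation boundary are censored; at least five uncensored events are
required, and all-censored samples are an explicit error.

## Scenarios and reproducibility

`run_scenario()` chains the stages appropriate to a preset (binding →
peak fit → enrichment; dwell → survival fit; salt → per-molecule D → slope;
behavior → classification → percentages) and returns a report embedding the
full parameter set and every derived stage seed. One master seed drives a
named per-stage sequence via a fixed affine hash (`derive_seed()`), so any
stage can be re-run in isolation and identical configs yield byte-identical
report bundles.

## Problem sizes and verification

The test suite verifies each estimator against an independent oracle:
brute-force double-strand scans for motif search, a brute-force double loop
for the MSD, closed-form Welch/chi-squared/exponential-MLE formulas, the
renderer's ground truth for localization, and survreg's exponential fit for
the censored MLE. Stochastic checks run at the study's own sample sizes
(n = 558/500/63/49 molecules; 200 trajectories of 2000 frames for estimator
bias; 200 seeded replicates for dwell recovery; 30 molecules × 3 salt
levels), sizes chosen so the whole suite completes in well under a minute of
compute per module while keeping Monte-Carlo error far below the asserted
tolerances.

## Known limitations

* The wild-type λ genome sequence is not bundled; genome-wide nickase-site
  counts run on user-supplied FASTA or on synthetic sequences with planted
  sites.
* Peak fits on binned counts inherit ~bin-width/√n center precision; the MLE
  option avoids binning but assumes a pure Gaussian mixture (no uniform
  background component).
* The tracker has no drift correction or multi-channel registration and is
  not designed for dense fields.
* At high D on a finite tether, boundary reflections attenuate the MSD
  slope; diffusion coefficients approaching the confinement regime are
  underestimated, which is a property of the measurement geometry, not of
  the estimator.
* Anomalous-diffusion exponents, HMM state segmentation, and microscopic
  hopping/sliding models beyond the salt-slope readout are out of scope.
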