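---
title: "Models and methods behind poretrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poretrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretrack)
```

poretrack analyses single-molecule fluorescence data of DNA nanopores
interacting with polymer-supported lipid membranes: where the pores are,
how they move, how many sit in one diffraction-limited spot, whether
cluster positions persist over time, and how fast pores bind to and leave
the membrane. This vignette describes the models, the tunable parameters,
the synthetic-data generator used to validate every stage, and the design
choices made where the methods left room.

## Coordinate and unit conventions

All positions are in micrometres with the origin at the field corner;
pixel *(i, j)* spans the half-open square `[i*px, (i+1)*px)` with
`px = 0.107` µm by default. Frames are 0-based. Times are seconds
(default frame interval 19 ms), photon quantities are photons per frame.
Lengths reported to the user in nanometres (FWHM, PICCS correlation
length) are labelled `_nm` explicitly.

## Localization and TALM rendering

Emitters are detected per frame by difference-of-Gaussians band-pass
filtering (inner scale = PSF sigma, outer scale twice that), local maxima
above `mean + 4·MAD` of the filtered frame, and merging of maxima closer
than two PSF sigmas (brightest kept). Each candidate is refined by
least-squares fitting of an *integrated* 2D Gaussian — the PSF integrated
over each pixel — which keeps the fit unbiased at sub-pixel positions.
The per-localization precision estimate uses the Thompson photon formula
`var = (s² + a²/12)/N + 8πs⁴b/(a²N²)` with PSF width `s`, pixel size `a`,
photon count `N` and background variance `b`. On noiseless symmetric
spots the fit is exact to solver tolerance (a quasi-Newton refinement
follows the simplex stage); with shot noise the empirical spread runs
about 1.2–1.3× this bound, as expected for least squares relative to the
information limit.

Super-resolution (TALM) images superimpose all localizations either as a
2D histogram — total mass then equals the localization count exactly —
or as unit-mass Gaussians of each localization's precision. Transverse
profiles of linear structures are fitted on the *raw projected
localizations*, not the rendered image, to avoid bin-width bias; the
FWHM is `2·sqrt(2·ln 2)·σ ≈ 2.3548·σ`. For a tube of diameter *d* the
projected transverse variance is `d²/8`, so the measured width is the
convolution `sqrt(σ_loc² + d²/8)`; `deconvolve_width()` inverts this
model but the package makes no claim beyond it.

## Trajectories and mobility

Linking minimizes total squared displacement per frame pair by optimal
bipartite assignment (a Hungarian solver written for this package, tested
against brute-force enumeration), with track birth/death entering the
cost matrix as alternatives and gap closing up to `max_gap` missed
frames. Merge/split events are not modelled: at the picomolar labelling
densities this pipeline targets, such events are rare, and the simple
assignment reproduces the behaviour of full cost-matrix trackers.

Immobile emitters are removed before tracking by DBSCAN on positions
pooled over 100-frame windows (`eps = 3σ_loc`, `min_samples = 10`),
because an immobile particle's localizations form a precision-limited
cloud while a mobile particle at `D = 2.5 µm²/s` hops ~435 nm between
frames. Clusters must persist ≥ 50 frames to count as immobile. Per-
trajectory mobility is classified by the MSD-fitted diffusion
coefficient against a threshold of 0.05 µm²/s — an order of magnitude
below the slow membrane-spanning population (1 µm²/s) and above the
apparent D produced by pure localization noise (`σ_loc²/Δt ≈ 0.019
µm²/s`). Trajectories shorter than five frames stay unclassified. Spatiotemporal-identification
approaches in the tracking literature do not share a single fixed
criterion; this threshold rule is the package's documented choice,
validated on synthetic data.

Dual-colour registration uses the closed-form (SVD) least-squares rigid
transform from matched fiducials; co-localization uses *mutual* nearest
neighbours within 107 nm (one pixel), compared on squared distances so
the boundary case is included deterministically. Mutual matching
prevents one bright spot from absorbing several partners.

## Diffusion analysis

For free Brownian motion observed with localization precision ε the MSD
is `MSD(t) = d(2Dt + 2ε²)` in *d* dimensions. `compute_msd()` pools
squared jump magnitudes over trajectories per lag; `fit_msd()` fits the
linear model by weighted least squares (weights = jump counts), flooring
D and ε at zero with a flag. Default fit windows follow the measurement
convention: lags 1–5 (first 100 ms) for 1D nanotube diffusion, lags
10–50 (200–1000 ms) for planar membranes. The intercept term `2dε²` is
only ~2 % of the lag-1 MSD at `D = 1 µm²/s`, so single-run ε estimates
are variance-limited; recovery tests average over acquisitions.

Jump-magnitude distributions at one lag resolve diffusive
subpopulations. With the per-dimension scale `v = 2(DΔt + ε²)` the
magnitude density is half-normal in 1D,
`P(x) = sqrt(2/(πv))·exp(−x²/(2v))`, and Rayleigh in 2D,
`P(x) = (x/v)·exp(−x²/(2v))`. A symbol subtlety decided here: the "MSD"
appearing inside these densities must denote the *per-dimension*
quantity `2(DΔt + ε²)`; reading it as the full 2D MSD (`4DΔt`) would
double the variance. The package adopts the per-dimension reading and
verifies it by simulation — the empirical per-coordinate jump variance
of simulated data matches `2(DΔt + ε²)` within three standard errors.

Mixtures are fitted by maximum likelihood (EM with a quantile-based
start plus random restarts) rather than histogram least squares: the MLE
is bin-free and better behaved at small n; a histogram variant is kept
for parity with binned step-length fitting. ε is shared across
components (one optical precision per dataset) and must be supplied —
at a single lag only the scales `v_i` are identifiable, so D_i is
derived as `(v_i/2 − ε²)/Δt`, floored at zero. Model order can be
selected by BIC across 1–3 components. Intensity-based oligomer analysis
divides each trajectory's median intensity by a single-fluorophore
reference and partitions trajectories into diffusion regimes.

## Photobleaching step counting

Intensity traces of immobile spots are modelled as piecewise-constant
signals in Gaussian noise. Segmentation is recursive: each segment is
split at the point maximizing the two-sample t statistic, with the noise
amplitude estimated once, robustly, from the median absolute first
difference divided by `sqrt(2)·0.6745` — a Haar-type estimator that the
steps themselves cannot inflate. The segment with the largest |t| is
always split next (ties to the earliest frame); splitting stops when no
segment exceeds the critical value for a 2 % false-positive probability,
Bonferroni-corrected over that segment's candidate split points.

Segment means are then merged agglomeratively and the number of states
is chosen by minimum description length,

```
MDL = RSS/(2σ²) + ((n_states + n_changepoints)/2)·log N ,
```

restricted to groupings whose state levels differ by at least 70
photons (one state is always admissible). The exact MDL constants are
held fixed; an exhaustive-search oracle in the test suite minimizes the
same objective and must agree with the two-phase search on short traces.

Counting applies three filters in order: dwells shorter than 50 frames
whose entering and leaving transitions have *opposite* sign (blinks,
diffusion spikes) are removed by merging into the preceding level;
successive downward steps closer than 6 frames merge into one event; and
counting runs over the strictly decaying part only — from the first
dwell at the maximum state to the first upward transition. The 50-frame
dwell filter deliberately spares monotone staircase dwells: with
exponential bleaching lifetimes a substantial fraction of inter-bleach
gaps is shorter than 50 frames, and removing those would merge genuine
successive bleaching events that the 6-frame lag rule is meant to govern.
On pure-noise traces the full chain (segmentation + filters) reports a
step in under 5 % of traces.

## PICCS

The spatial persistence of immobile clusters between two time points is
quantified by the cumulative cross-correlation `C_cum(r)`: the mean
number of second-pattern points within r of a first-pattern point, with
edge effects handled by excluding first-pattern points within the
maximal radius of the field border (exact, and adequate for simulated
and cropped fields). For a correlated fraction α displaced by an
isotropic Gaussian of per-coordinate scale σ_c over an uncorrelated
background of density ρ,

```
C_cum(r) = α(1 − exp(−r²/(2σ_c²))) + ρπr² .
```

The long-range regime (`r ≥ 3·σ_guess`, capped at half the maximal
radius) is fitted linearly against `πr²` — slope ρ, intercept α — and
the short-range residual is fitted with the Gaussian kernel for σ_c
(bounded `port` fit). The window is *not* re-derived from the fitted σ_c
by default: iterating couples the window choice to noise in the
short-range fit and skews the null distribution of α; with a sensible
`sigma_guess` a single pass is unbiased under complete spatial
randomness. Significance is assessed by Monte Carlo: the second pattern
is resampled as CSR at matched density and the 2.5/97.5 percentiles of
the refitted α form a 95 % confidence band.

## Binding kinetics and surface density

Pseudo-first-order surface binding at constant analyte concentration C
gives an association phase `R(t) = Req(1 − e^{−k_obs t})` with
`k_obs = k_a·C + k_d` and a dissociation phase `R(t) = R₀e^{−k_d t}`.
The phases are fitted separately and sequentially — dissociation first,
then association with k_d fixed — matching how flow-cell experiments are
evaluated; a global simultaneous fit is available as an option. Then
`k_a = (k_obs − k_d)/C` and `K_D = k_d/k_a`. When `k_obs ≤ k_d` (no
measurable concentration dependence) k_a is flagged non-identifiable
rather than forced. Note that k_a inherits an amplified error whenever
`k_a·C ≪ k_d`; the round-trip tests cover k_a over 10³–10⁷ M⁻¹s⁻¹ at
tolerances reflecting this conditioning.

Mass signals convert to molecular surface densities as
`density = mass·N_A/M` (0.8 ng/mm² of a 96 kDa assembly ≈ 5.0×10³ µm⁻²,
one molecule per ~14.1 nm square). The pore molar mass is computed by
`oligo_molar_mass()` from a strand-composition table; the table shipped
in `inst/extdata/np3c_strands_synthetic.csv` is a *synthetic* stand-in
(12 strands of 26 nt, balanced composition, ≈ 95.9 kDa) constructed to
match the six-duplex pore architecture, since the original strand list
is not redistributable here.

## The synthetic-data generator

Every analysis stage is validated against `sim_*()` generators whose
defaults are the study conditions: 107 nm pixels, 19 ms frames, 19/25 nm
localization precisions, 30-frame trajectories, two mobile populations
at 2.5 and 1.0 µm²/s, nanotubes of 16 nm diameter probed at 1 µm²/s,
bleaching steps of 500 photons with exponential lifetimes of mean 150
frames (chosen so the 50-frame dwell filter is actually exercised),
cluster patterns at ~2 µm⁻² with a 9.2 % persisting fraction jittered by
22.5 nm, and binding curves at `k_a = 1.5×10⁵ M⁻¹s⁻¹`,
`k_d = 4.1×10⁻⁴ s⁻¹`, 100 nM. Emitter brightness (500 photons/frame) and
background (10 photons/px/frame) are assumptions — the source
measurements do not state them — set so that a 70-photon state
separation is a sub-level quantity. PSF sigma defaults to 1.2 px
(≈ 128 nm), typical for a ×150/1.45 NA objective at 670 nm. Nanotube
ends reflect rather than absorb, matching finite tubes with bouncing
ends.

What the generator does *not* emulate — and hence what green tests do
not show about real data: detector EM gain and read noise, PSF
aberrations and astigmatism, stage drift, fluorophore blinking kinetics
beyond simple two-state bleaching, incomplete labelling, anomalous
(α ≠ 1) diffusion, and merge/split events in dense fields. Conclusions
about those regimes need real calibration data.

Reproducibility: a fixed `rng_seed` in `acq_config()` makes every
generator byte-reproducible; the pipeline derives per-stage seeds from
one master seed, and re-running `run_pipeline()` with the same
configuration yields a byte-identical JSON report.

## Problem sizes used in validation

Recovery tests use 2000 trajectories × 30 frames for the planar mixture
(≈ 58 000 jumps), 700 × 30 for nanotubes, 150–200 traces of 1200–1500
frames for step counting, 50 × 50 µm pattern pairs at 2 µm⁻² (≈ 5000
points) averaged over 10 seeds for PICCS, and 441-point binding curves.
These sizes put Monte Carlo error comfortably inside the stated
recovery tolerances (15 % for mixture components, 3× the reported
uncertainty for PICCS, 0.1 %/5 % for noiseless/noisy kinetics) while the
whole suite runs in minutes on one CPU.

## Known limitations

* The detector is a standard DoG + Gaussian-fit scheme, not a
  reimplementation of the published multi-target tracker; likewise the
  linker replaces the full u-track cost-matrix machinery. Both are
  adequate at sparse densities and are validated only there.
* ε and D are not jointly identifiable from a single-lag jump
  distribution; ε must come from configuration or an MSD intercept.
* Step counts are not corrected for incomplete labelling or undetected
  fast bleaching; they are lower bounds by construction.
* PICCS assumes a Gaussian displacement kernel and margin-excluded
  rectangular fields.
* The surface-density conversion is exact only up to the molar mass
  supplied; the shipped composition table is synthetic (see above).
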