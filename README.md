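# poretrack

Single-molecule analysis for fluorescence imaging of DNA nanopores in
polymer-supported lipid membranes. DNA nanopores — six-helix DNA bundles
with cholesterol anchors — tether to, insert into, cluster within and
even reshape lipid bilayers. Quantifying those behaviours from TIRF
microscopy movies and flow-cell binding data requires a chain of
single-molecule methods, and this package implements that chain
end-to-end for R users:

* **Localization** — difference-of-Gaussians detection and integrated
  2D-Gaussian least-squares fitting of emitters in TIFF stacks, with
  Thompson-formula precision estimates; super-resolution (TALM)
  rendering and transverse FWHM profiling of tubular structures.
* **Tracking** — optimal per-frame assignment (Hungarian algorithm) with
  gap closing; DBSCAN separation of immobile clusters; mobile/immobile
  classification; dual-colour rigid registration, 107 nm mutual
  nearest-neighbour co-localization, and kymographs.
* **Diffusion** — pooled MSD curves with the linear model
  `MSD(t) = d(2Dt + 2ε²)`, and jump-distance mixture fits: half-normal
  (1D, nanotubes) or Rayleigh (2D, planar membranes) densities
  `P(x) = (x/v)·e^(−x²/2v)` with per-dimension scale `v = 2(DΔt + ε²)`,
  fitted by EM with BIC model selection.
* **Step counting** — photobleaching analysis of immobile spots by
  recursive t-test change-point segmentation with a robust (Haar-type)
  noise estimate, MDL state selection with a 70-photon minimum
  separation, blink/dwell filters and a 6-frame event merge
  (STaSI-style).
* **PICCS** — cumulative cross-correlation of point patterns,
  `C_cum(r) = α(1 − e^(−r²/2σ_c²)) + ρπr²`, yielding the correlated
  fraction α and correlation length σ_c, with a Monte Carlo CSR null.
* **Kinetics** — phase-wise pseudo-first-order fits of TIRFS-RIf binding
  curves (`k_obs = k_a·C + k_d`), and conversion of surface mass signals
  to molecular densities.
* **Simulation** — generators for every input type (Brownian mixtures
  with localization noise, nanotube 1D diffusion, PSF-rendered movies,
  bleaching traces, correlated point patterns, binding curves) with
  recorded ground truth, so every stage is validated by recovery tests.

Everything is tibble-first: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on every result type.

## Worked example

Simulate the two-population planar scenario (fast 2.5 µm²/s docked
pores, slow 1.0 µm²/s membrane-spanning pores, 2000 trajectories of 30
frames at 19 ms with 19 nm precision) and resolve the mixture from the
jump-distance distribution:

```r
library(poretrack)

cfg <- acq_config(frame_count = 30, rng_seed = 1)
locs <- sim_planar_trajectories(
  data.frame(D = c(2.5, 1.0), fraction = c(0.5, 0.5)),
  n = 2000, cfg = cfg
)
jumps <- jump_magnitudes(locs, lag = 1, d = 2)
fit <- fit_jump_distribution(jumps, d = 2, n_components = 2,
                             dt = cfg$frame_interval, eps = 0.019)
fit
#> <jump_fit> 2D mle, 2 component(s), n = 58000 jumps
#>       v_um2    weight   D_um2_s
#>  0.09675997 0.4949495 2.5273149
#>  0.03849856 0.5050505 0.9941199
#>   eps = 0.019 um, dt = 0.019 s, logLik = 21395.65, BIC = -42758.40
```

The two fitted components (2.53 and 0.99 µm²/s at weights ≈ 0.5/0.5)
recover the generating coefficients; on real data they separate
membrane-docked from membrane-spanning pores. The surface-density
arithmetic and binding kinetics:

```r
mass <- oligo_molar_mass(system.file("extdata", "np3c_strands_synthetic.csv",
                                     package = "poretrack"))
surface_density(0.8, mass)   # 0.8 ng/mm^2 of ~96 kDa pores
#> # A tibble: 1 × 2
#>   density_um2 area_side_nm
#>         <dbl>        <dbl>
#> 1       5021.         14.1

bc <- sim_binding_curve(1.5e5, 4.1e-4, 1e-7, noise_sigma = 0)
fit_binding_phases(bc)
#> <kinetic_fit> (sequential)
#>   ka    = 1.5e+05 M^-1 s^-1
#>   kd    = 0.00041 s^-1
#>   k_obs = 0.01541 s^-1  (C = 1e-07 M)
#>   KD    = 2.733e-09 M, Req = 0.9734
```

A 0.8 ng/mm² mass signal of a ~96 kDa pore corresponds to ≈ 5000
molecules per µm², one per ~14 nm square; the phase-wise fit returns the
generating rate constants exactly on noiseless input.

`run_pipeline(default_pipeline_config(seed = 1))` chains all stages on
synthetic data and emits a machine-readable JSON report (mobility
fractions, diffusion components, step-count histogram, PICCS α/σ_c,
kinetic constants); re-running with the same seed reproduces the report
byte for byte.

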