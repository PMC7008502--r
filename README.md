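# muellermc

Polarized Monte Carlo simulation and logarithmic Mueller matrix
decomposition for transmission polarimetry of thin turbid slabs — in
particular the optical models used to interpret Mueller-microscopy
measurements of the dermal layer of skin tissue cuts.

## What it does, and for whom

Transmission Mueller microscopy delivers the full 4×4 polarization
transfer matrix **M** of a tissue section, but the raw elements mix
retardance, diattenuation and depolarization and depend on how the sample
was oriented on the stage. `muellermc` is for researchers in tissue
polarimetry / biophotonics who want to

* simulate the transmission Mueller matrix of a slab containing
  monodisperse **spherical** scatterers (cells, organelles — Mie theory)
  and aligned **infinite cylindrical** scatterers (collagen fibrils —
  oblique-incidence scattering-matrix theory) embedded in an isotropic or
  **uniaxial linearly birefringent** host, with polarization-resolved
  (dichroic) extinction for the aligned cylinders;
* analyse measured or simulated matrices with the **logarithmic Mueller
  matrix decomposition (LMMD)**: the principal matrix logarithm
  `L = ln M` split by the metric `G = diag(1,−1,−1,−1)` into
  a polarization part `Lm` (G-antisymmetric) and a depolarization part
  `Lu` (G-symmetric);
* work with the **rotation-invariant** parameter set
  `RT = √(Lm24² + Lm34²)` (total linear retardance),
  `DT = √(Lm12² + Lm13²)` (total linear dichroism), `RC = Lm23`,
  `DC = Lm14`, `αL = (α22+α33)/2`, `α44 = Lu44`, and the anisotropy of
  linear depolarization
  `αLA = ½√((α22−α33)² + (Lu23+Lu32)²)`,
  all unchanged under in-plane sample rotation;
* run the **model-discrimination experiment** that separates the
  sphere–cylinder (SC), sphere–birefringence (SB) and
  sphere–cylinder–birefringence (SCB) models of the dermis: only SCB
  reproduces linear-in-thickness retardance *and* nonzero dichroism *and*
  nonzero anisotropic depolarization simultaneously.

The heavy transport loop is compiled (Rcpp, C++17); results come back as
tibbles with `tidy()`/`glance()` methods and `autoplot()` graphics.

## Worked example

Simulate the SCB dermal model at 15 µm and read off the invariants:

```r
library(muellermc)
cfg <- make_preset("SCB", thickness_um = 15, n_photons = 2e4, seed = 42)
res <- run_simulation(cfg)
print(res, digits = 3)
#> Monte Carlo transmission simulation: d = 15 um, mu_s = 1500 cm^-1, mu_c = 1500 cm^-1, delta_n = 0.009
#>   20000 photons/state in 10 batches, seed 42
#>   photon fates:
#>                   class     n
#>    transmitted_detected 25967
#>  transmitted_undetected     0
#>               reflected 54033
#>                    lost     0
#>   averaged Mueller matrix (normalized):
#>        [,1]   [,2]   [,3]   [,4]
#> [1,]  1.000 -0.134 -0.002  0.016
#> [2,] -0.090  0.320  0.030  0.004
#> [3,] -0.001 -0.008 -0.012  0.188
#> [4,] -0.001 -0.002 -0.180 -0.046
#>   invariants:
#>    RT    DT     RC      DC    aL   a44   aLA imag_residual
#>  1.74 0.191 0.0625 0.00866 -1.34 -1.85 0.183 0
```

Reading the numbers: the slab retards by `RT ≈ 1.74` rad (close to the
ballistic `2π·Δn·d/λ = 1.59` rad plus a small multiple-scattering excess),
the aligned cylinders produce a clear linear dichroism `DT ≈ 0.19` and an
anisotropy of linear depolarization `αLA ≈ 0.18`, circular effects are at
the Monte Carlo noise level (`RC`, `DC` ≈ 0), and circular depolarization
exceeds linear (`|α44| > |αL|`) as expected for sub-wavelength (Rayleigh)
scatterers. An SB run at the same thickness gives the same `RT` but
`DT ≈ 0` and `αLA ≈ 0` — the discrimination signature.

Thickness sweeps and the report:

```r
ds <- seq(3, 24, by = 3)
sweeps <- list(
  SB  = thickness_sweep(make_preset("SB"),  ds, n_photons = 1e5, seed = 11),
  SCB = thickness_sweep(make_preset("SCB", mu_c_cm = 500), ds,
                        n_photons = 2e5, seed = 11)
)
discrimination_report(sweeps)
autoplot(sweeps$SCB)
```

A thin command-line front end is installed under
`system.file("cli", "muellermc", package = "muellermc")` with
`presets`, `simulate`, `sweep`, `report`, `decompose` and
`phase-function` subcommands.

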