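---
title: "Modeling the dermal layer with polarized Monte Carlo and logarithmic Mueller decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the dermal layer with polarized Monte Carlo and logarithmic Mueller decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellermc)
```

## The problem

Transmission Mueller microscopy measures the full 4×4 polarization transfer
matrix of a thin tissue cut. The matrix mixes several physical effects —
retardance from aligned birefringent structures, diattenuation from
oriented scatterers, depolarization from multiple scattering — and the raw
matrix elements additionally depend on how the sample happened to be
oriented on the stage. `muellermc` provides the two tools needed to turn
such measurements into microstructural statements about the dermal layer of
skin tissue:

1. a **polarized Monte Carlo simulator** for slabs containing monodisperse
   spherical scatterers (cells, organelles) and infinitely long aligned
   cylindrical scatterers (collagen fibrils) embedded in an isotropic or
   uniaxial linearly birefringent host medium, and
2. the **logarithmic Mueller matrix decomposition (LMMD)** together with a
   set of **rotation-invariant parameters** that are unaffected by in-plane
   sample orientation.

Three candidate optical models of the dermis are compared: spheres and
cylinders in an isotropic host (SC), spheres in a birefringent host (SB),
and spheres plus cylinders in a birefringent host (SCB). The discrimination
logic is that only SCB reproduces simultaneously a linear growth of
retardance with thickness, nonzero linear dichroism, and a nonzero
*anisotropy* of linear depolarization.

## The decomposition and its invariants

A normalized transmission Mueller matrix ($m_{11}=1$) is decomposed through
its principal matrix logarithm, computed from the complex eigendecomposition
$M = U \Lambda U^{-1}$ as $L = U \ln(\Lambda) U^{-1}$ and realified. $L$
collects the differential optical properties accumulated over the optical
path. With the metric $G = \mathrm{diag}(1,-1,-1,-1)$ it splits exactly into

* $L_m = \tfrac12 (L - G L^T G)$, the G-antisymmetric part: retardance and
  dichroism generators, and
* $L_u = \tfrac12 (L + G L^T G)$, the G-symmetric part: depolarization
  generators.

The elementary coefficients are read off entrywise (`lmmd_coefficients()`):
linear dichroism $LD = L_{m,12}$ and $LD' = L_{m,13}$, circular dichroism
$CD = L_{m,14}$, circular retardance $CB = L_{m,23}$, linear retardance
$LB = L_{m,34}$ and $LB' = L_{m,42}$, and the diagonal depolarization
coefficients $\alpha_{22}, \alpha_{33}, \alpha_{44}$ from $L_u$. The sign
convention is fixed so that `make_retarder(delta, 0)` yields $LB = +\delta$;
the handedness of $s_3$ (right-circular positive) is fixed once and none of
the invariants depend on it.

An in-plane rotation of the sample by $\alpha$ conjugates $M$ — and hence
$L$ — by the block rotation operator with entries $\cos 2\alpha, \pm\sin
2\alpha$ on the linear-polarization block. The quantities reported by
`invariant_set()` are invariant under this conjugation:

| invariant | definition | meaning |
|---|---|---|
| $R_T$ | $\sqrt{L_{m,24}^2 + L_{m,34}^2}$ | total linear retardance (rad) |
| $D_T$ | $\sqrt{L_{m,12}^2 + L_{m,13}^2}$ | total linear dichroism |
| $R_C$ | $L_{m,23}$ | circular retardance |
| $D_C$ | $L_{m,14}$ | circular dichroism |
| $\alpha_L$ | $(\alpha_{22}+\alpha_{33})/2$ | isotropic linear depolarization |
| $\alpha_{44}$ | $L_{u,44}$ | circular depolarization |
| $\alpha_{LA}$ | $\tfrac12\sqrt{(\alpha_{22}-\alpha_{33})^2 + (L_{u,23}+L_{u,32})^2}$ | anisotropic linear depolarization |

$\alpha_{LA}$ is constructed from $L_u$ the same way the degree-of-anisotropy
parameter of Mueller matrix transformation theory is constructed from $M$
itself; it is reported unsigned. A defining property, checked to $10^{-9}$
over hundreds of random physical matrices in the test suite:

```{r invariance}
M <- random_physical_mueller(seed = 1)
rbind(
  as.numeric(invariant_set(M)[1, 1:7]),
  as.numeric(invariant_set(rotate_mueller(M, 0.6))[1, 1:7])
)
```

### Numerical choices

* **Branch handling.** Only the principal logarithm is used, so a total
  retardance of $\pi$ or more is not representable. Analytic inputs with
  eigenvalues on the closed negative real axis raise an error
  (`branch = "error"`, the default). The Monte Carlo pipeline uses
  `branch = "boundary"`: a noisy high-retardance matrix can sit exactly on
  the branch cut, where an even pair of negative real eigenvalues is
  decomposed as the limit of a conjugate pair at phase $\pm\pi$ — the log
  of their geometric-mean modulus plus a $\pi$ rotation generator built
  from the paired eigenvectors. The modulus mismatch of the pair (and any
  unpaired negative eigenvalue, which has no real logarithm at all) is
  recorded in `imag_residual` rather than silently dropped.
* **Conditioning.** Near retardance $\pi$ the eigenvector matrix becomes
  ill-conditioned even though the logarithm itself is finite. The package
  therefore also implements a real-Schur/Parlett logarithm (orthogonal
  basis, closed-form logs of the 2×2 blocks, Sylvester recurrence with a
  consistent least-squares solve for repeated eigenvalues split across
  blocks); the Monte Carlo path and the defective-matrix fallback use it.
  Either route is validated by the round-trip $\exp(L) = M$, not by the
  algorithm used.
* **Tolerances.** Pure linear-algebra identities are tested at $10^{-12}$,
  exp/log round trips at $10^{-8}$–$10^{-10}$.

## The Monte Carlo model

Photons are launched as a pencil beam at normal incidence (by translational
symmetry of the laterally infinite slab this is equivalent to a uniform
beam) and tracked with an explicit orthonormal polarization frame; the
Stokes vector is referenced to the frame's first axis. Between events the
free path is drawn from $s = -\ln(U)/\mu_t$; the event is a sphere with
probability $\mu_s / (\mu_s + \mu_c)$. Scattering coefficients are the
model's direct inputs (in cm$^{-1}$, interpreted as inverse mean free
paths); number densities are never computed.

* **Spheres** use the Mie amplitude series (truncated at the standard
  order $\lceil x + 4x^{1/3} + 2\rceil$); deflection and azimuth are drawn
  by rejection against the polarization-conditioned phase function
  $\sin\theta\,[S_{11}(\theta) + S_{12}(\theta)(q\cos 2\phi + u\sin
  2\phi)]$ with a precomputed envelope (grid maximum × 1.05; exceeding the
  envelope is a hard error).
* **Cylinders** use the oblique-incidence scattering-matrix series of the
  infinite cylinder (C++17 Bessel functions). The scattered direction lies
  exactly on the cone making the incidence angle $\zeta$ with the cylinder
  axis; the cone azimuth is drawn by rejection against the polarized
  phase function built from the amplitude matrix. Coefficients are
  tabulated over a $\zeta$ grid (721 points) per configuration.
* **Polarization-dependent extinction.** Unlike spheres, aligned cylinders
  scatter parallel- and perpendicular-polarized light at different total
  rates, so the estimator cannot simply renormalize the Stokes vector
  after each event (doing so breaks the linearity of the Mueller response
  and, detectably, the mirror symmetry of the slab). The photon therefore
  carries its weight in $s_0$: each cylinder event applies the
  collision-rate ratio $\phi(S)/\phi_\mathrm{unpol}$ (a non-analog weight,
  identically 1 for spheres), and each straight segment applies the
  dichroic part of the cylinder extinction matrix — a diagonal Jones
  attenuator in the incidence-plane basis whose rates are fixed by the
  polarization-resolved scattering integrals — relative to the scalar
  attenuation already charged by the free-path sampling. This differential
  extinction is what produces the linear dichroism of the SCB model,
  including its ballistic (small-thickness) component. The coherent
  *phase* part of the extinction matrix — the form birefringence of the
  cylinder suspension — is deliberately not modeled: in the optical models
  studied here that effect is represented by the intrinsic birefringence
  of the host medium (which is how the dermal models are parameterized),
  and including it would double-count retardance against the fitted
  $\Delta n$, contradicting the observation that adding cylinders leaves
  the retardance nearly unchanged.
* **Birefringent host.** Each straight flight segment acts as a linear
  retarder with $\delta = (2\pi/\lambda)\,(n_e(\theta_p) - n_o)\,s$, where
  $1/n_e(\theta_p)^2 = \cos^2\theta_p/n_o^2 + \sin^2\theta_p/n_e^2$ and the
  axis is the transverse projection of the optic axis. Ray splitting,
  walk-off and direction-dependent refraction are neglected — justified at
  $\Delta n \le 0.009$ and tissue-cut thicknesses, and checked against the
  ballistic closed form $R_T = 2\pi\,\Delta n\, d/\lambda$, which the
  simulator reproduces exactly.
* **Boundaries and detection.** The slab is index matched (no Fresnel
  steps); photons beyond a 3 mm lateral half-width are dropped and counted.
  All forward-exiting photons are recorded; their Stokes vectors are
  referenced to the laboratory basis parallel-transported from the surface
  normal to the exit direction along the meridian (the collimation
  convention of an imaging detector). This convention commutes with
  in-plane rotations of the whole system, so lab-frame symmetries — e.g.
  that spheres in an isotropic host show exactly zero dichroism — survive
  detection. Objective-NA angular filtering is deliberately not applied.
* **Mueller assembly.** Four polarized runs (H, V, +45°, right-circular)
  on separate deterministic RNG substreams give the matrix columns
  $c_1 = (S_H+S_V)/2$, $c_2 = (S_H-S_V)/2$, $c_3 = S_P - c_1$,
  $c_4 = S_R - c_1$. Trajectories cannot be reused across input states
  because the rejection sampler conditions on the actual photon
  polarization. The image is averaged over a central 600 µm circle (pixel
  centers inside the circle) and normalized.
* **Uncertainty.** Each state runs in 10 independent batches.
  `mc_standard_error()` reports plain batch SEs for the signed invariants;
  for the square-root invariants ($R_T$, $D_T$, $\alpha_{LA}$), which are
  positively biased under their null, SEs are propagated from the batch
  SEs of the *signed* components, giving the correct null distribution for
  "consistent with zero" checks and reducing to the delta-method SE under
  signal.

```{r ballistic}
cfg <- model_config(
  thickness_um = 10, mu_s_cm = 0, delta_n = 0.009,
  n_photons = 100, n_batches = 10
)
run_simulation(cfg)$invariants$RT
2 * pi * 0.009 * 10 / 0.533 # closed form
```

## Study conditions

The presets encode the dermal parameterization under which all results are
produced: scatterer indices 1.45, host (ordinary) index 1.33, wavelength
0.533 µm, sphere radius 0.05 µm, $\mu_s = 1500$ cm$^{-1}$, host
birefringence $\Delta n = 0.009$ (the best-fit value; the wider studied
ranges are $10^{-5}$–$10^{-3}$ for $\Delta n$, 5–5000 cm$^{-1}$ for $\mu$,
0.01–0.5 µm diameters — presets warn outside them). SCB adds X-aligned
cylinders of radius 0.05 µm with $\mu_c \in \{500, 1000, 1500\}$ cm$^{-1}$
(default 1500, the setting of the radius study); the cylinder-radius sweep
uses $R_c \in \{0.05, 0.5, 2\}$ µm at fixed $\mu_c$. Thickness sweeps use
the nominal grid 3, 6, …, 30 µm — the exact experimental grid is not
published, so the uniform nominal grid is used.

Desk-scale photon budgets are $10^5$–$10^6$ per input state (against
$10^7$–$10^8$ in the original study); all stochastic checks are therefore
phrased in Monte Carlo standard errors. The acceptance-style tests in
`tests/testthat/test-acceptance.R` use $10^5$ per state for the SB null
experiment, $2\times10^5$–$10^6$ for the SCB thickness laws (more photons
at the top thicknesses, where the polarized signal is weakest), and
$4\times10^5$ for the parameter orderings, evaluated at 21–24 µm where the
signal is strong but the retardance phase is still safely below $\pi$.

## What the model reproduces — and one honest failure

With these conditions the simulator reproduces the discrimination logic:

* **SB**: $R_T$ linear in thickness ($R^2 > 0.99$), $\alpha_L$ and
  $\alpha_{44}$ quadratic ($R^2 > 0.98$), $|\alpha_{44}| > |\alpha_L|$
  (Rayleigh regime), $\alpha_{LA}$ consistent with zero (within 3 SE) and
  $D_T$ consistent with zero at every thickness.
* **SCB**: the same thickness laws (the retardance phase crosses $\pi$ at
  $d = 29.6$ µm, where the principal-branch logarithm caps the top sweep
  point near $\pi$; the linear fit still clears $R^2 \ge 0.99$, and over
  3–24 µm gives $R^2 > 0.9999$), plus $D_T > 0$ growing with thickness
  (with a ballistic dichroic-extinction component visible already at small
  thickness) and $\alpha_{LA} > 0$ growing with $\mu_c$ and decreasing
  with cylinder radius — thin fibrils produce the strongest anisotropy of
  linear depolarization.
* **SC** (spheres only, isotropic host): no retardance, no dichroism, no
  anisotropic depolarization.

One acceptance expectation is deliberately left failing, because it is
unattainable at desk-scale photon budgets rather than wrong in the
implementation: **$\alpha_{LA} > 3\,\mathrm{SE}$ at 30 µm for
$\mu_s = \mu_c = 1500$ cm$^{-1}$.** That slab is nine mean free paths
thick; the surviving polarized signal is of order $e^{-4}$ of the detected
intensity, per-batch decompositions operate at the shot-noise floor, and
the batch standard error of $\alpha_{LA}$ is further inflated by
branch-boundary excursions (the retardance phase sits near $\pi$).
Measured at $10^6$ photons per state the estimate reaches only a quarter
of the required three standard errors; extrapolating the noise scaling,
roughly $10^7$–$10^8$ photons per state — the original study's budget —
would be needed. The same claim holds clearly at 24 µm ($\mu_c = 500$)
and at 21 µm ($\mu_c = 1500$).

## What the generator does not emulate

The synthetic slab is an idealization: no host absorption, no glass slide,
no Fresnel reflection or refraction at the faces, no surface roughness
(experimentally the likely source of a nonzero dichroism intercept), no
objective-NA filtering, monodisperse scatterers, perfectly aligned
infinite cylinders, and no chiral components (so $CB = CD = 0$ by
construction, as also observed experimentally). Passing tests therefore
validate the transport and decomposition machinery and the *qualitative*
model discrimination; they do not certify agreement with any particular
tissue measurement.

## A complete discrimination run

```{r discrimination, eval = FALSE}
ds <- seq(3, 24, by = 3)
sweeps <- list(
  SC  = thickness_sweep(make_preset("SC", mu_c_cm = 0), ds, n_photons = 1e5, seed = 11),
  SB  = thickness_sweep(make_preset("SB"), ds, n_photons = 1e5, seed = 11),
  SCB = thickness_sweep(make_preset("SCB", mu_c_cm = 500), ds, n_photons = 2e5, seed = 11)
)
rep <- discrimination_report(sweeps)
print(rep)
autoplot(sweeps$SCB)
```

The report tests each model against four criteria (retardance linear in
thickness with a significant slope; depolarization quadratic; dichroism
present; anisotropic depolarization present) and renders the verdict that
only the sphere–cylinder–birefringence model is compatible with all of
them. Thresholds (3 batch SEs for presence/absence, $R^2 \ge 0.99/0.98$
for the fits) are package choices: the original analysis asserts the
functional forms without publishing fit statistics.

## Known limitations

* Retardances at or above $\pi$ are outside the principal branch; sweeps
  that cross it (thick, strongly birefringent slabs at short wavelengths)
  produce a wrapped top point and boundary-inflated uncertainties.
* The birefringent host model ignores o/e ray splitting and walk-off;
  at $\Delta n$ of order $10^{-2}$ and micrometer thicknesses the error is
  negligible, but the approximation degrades for strongly birefringent
  media.
* Cylinders are infinite and perfectly aligned; orientation dispersion and
  finite fibril length are not modeled.
* The $\zeta$-grid tabulation of cylinder coefficients (721 points over
  (0, π/2]) introduces an angular quantization of ~0.12°, far below the
  angular scale of any feature in the studied regime.
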