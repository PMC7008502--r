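# Single-scattering physics: user-facing wrappers over the compiled kernels.

#' Mie scattering amplitudes
#'
#' Complex amplitude functions `S1(theta)` (perpendicular) and `S2(theta)`
#' (parallel) of a homogeneous sphere from the Mie partial-wave series,
#' truncated at the standard order `ceiling(x + 4 x^(1/3) + 2)`.
#'
#' @param x Size parameter `2 pi R n_host / lambda` (host-relative), `> 0`.
#' @param m Relative refractive index `n_particle / n_host`.
#' @param theta Scattering angles in radians (vectorized).
#' @return A tibble with columns `theta`, `S1`, `S2` (complex).
#' @examples
#' mie_amplitudes(0.78, 1.45 / 1.33, c(0, pi / 2, pi))
#' @export
mie_amplitudes <- function(x, m, theta) {
  stopifnot(x > 0, m > 0)
  res <- cpp_mie_amplitudes(x, m, as.numeric(theta))
  tibble::tibble(theta = as.numeric(theta), S1 = res$S1, S2 = res$S2)
}

#' Mie scattering efficiency and cross-section
#'
#' @inheritParams mie_amplitudes
#' @param radius_um Sphere radius in micrometers (for the cross-section).
#' @return A one-row tibble with `Qsca` and, when `radius_um` is given,
#'   `sigma_um2 = Qsca * pi * radius_um^2`.
#' @export
mie_efficiency <- function(x, m, radius_um = NULL) {
  stopifnot(x > 0, m > 0)
  q <- cpp_mie_qsca(x, m)
  out <- tibble::tibble(Qsca = q)
  if (!is.null(radius_um)) {
    out$sigma_um2 <- q * pi * radius_um^2
  }
  out
}

#' Scattering cross-section of a sphere
#'
#' Convenience wrapper computing the size parameter and relative index from
#' physical quantities.
#'
#' @param radius_um Sphere radius, micrometers.
#' @param n_particle,n_host Absolute refractive indices.
#' @param wavelength_um Vacuum wavelength, micrometers.
#' @return A one-row tibble with `x`, `m`, `Qsca`, `sigma_um2`.
#' @export
mie_cross_section <- function(radius_um, n_particle, n_host, wavelength_um) {
  x <- 2 * pi * radius_um * n_host / wavelength_um
  m <- n_particle / n_host
  q <- cpp_mie_qsca(x, m)
  tibble::tibble(x = x, m = m, Qsca = q, sigma_um2 = q * pi * radius_um^2)
}

#' Single-scattering Mueller matrix of a sphere
#'
#' Assembled from the Mie amplitudes at angle `theta`, referenced to the
#' scattering plane (block structure with `m22 = m11`, `m44 = m33`,
#' `m43 = -m34`).
#'
#' @inheritParams mie_amplitudes
#' @param theta Scattering angle, radians (scalar).
#' @return A 4x4 Mueller matrix (unnormalized: `m11` carries the
#'   differential cross-section scale).
#' @export
single_scatter_mueller <- function(x, m, theta) {
  stopifnot(length(theta) == 1)
  cpp_single_scatter_mueller(x, m, theta)
}

#' Infinite-cylinder scattering amplitudes at oblique incidence
#'
#' The four complex entries of the cylinder amplitude matrix
#' `[T1 T4; T3 T2]` mapping `(E_par, E_perp)` of the incident wave (parallel
#' = in the plane containing the cylinder axis and the incident direction)
#' to the scattered wave on the cone making angle `zeta` with the axis.
#'
#' @inheritParams mie_amplitudes
#' @param zeta Angle between incident direction and cylinder axis, in
#'   `(0, pi/2]`; `pi/2` is normal incidence. Propagation along the axis
#'   (`zeta = 0`) is rejected.
#' @param Theta Scattering azimuths around the axis, radians (vectorized);
#'   `0` is the forward direction.
#' @return A tibble with columns `Theta`, `T1`, `T2`, `T3`, `T4`.
#' @export
cylinder_amplitudes <- function(x, m, zeta, Theta) {
  if (!(zeta > 0)) {
    stop("zeta = 0: grazing incidence along the cylinder axis", call. = FALSE)
  }
  res <- cpp_cylinder_amplitudes(x, m, zeta, as.numeric(Theta))
  tibble::tibble(
    Theta = as.numeric(Theta),
    T1 = res$T1, T2 = res$T2, T3 = res$T3, T4 = res$T4
  )
}

#' Cylinder scattering efficiencies
#'
#' Scattering efficiencies for incident polarization parallel and
#' perpendicular to the incidence plane, normalized to the transverse size
#' parameter `x * sin(zeta)` (so at normal incidence they are the standard
#' per-unit-length efficiencies).
#'
#' @inheritParams cylinder_amplitudes
#' @return A one-row tibble with `Q_par` and `Q_perp`.
#' @export
cylinder_efficiency <- function(x, m, zeta) {
  q <- cpp_cylinder_qsca(x, m, zeta)
  tibble::tibble(Q_par = q[["Q_par"]], Q_perp = q[["Q_perp"]])
}

#' Sample sphere scattering angles by rejection
#'
#' Draws deflection and azimuth angles `(theta, phi)` from the polarized
#' single-scattering phase function of the incident Stokes vector, using
#' rejection against a precomputed envelope (maximum of the phase function
#' over a fine angular grid times a 1.05 safety factor). A draw exceeding
#' the envelope is a hard error.
#'
#' @param stokes Incident Stokes vector (length 4, `s0 > 0`).
#' @inheritParams mie_amplitudes
#' @param n Number of draws.
#' @param seed Integer seed for the deterministic sampler stream.
#' @return A tibble with columns `theta`, `phi`.
#' @export
sample_sphere_angles <- function(stokes, x, m, n, seed = 1) {
  res <- cpp_sample_sphere_angles(as.numeric(stokes), x, m, as.integer(n), as.numeric(seed))
  tibble::tibble(theta = res[, 1], phi = res[, 2])
}

#' Sample cylinder scattering azimuths by rejection
#'
#' Draws the cone azimuth `Theta` from the polarized cylinder phase function
#' for incidence angle `zeta`; the exit direction lies exactly on the
#' `zeta`-cone around the cylinder axis.
#'
#' @inheritParams sample_sphere_angles
#' @inheritParams cylinder_amplitudes
#' @return A numeric vector of `n` azimuths in `[0, 2 pi)`.
#' @export
sample_cylinder_angles <- function(stokes, x, m, zeta, n, seed = 1) {
  as.numeric(cpp_sample_cylinder_angles(
    as.numeric(stokes), x, m, zeta, as.integer(n), as.numeric(seed)
  ))
}

#' Jones to Mueller conversion
#'
#' Mueller matrix of a deterministic optical element given its 2x2 complex
#' amplitude (Jones) matrix in the `(E_par, E_perp)` basis. Used internally
#' to assemble single-scattering matrices; exposed for testing and fixture
#' construction.
#'
#' @param J A 2x2 complex matrix.
#' @return A 4x4 Mueller matrix.
#' @export
jones_to_mueller <- function(J) {
  cpp_jones_to_mueller(J)
}
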