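# Single-scattering kernels: Mie spheres, infinite cylinders, rejection
# sampling of scattering angles.

m_rel <- 1.45 / 1.33

test_that("Mie amplitudes: forward degeneracy, Rayleigh dipole, no contrast", {
  amp <- mie_amplitudes(0.78, m_rel, 0)
  expect_equal(amp$S1[1], amp$S2[1], tolerance = 1e-12)
  # Rayleigh limit: S2/S1 -> cos(theta)
  th <- seq(0.1, 3, by = 0.2)
  amp <- mie_amplitudes(0.05, 1.0902, th)
  expect_lt(max(Mod(amp$S2 / amp$S1 - cos(th))), 1e-3)
  # index-matched scatterer has vanishing amplitudes
  amp <- mie_amplitudes(0.5, 1, c(0.3, 1.5))
  expect_lt(max(Mod(amp$S1), Mod(amp$S2)), 1e-14)
})

test_that("Mie efficiency matches Rayleigh closed form and independent series", {
  q <- mie_efficiency(0.1, 1.0902)$Qsca
  q_ray <- 8 / 3 * 0.1^4 * abs((1.0902^2 - 1) / (1.0902^2 + 2))^2
  expect_equal(q, q_ray, tolerance = 0.01)
  expect_equal(mie_efficiency(1, 1)$Qsca, 0, tolerance = 1e-14)
  for (x in c(0.3, 1, 3)) {
    expect_equal(mie_efficiency(x, 1.0902)$Qsca, oracle_mie(x, 1.0902)$Qsca,
      tolerance = 1e-8
    )
  }
  # amplitudes against the independent half-integer-Bessel series
  th <- c(0.2, 1.1, 2.4)
  amp <- mie_amplitudes(1, 1.0902, th)
  orc <- oracle_mie(1, 1.0902, th)
  expect_lt(max(Mod(amp$S1 - orc$S1)), 1e-8)
  expect_lt(max(Mod(amp$S2 - orc$S2)), 1e-8)
  # cross-section plumbing
  cs <- mie_cross_section(0.05, 1.45, 1.33, 0.533)
  expect_equal(cs$x, 2 * pi * 0.05 * 1.33 / 0.533)
  expect_equal(cs$sigma_um2, cs$Qsca * pi * 0.05^2)
})

test_that("single-scattering Mueller matrix has the sphere block structure", {
  for (th in c(0, 0.7, 2.1)) {
    M <- single_scatter_mueller(0.78, m_rel, th)
    expect_equal(M[2, 2], M[1, 1], tolerance = 1e-12)
    expect_equal(M[4, 4], M[3, 3], tolerance = 1e-12)
    expect_equal(M[4, 3], -M[3, 4], tolerance = 1e-12)
    expect_lt(max(abs(M[1:2, 3:4]), abs(M[3:4, 1:2])), 1e-14)
  }
  # forward: no depolarization, fully diagonal
  M0 <- single_scatter_mueller(0.78, m_rel, 0)
  expect_lt(abs(M0[1, 2]), 1e-14)
  # Rayleigh at 90 degrees: complete polarization, S12/S11 = -1
  M9 <- single_scatter_mueller(0.05, m_rel, pi / 2)
  expect_equal(M9[1, 2] / M9[1, 1], -1, tolerance = 1e-3)
  # quadrature normalization: int S11 sin(th) dth = x^2 Qsca / 2
  x <- 0.78
  th <- seq(0, pi, length.out = 4001)
  s11 <- vapply(th, function(t) single_scatter_mueller(x, m_rel, t)[1, 1], 1)
  integ <- sum((s11 * sin(th))[-1] + (s11 * sin(th))[-4001]) / 2 * diff(th[1:2])
  expect_equal(integ, x^2 * mie_efficiency(x, m_rel)$Qsca / 2, tolerance = 1e-6)
})

test_that("cylinder amplitudes: normal incidence symmetry and oracle", {
  x <- 0.78
  Th <- c(0.3, 1.0, 2.0)
  ca <- cylinder_amplitudes(x, m_rel, pi / 2, Th)
  expect_lt(max(Mod(ca$T3), Mod(ca$T4)), 1e-14)
  orc <- oracle_cyl_normal(x, m_rel)
  nvec <- seq_along(orc$bI) - 1
  T1_orc <- vapply(Th, function(t) sum(orc$bI * cos(nvec * t) * c(1, rep(2, length(nvec) - 1))), complex(1))
  T2_orc <- vapply(Th, function(t) sum(orc$aII * cos(nvec * t) * c(1, rep(2, length(nvec) - 1))), complex(1))
  expect_lt(max(Mod(ca$T1 - T1_orc)), 1e-10)
  expect_lt(max(Mod(ca$T2 - T2_orc)), 1e-10)
  # index matching kills all amplitudes
  ca0 <- cylinder_amplitudes(x, 1, 1.2, Th)
  expect_lt(max(Mod(ca0$T1), Mod(ca0$T2), Mod(ca0$T3), Mod(ca0$T4)), 1e-12)
  expect_error(cylinder_amplitudes(x, m_rel, 0, Th), "grazing")
})

test_that("cylinder energy balance closes against the efficiency series", {
  x <- 0.78
  zeta <- 1.1
  Th <- seq(0, 2 * pi, length.out = 8193)[-8193]
  A <- cylinder_amplitudes(x, m_rel, zeta, Th)
  eff <- cylinder_efficiency(x, m_rel, zeta)
  qI <- mean(Mod(A$T1)^2 + Mod(A$T3)^2) * 2 / (x * sin(zeta))
  qII <- mean(Mod(A$T2)^2 + Mod(A$T4)^2) * 2 / (x * sin(zeta))
  expect_equal(qI, eff$Q_par, tolerance = 1e-3)
  expect_equal(qII, eff$Q_perp, tolerance = 1e-3)
})

test_that("jones conversion maps fields consistently to Stokes vectors", {
  # identity and a quarter-wave Jones element
  expect_mueller_equal(jones_to_mueller(diag(2) + 0i), diag(4), 1e-14)
  set.seed(21)
  stokes_of <- function(E) {
    c(
      Mod(E[1])^2 + Mod(E[2])^2, Mod(E[1])^2 - Mod(E[2])^2,
      2 * Re(E[1] * Conj(E[2])), -2 * Im(E[1] * Conj(E[2]))
    )
  }
  for (i in 1:10) {
    J <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
    M <- jones_to_mueller(J)
    E <- complex(real = rnorm(2), imaginary = rnorm(2))
    expect_equal(as.numeric(M %*% stokes_of(E)), stokes_of(as.vector(J %*% E)),
      tolerance = 1e-10
    )
  }
})

test_that("sphere angle sampling follows the polarized phase function", {
  # unpolarized input: phi uniform (KS test)
  ang <- sample_sphere_angles(c(1, 0, 0, 0), 0.05, 1.0902, 1e5, seed = 4)
  ks <- suppressWarnings(ks.test(ang$phi, "punif", 0, 2 * pi))
  expect_gt(ks$p.value, 0.01)
  # unpolarized Rayleigh theta-marginal ~ (1 + cos^2) sin(theta)
  br <- seq(0, pi, length.out = 51)
  counts <- table(cut(ang$theta, br))
  mids <- (br[-1] + br[-51]) / 2
  expect_gt(chisq_gof_p(as.numeric(counts), (1 + cos(mids)^2) * sin(mids)), 1e-3)
  # fully polarized input: phi-marginal against quadrature of the
  # phase function (S11 + S12 cos(2 phi) integrated over theta)
  ang <- sample_sphere_angles(c(1, 1, 0, 0), 0.05, 1.0902, 1e5, seed = 5)
  th <- seq(0, pi, length.out = 2001)
  amp <- mie_amplitudes(0.05, 1.0902, th)
  s11 <- (Mod(amp$S1)^2 + Mod(amp$S2)^2) / 2
  s12 <- (Mod(amp$S2)^2 - Mod(amp$S1)^2) / 2
  w11 <- sum(s11 * sin(th))
  w12 <- sum(s12 * sin(th))
  brp <- seq(0, 2 * pi, length.out = 41)
  midp <- (brp[-1] + brp[-41]) / 2
  counts <- table(cut(ang$phi, brp))
  expect_gt(chisq_gof_p(as.numeric(counts), w11 + w12 * cos(2 * midp)), 1e-3)
})

test_that("cylinder angle sampling respects the cone and the phase function", {
  zeta <- 1.2
  x <- 0.78
  Th <- sample_cylinder_angles(c(1, 0, 0, 0), x, m_rel, zeta, 1e5, seed = 6)
  expect_true(all(Th >= 0 & Th < 2 * pi))
  # mirror symmetry of the unpolarized distribution about the forward plane
  f <- mean(Th < pi)
  expect_lt(abs(f - 0.5), 0.01)
  # chi-square against the quadrature of the unpolarized phase function
  grid <- seq(0, 2 * pi, length.out = 2001)[-2001]
  A <- cylinder_amplitudes(x, m_rel, zeta, grid)
  dens <- (Mod(A$T1)^2 + Mod(A$T2)^2 + Mod(A$T3)^2 + Mod(A$T4)^2) / 2
  br <- seq(0, 2 * pi, length.out = 41)
  probs <- vapply(
    seq_len(40),
    function(k) sum(dens[grid >= br[k] & grid < br[k + 1]]), 1
  )
  counts <- table(cut(Th, br))
  expect_gt(chisq_gof_p(as.numeric(counts), probs), 1e-3)
})

test_that("cross sections grow monotonically with size parameter in the studied regime", {
  xs <- seq(0.1, 1, by = 0.1)
  qs <- vapply(xs, function(x) mie_efficiency(x, m_rel)$Qsca * x^2, 1)
  expect_true(all(diff(qs) > 0))
  qc <- vapply(xs, function(x) cylinder_efficiency(x, m_rel, pi / 2)$Q_par * x, 1)
  expect_true(all(diff(qc) > 0))
})
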