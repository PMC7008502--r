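# Independent oracles used across the test files.
#
# The Mie oracle builds the partial-wave series from R's half-integer
# Bessel functions (Riccati-Bessel psi/chi via besselJ/besselY with upward
# recurrences), a completely different computational route from the
# compiled kernel (downward logarithmic-derivative recurrence).  The
# cylinder oracle implements the normal-incidence closed forms.

oracle_mie <- function(x, m, theta = NULL) {
  N <- ceiling(x + 4 * x^(1 / 3) + 2)
  n <- seq_len(N)
  rb <- function(z) { # psi_n(z), psi_n'(z), chi_n(z), chi_n'(z) for n = 1..N
    psi <- sqrt(pi * z / 2) * besselJ(z, n + 0.5)
    chi <- -sqrt(pi * z / 2) * besselY(z, n + 0.5)
    psim1 <- c(sin(z), psi[-N])
    chim1 <- c(cos(z), chi[-N])
    list(
      psi = psi, dpsi = psim1 - n * psi / z,
      chi = chi, dchi = chim1 - n * chi / z
    )
  }
  h <- rb(x)
  g <- rb(m * x)
  xi <- h$psi - 1i * h$chi
  dxi <- h$dpsi - 1i * h$dchi
  a <- (m * g$psi * h$dpsi - h$psi * g$dpsi) /
    (m * g$psi * dxi - xi * g$dpsi)
  b <- (g$psi * h$dpsi - m * h$psi * g$dpsi) /
    (g$psi * dxi - m * xi * g$dpsi)
  qsca <- 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  out <- list(a = a, b = b, Qsca = qsca)
  if (!is.null(theta)) {
    S1 <- S2 <- complex(length(theta))
    for (k in seq_along(theta)) {
      mu <- cos(theta[k])
      pin <- numeric(N)
      taun <- numeric(N)
      pin[1] <- 1
      taun[1] <- mu
      if (N > 1) {
        pin[2] <- 3 * mu
        taun[2] <- 2 * mu * pin[2] - 3
        for (j in 3:N) {
          pin[j] <- ((2 * j - 1) * mu * pin[j - 1] - j * pin[j - 2]) / (j - 1)
          taun[j] <- j * mu * pin[j] - (j + 1) * pin[j - 1]
        }
      }
      f <- (2 * n + 1) / (n * (n + 1))
      S1[k] <- sum(f * (a * pin + b * taun))
      S2[k] <- sum(f * (a * taun + b * pin))
    }
    out$S1 <- S1
    out$S2 <- S2
  }
  out
}

# normal-incidence infinite-cylinder coefficients (case I: E parallel to
# the cylinder axis; case II: perpendicular)
oracle_cyl_normal <- function(x, m, N = ceiling(x + 4 * x^(1 / 3) + 2)) {
  n <- 0:N
  Jx <- besselJ(x, 0:(N + 1))
  Jmx <- besselJ(m * x, 0:(N + 1))
  Yx <- besselY(x, 0:(N + 1))
  dJ <- function(v) c(-v[2], (v[seq_len(N)] - v[seq_len(N) + 2]) / 2)
  dJx <- dJ(Jx)
  dJmx <- dJ(Jmx)
  dYx <- dJ(Yx)
  H <- Jx[n + 1] + 1i * Yx[n + 1]
  dH <- dJx + 1i * dYx
  bI <- (m * dJmx * Jx[n + 1] - Jmx[n + 1] * dJx) /
    (m * dJmx * H - Jmx[n + 1] * dH)
  aII <- (dJmx * Jx[n + 1] - m * Jmx[n + 1] * dJx) /
    (dJmx * H - m * Jmx[n + 1] * dH)
  list(bI = bI, aII = aII)
}

expect_mueller_equal <- function(M1, M2, tol = 1e-12) {
  expect_lt(max(abs(M1 - M2)), tol)
}

# chi-square goodness-of-fit statistic against given bin probabilities
chisq_gof_p <- function(counts, probs) {
  n <- sum(counts)
  e <- n * probs / sum(probs)
  stat <- sum((counts - e)^2 / e)
  pchisq(stat, df = length(counts) - 1, lower.tail = FALSE)
}
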