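# Matrix logarithm and the G-antisymmetric / G-symmetric split.

test_that("matrix logarithm of simple media matches closed forms", {
  expect_mueller_equal(mueller_log(diag(4))$L, matrix(0, 4, 4))
  D <- diag(c(1, 0.9, 0.9, 0.8))
  expect_mueller_equal(mueller_log(D)$L, diag(c(0, log(0.9), log(0.9), log(0.8))), 1e-12)
  L <- mueller_log(make_retarder(0.5, 0))$L
  ref <- matrix(0, 4, 4)
  ref[3, 4] <- 0.5
  ref[4, 3] <- -0.5
  expect_mueller_equal(L, ref, 1e-12)
})

test_that("matrix logarithm errors follow the principal-branch contract", {
  expect_error(mueller_log(diag(c(1, 1, 0, 1))), "singular")
  # half-wave plate: eigenvalue pair at -1, retardance pi not representable
  expect_error(mueller_log(make_retarder(pi, 0)), "negative real axis")
  expect_error(mueller_log(diag(c(2, 1, 1, 1))), "normalized")
  # boundary mode decomposes the same matrix at the limiting phase pi
  d <- mueller_log(make_retarder(pi, 0), branch = "boundary")
  expect_equal(total_linear_retardance(d), pi, tolerance = 1e-9)
})

test_that("exp/log round trip holds for 500 seeded random physical matrices", {
  set.seed(2024)
  worst <- 0
  for (i in 1:500) {
    M <- normalize_mueller(random_physical_mueller())
    d <- mueller_log(M)
    worst <- max(worst, max(abs(muellermc:::mat_exp(d$L) - M)))
    expect_lt(d$imag_residual, 1e-8)
  }
  expect_lt(worst, 1e-8)
})

test_that("logarithm is linear in optical path (powers of a thin element)", {
  M <- normalize_mueller(random_physical_mueller(seed = 31, bound = 0.1))
  L1 <- mueller_log(M)$L
  for (k in 2:3) {
    Mk <- diag(4)
    for (j in seq_len(k)) Mk <- Mk %*% M
    # the k-fold slab picks up a transmittance scale; ln(m11) I restores it
    Lk <- mueller_log(normalize_mueller(Mk))$L + log(Mk[1, 1]) * diag(4)
    expect_mueller_equal(Lk, k * L1, 1e-8)
  }
})

test_that("g_split separates polarization and depolarization generators", {
  z <- muellermc:::g_split(matrix(0, 4, 4))
  expect_mueller_equal(z$Lm, matrix(0, 4, 4))
  expect_mueller_equal(z$Lu, matrix(0, 4, 4))
  # pure retarder generator is entirely G-antisymmetric
  L <- matrix(0, 4, 4)
  L[3, 4] <- 0.7
  L[4, 3] <- -0.7
  s <- g_split(L)
  expect_mueller_equal(s$Lm, L)
  expect_mueller_equal(s$Lu, matrix(0, 4, 4))
  # diagonal generator is entirely G-symmetric
  Ld <- diag(c(0, -0.2, -0.4, -0.6))
  s <- g_split(Ld)
  expect_mueller_equal(s$Lm, matrix(0, 4, 4))
  expect_mueller_equal(s$Lu, Ld)
  # entrywise definition and exact closure for random input
  set.seed(5)
  L <- matrix(rnorm(16), 4, 4)
  s <- g_split(L)
  expect_equal(s$Lm[1, 2], (L[1, 2] + L[2, 1]) / 2)
  expect_equal(s$Lu[1, 2], (L[1, 2] - L[2, 1]) / 2)
  expect_equal(s$Lm[2, 3], (L[2, 3] - L[3, 2]) / 2)
  expect_equal(s$Lu[2, 3], (L[2, 3] + L[3, 2]) / 2)
  expect_mueller_equal(s$Lm + s$Lu, L)
  G <- diag(c(1, -1, -1, -1))
  expect_mueller_equal(G %*% t(s$Lm) %*% G, -s$Lm, 1e-12)
  expect_mueller_equal(G %*% t(s$Lu) %*% G, s$Lu, 1e-12)
  # idempotence: splitting a pure component returns it unchanged
  s2 <- g_split(s$Lm)
  expect_mueller_equal(s2$Lm, s$Lm)
  expect_mueller_equal(s2$Lu, matrix(0, 4, 4))
})

test_that("elementary coefficients recover the generating parameters", {
  co <- lmmd_coefficients(diag(4))
  expect_true(all(abs(as.numeric(co)) < 1e-14))
  co <- lmmd_coefficients(make_retarder(0.5, 0))
  expect_equal(co$LB, 0.5, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(co[setdiff(names(co), "LB")]))), 1e-10)
  co <- lmmd_coefficients(make_depolarizer(-0.2, -0.4, -0.6))
  expect_equal(c(co$a22, co$a33, co$a44), c(-0.2, -0.4, -0.6), tolerance = 1e-12)
  expect_lt(max(abs(c(co$LD, co$LDp, co$CD, co$CB, co$LB, co$LBp))), 1e-10)
})

test_that("pure fixtures carry no spurious coefficient families", {
  # retarder: no dichroism, no depolarization
  co <- lmmd_coefficients(make_retarder(1.1, 0.4))
  expect_lt(max(abs(c(co$LD, co$LDp, co$CD, co$a22, co$a33, co$a44))), 1e-10)
  # diagonal depolarizer: only a22/a33/a44
  co <- lmmd_coefficients(make_depolarizer(-0.1, -0.3, -0.5))
  expect_lt(max(abs(c(co$LD, co$LDp, co$CD, co$CB, co$LB, co$LBp))), 1e-10)
})

test_that("schur-based logarithm round-trips, including near the branch boundary", {
  set.seed(8)
  for (i in 1:100) {
    M <- random_physical_mueller()
    L <- muellermc:::mat_log_schur(M)
    expect_mueller_equal(muellermc:::mat_exp(L), M, 1e-10)
  }
  # commuting retarder-depolarizer product with retardance close to pi
  M <- make_retarder(3.1, 0.2) %*%
    rotate_mueller(diag(c(1, exp(-0.5), exp(-2), exp(-2))), 0.2)
  L <- muellermc:::mat_log_schur(M)
  expect_mueller_equal(muellermc:::mat_exp(L), M, 1e-10)
  expect_equal(total_linear_retardance(L), 3.1, tolerance = 1e-9)
})

test_that("lmmd objects tidy, glance and serialize", {
  d <- mueller_log(make_retarder(0.5, 0))
  td <- tidy(d)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$term == "LB"], 0.5, tolerance = 1e-12)
  expect_true(all(c("imag_residual", "split_closure") %in% names(glance(d))))
  f <- tempfile(fileext = ".json")
  write_lmmd(d, f)
  rec <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(matrix(rec$L, 4, 4, byrow = TRUE), d$L, tolerance = 1e-12)
  expect_equal(rec$LB, 0.5, tolerance = 1e-12)
  unlink(f)
})
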