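# Mueller/Stokes algebra and the closed-form fixtures.

test_that("rotation operator has the block-rotation structure", {
  expect_mueller_equal(rotation_matrix(0), diag(4))
  expect_mueller_equal(rotation_matrix(pi / 2), diag(c(1, -1, -1, 1)))
  R4 <- rotation_matrix(pi / 4)
  expect_equal(R4[2, 3], -1)
  expect_equal(R4[3, 2], 1)
  expect_equal(R4[2, 2], 0, tolerance = 1e-15)
  expect_equal(R4[3, 3], 0, tolerance = 1e-15)
  # R(alpha) R(-alpha) = I and 2-alpha periodicity
  for (a in c(0.1, 1.2, 2.9)) {
    expect_mueller_equal(rotation_matrix(a) %*% rotation_matrix(-a), diag(4))
    expect_mueller_equal(rotation_matrix(a + pi), rotation_matrix(a))
  }
})

test_that("rotate_mueller conjugates and round-trips exactly", {
  set.seed(42)
  for (i in 1:20) {
    M <- random_physical_mueller()
    a <- runif(1, -pi, pi)
    expect_mueller_equal(rotate_mueller(rotate_mueller(M, a), -a), M, 1e-12)
  }
  expect_mueller_equal(rotate_mueller(diag(4), 0.77), diag(4))
  # rotated retarder equals the closed-form retarder at the rotated axis
  expect_mueller_equal(
    rotate_mueller(make_retarder(0.5, 0), pi / 8),
    make_retarder(0.5, pi / 8), 1e-12
  )
  # a linearly isotropic depolarizer commutes with in-plane rotation
  D <- diag(c(1, 0.8, 0.8, 0.5))
  expect_mueller_equal(rotate_mueller(D, 1.1), D, 1e-12)
})

test_that("normalization divides by m11 and rejects degenerate input", {
  expect_mueller_equal(normalize_mueller(diag(c(2, 1, 1, 1))), diag(c(1, 0.5, 0.5, 0.5)))
  expect_mueller_equal(normalize_mueller(diag(4)), diag(4))
  expect_error(normalize_mueller(diag(c(0, 1, 1, 1))), "m11")
  expect_error(normalize_mueller(diag(c(-1, 1, 1, 1))), "m11")
})

test_that("retarder fixture: closed form, determinant, orthogonal block", {
  expect_mueller_equal(make_retarder(0, 0.3), diag(4))
  expect_mueller_equal(make_retarder(pi, 0), diag(c(1, 1, -1, -1)))
  for (th in c(0, 0.4, 1.9)) {
    M <- make_retarder(0.8, th)
    expect_equal(det(M), 1, tolerance = 1e-12)
    B <- M[2:4, 2:4]
    expect_mueller_equal(B %*% t(B), diag(3), 1e-12)
  }
  # matrix-exponential round trip through the package logarithm
  M <- make_retarder(0.5, 0.3)
  expect_mueller_equal(muellermc:::mat_exp(mueller_log(M)$L), M, 1e-10)
})

test_that("diattenuator fixture is the exponential of its stated generator", {
  expect_mueller_equal(make_diattenuator(0, 0.2), diag(4))
  L <- matrix(0, 4, 4)
  L[1, 2] <- L[2, 1] <- 0.3
  expect_mueller_equal(make_diattenuator(0.3, 0), Matrix::as.matrix(Matrix::expm(L)), 1e-12)
  # m12 = sinh(d) on the generator scale
  expect_equal(make_diattenuator(0.3, 0)[1, 2], sinh(0.3), tolerance = 1e-12)
})

test_that("depolarizer fixture is diagonal in the exponentiated generators", {
  expect_mueller_equal(make_depolarizer(0, 0, 0), diag(4))
  expect_mueller_equal(
    make_depolarizer(-0.2, -0.4, -0.6),
    diag(c(1, exp(-0.2), exp(-0.4), exp(-0.6)))
  )
  expect_error(make_depolarizer(0.1, -0.4, -0.6), "<= 0")
})

test_that("random matrices are reproducible and have principal logs", {
  M1 <- random_physical_mueller(seed = 7)
  M2 <- random_physical_mueller(seed = 7)
  expect_identical(M1, M2)
  set.seed(123)
  for (i in 1:50) {
    M <- random_physical_mueller()
    d <- mueller_log(normalize_mueller(M))
    expect_lt(max(abs(muellermc:::mat_exp(d$L)) - abs(normalize_mueller(M))), 1e-9)
  }
})

test_that("internal matrix exponential agrees with an independent implementation", {
  set.seed(9)
  for (i in 1:20) {
    A <- matrix(runif(16, -0.8, 0.8), 4, 4)
    expect_mueller_equal(
      muellermc:::mat_exp(A),
      Matrix::as.matrix(Matrix::expm(A)), 1e-11
    )
  }
})

test_that("serialization round-trips through both plain-text formats", {
  M <- random_physical_mueller(seed = 3)
  f1 <- tempfile(fileext = ".txt")
  f2 <- tempfile(fileext = ".tsv")
  write_mueller(M, f1, format = "matrix")
  write_mueller(M, f2, format = "row")
  expect_equal(read_mueller(f1), M, tolerance = 1e-14)
  expect_equal(read_mueller(f2), M, tolerance = 1e-14)
  unlink(c(f1, f2))
})

test_that("stokes constructor enforces physicality", {
  expect_equal(stokes(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_error(stokes(-1, 0, 0, 0), "non-negative")
  expect_error(stokes(1, 1, 0.5, 0), "exceeds")
})
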