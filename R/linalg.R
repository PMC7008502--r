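# Internal dense 4x4 linear algebra: matrix exponential (Pade scaling and
# squaring) and matrix logarithm (eigendecomposition, with an inverse
# scaling-and-squaring fallback for defective inputs).  Kept in-package so
# the decomposition pipeline has no heavy dependencies; tests cross-check
# against independent implementations.

#' @noRd
mat_exp <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  # Higham's scaling-and-squaring with the order-13 Pade approximant.
  b <- c(
    64764752532480000, 32382376266240000, 7771770303897600,
    1187353796428800, 129060195264000, 10559470521600, 670442572800,
    33522128640, 1323241920, 40840800, 960960, 16380, 182, 1
  )
  n <- nrow(A)
  nrmA <- norm(A, "1")
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.eps) / 5.37)))
  A <- A / 2^s
  I <- diag(n)
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
    b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  E <- solve(V - U, V + U)
  for (k in seq_len(s)) E <- E %*% E
  E
}

# Principal matrix logarithm via complex eigendecomposition.  Returns the
# realified logarithm together with the largest imaginary magnitude that was
# discarded, so callers can monitor numerical health of noisy inputs.
#
# branch = "error": eigenvalues on the closed negative real axis are a hard
#   error (retardance >= pi is not representable on the principal branch).
# branch = "boundary": an even number of negative real eigenvalues is
#   treated as the limit of a conjugate pair at phase +/- pi (a noisy matrix
#   sitting exactly on the branch boundary); the realification residual
#   records the cost.  An odd count still errors (no real logarithm exists).
#' @noRd
mat_log_eigen <- function(M, tol_singular = 1e-12, tol_real = 1e-12,
                          branch = c("error", "boundary")) {
  branch <- match.arg(branch)
  ev <- eigen(M)
  lam <- as.complex(ev$values)
  if (any(abs(lam) < tol_singular)) {
    stop("matrix is numerically singular; no logarithm exists", call. = FALSE)
  }
  on_cut <- which(abs(Im(lam)) <= tol_real * max(abs(lam)) & Re(lam) < 0)
  if (branch == "boundary") {
    # Noisy Monte Carlo matrices can sit arbitrarily close to the branch
    # cut (retardance phase -> pi), where the eigenvector basis degrades;
    # the orthogonal-basis Schur route stays well conditioned there.
    L <- mat_log_schur(M)
    if (!is.null(L)) {
      return(list(L = L, imag_residual = 0))
    }
    # Genuine negative real eigenvalues: pair them (by modulus) as the
    # limit of a conjugate pair at phase pi, i.e. a pi rotation generator
    # J = v1 w2' - v2 w1' acting in the plane of their eigenvectors,
    # together with the log of their geometric-mean modulus.  exp(L) = M
    # holds exactly for equal moduli; the modulus mismatch of a noisy pair
    # is recorded in the residual.  An unpaired (odd) leftover has no real
    # logarithm at all; it keeps phase +i*pi and the realification drops
    # it, again recorded (deep-noise matrices only).
    loglam <- log(lam)
    V <- ev$vectors
    Wi <- solve(V)
    L_rot <- matrix(0, nrow(M), ncol(M))
    resid <- 0
    ord <- on_cut[order(Mod(lam[on_cut]))]
    k <- 1L
    while (k + 1L <= length(ord)) {
      i1 <- ord[k]
      i2 <- ord[k + 1L]
      r1 <- Mod(lam[i1])
      r2 <- Mod(lam[i2])
      v1 <- Re(V[, i1])
      v2 <- Re(V[, i2])
      w1 <- Re(Wi[i1, ])
      w2 <- Re(Wi[i2, ])
      P <- v1 %o% w1 + v2 %o% w2
      J <- v1 %o% w2 - v2 %o% w1
      L_rot <- L_rot + log(sqrt(r1 * r2)) * P + pi * J
      loglam[c(i1, i2)] <- 0
      resid <- max(resid, abs(log(r1 / r2)) / 2)
      k <- k + 2L
    }
    if (k == length(ord)) {
      resid <- max(resid, pi)
      loglam[ord[k]] <- log(Mod(lam[ord[k]])) + (0+1i) * pi
    }
    Lc <- V %*% diag(loglam) %*% Wi
    return(list(
      L = Re(Lc) + L_rot,
      imag_residual = max(abs(Im(Lc)), resid)
    ))
  }
  if (length(on_cut) > 0) {
    stop(
      "matrix has an eigenvalue on the negative real axis; the principal ",
      "logarithm is not defined (total retardance >= pi is not representable)",
      call. = FALSE
    )
  }
  V <- ev$vectors
  # (Nearly) defective eigenvector matrix: the Schur route only needs
  # exp(L) = M to hold and does not depend on eigenvector conditioning.
  # (SVD-based condition number: kappa() does not accept complex input.)
  sv <- svd(V, nu = 0, nv = 0)$d
  kap <- max(sv) / min(sv)
  if (!is.finite(kap) || kap > 1e10) {
    L <- mat_log_schur(M)
    if (is.null(L)) {
      stop("matrix logarithm failed: defective matrix", call. = FALSE)
    }
    return(list(L = L, imag_residual = 0))
  }
  Lc <- V %*% diag(log(lam)) %*% solve(V)
  list(L = Re(Lc), imag_residual = max(abs(Im(Lc))))
}

# Real-Schur / Parlett matrix logarithm.  The orthogonal Schur basis stays
# perfectly conditioned even when a complex eigenvalue pair approaches the
# negative real axis (retardance phase -> pi), where the eigenvector route
# becomes numerically defective.  2x2 diagonal blocks carry the complex
# pairs: for B = mu*I + W with W^2 = -nu^2 I,
#   log B = log(r) I + (phi / nu) W,  r = sqrt(mu^2 + nu^2), phi = atan2(nu, mu),
# continuous up to phi = pi.  Returns NULL when a 1x1 diagonal block is
# non-positive (real negative eigenvalue: no smooth real logarithm) so the
# caller can decide how to proceed.
#' @noRd
mat_log_schur <- function(M) {
  sc <- Matrix::Schur(Matrix::Matrix(M), vectors = TRUE)
  TT <- as.matrix(sc@T)
  Q <- as.matrix(sc@Q)
  n <- nrow(TT)
  starts <- integer(0)
  sizes <- integer(0)
  i <- 1L
  while (i <= n) {
    two <- i < n && abs(TT[i + 1, i]) >
      1e-14 * (abs(TT[i, i]) + abs(TT[i + 1, i + 1]) + 1)
    starts <- c(starts, i)
    sizes <- c(sizes, if (two) 2L else 1L)
    i <- i + if (two) 2L else 1L
  }
  LT <- matrix(0, n, n)
  for (k in seq_along(starts)) {
    s <- starts[k]
    if (sizes[k] == 1L) {
      if (TT[s, s] <= 0) return(NULL)
      LT[s, s] <- log(TT[s, s])
    } else {
      B <- TT[s:(s + 1), s:(s + 1)]
      mu <- (B[1, 1] + B[2, 2]) / 2
      W <- B - mu * diag(2)
      nu <- sqrt(max(det(W), 0)) # W^2 = -det(W) I for the traceless part
      if (nu <= 0) return(NULL)
      r <- sqrt(mu^2 + nu^2)
      phi <- atan2(nu, mu)
      LT[s:(s + 1), s:(s + 1)] <- log(r) * diag(2) + (phi / nu) * W
    }
  }
  nb <- length(starts)
  if (nb > 1) {
    for (gap in 1:(nb - 1)) {
      for (ki in 1:(nb - gap)) {
        kj <- ki + gap
        ri <- starts[ki]:(starts[ki] + sizes[ki] - 1L)
        rj <- starts[kj]:(starts[kj] + sizes[kj] - 1L)
        # Parlett recurrence: Tii X - X Tjj = Lii Tij - Tij Ljj + sum(mid)
        C <- LT[ri, ri, drop = FALSE] %*% TT[ri, rj, drop = FALSE] -
          TT[ri, rj, drop = FALSE] %*% LT[rj, rj, drop = FALSE]
        if (gap > 1) {
          for (km in (ki + 1):(kj - 1)) {
            rm <- starts[km]:(starts[km] + sizes[km] - 1L)
            C <- C + LT[ri, rm, drop = FALSE] %*% TT[rm, rj, drop = FALSE] -
              TT[ri, rm, drop = FALSE] %*% LT[rm, rj, drop = FALSE]
          }
        }
        p <- length(ri)
        q <- length(rj)
        A <- kronecker(diag(q), TT[ri, ri, drop = FALSE]) -
          kronecker(t(TT[rj, rj, drop = FALSE]), diag(p))
        # Blocks sharing an eigenvalue (repeated roots split across blocks)
        # make the Sylvester operator singular; the system is then solved in
        # the least-squares sense and accepted only if consistent.
        sv <- svd(A)
        keep <- sv$d > 1e-12 * max(sv$d, 1e-300)
        cv <- as.vector(C)
        x <- sv$v[, keep, drop = FALSE] %*%
          (crossprod(sv$u[, keep, drop = FALSE], cv) / sv$d[keep])
        if (max(abs(A %*% x - cv)) > 1e-8 * (1 + max(abs(cv)))) return(NULL)
        LT[ri, rj] <- matrix(x, p, q)
      }
    }
  }
  Q %*% LT %*% t(Q)
}

# Minkowski-like signature matrix of the Stokes space.
#' @noRd
g_metric <- function() diag(c(1, -1, -1, -1))
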