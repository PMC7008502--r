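# Mueller/Stokes algebra and closed-form synthetic optical elements.

#' Stokes vector
#'
#' Builds a Stokes vector `(s0, s1, s2, s3)` describing intensity and
#' polarization of a beam: `s0` total intensity, `s1` horizontal minus
#' vertical linear polarization (horizontal = laboratory X axis), `s2` the
#' +45 minus -45 component, `s3` right minus left circular.
#'
#' @param s0,s1,s2,s3 Numeric scalars. `s0` must be non-negative and the
#'   polarized intensity must not exceed `s0` (within `tol`).
#' @param tol Tolerance for the physicality check.
#' @return A numeric vector of length 4.
#' @examples
#' stokes(1, 1, 0, 0) # horizontally polarized light
#' @export
stokes <- function(s0, s1 = 0, s2 = 0, s3 = 0, tol = 1e-9) {
  s <- c(s0, s1, s2, s3)
  stopifnot(is.numeric(s), length(s) == 4, all(is.finite(s)))
  if (s0 < 0) stop("s0 must be non-negative", call. = FALSE)
  if (s1^2 + s2^2 + s3^2 > s0^2 * (1 + tol) + tol) {
    stop("polarized intensity exceeds total intensity", call. = FALSE)
  }
  s
}

#' @noRd
as_mueller <- function(M) {
  if (is.numeric(M) && length(M) == 16 && is.null(dim(M))) {
    M <- matrix(M, 4, 4, byrow = TRUE)
  }
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)), is.numeric(M))
  unname(M)
}

#' In-plane rotation operator for Mueller matrices
#'
#' The block rotation matrix `R(alpha)` describing an in-plane rotation of a
#' sample by azimuth `alpha` in transmission: identity on the intensity and
#' circular components, a `2*alpha` rotation on the linear-polarization block.
#' A rotated sample has Mueller matrix `R(alpha) %*% M %*% R(-alpha)`; see
#' [rotate_mueller()].
#'
#' @param alpha Rotation azimuth in radians. All derived quantities are
#'   periodic in `2*alpha`, so `alpha + pi` gives the same operator.
#' @return A 4x4 rotation operator.
#' @examples
#' rotation_matrix(0)        # identity
#' rotation_matrix(pi / 2)   # diag(1, -1, -1, 1)
#' @export
rotation_matrix <- function(alpha) {
  c2 <- cos(2 * alpha)
  s2 <- sin(2 * alpha)
  matrix(c(
    1, 0, 0, 0,
    0, c2, -s2, 0,
    0, s2, c2, 0,
    0, 0, 0, 1
  ), 4, 4, byrow = TRUE)
}

#' Rotate a Mueller matrix in its plane
#'
#' Applies the transmission-geometry rotational transformation
#' `M' = R(alpha) M R(-alpha)`. Rotating by `alpha` and then `-alpha`
#' recovers `M` exactly. Positive `alpha` rotates the sample
#' counterclockwise as seen against the beam.
#'
#' @param M A 4x4 Mueller matrix (or a row-major length-16 vector).
#' @param alpha Rotation azimuth in radians.
#' @return The rotated 4x4 Mueller matrix.
#' @examples
#' M <- make_retarder(0.5, 0)
#' all.equal(rotate_mueller(M, pi / 8), make_retarder(0.5, pi / 8))
#' @export
rotate_mueller <- function(M, alpha) {
  M <- as_mueller(M)
  rotation_matrix(alpha) %*% M %*% rotation_matrix(-alpha)
}

#' Normalize a Mueller matrix to unit transmittance
#'
#' Divides all 16 entries by `m11` so that the output has `m11 = 1`. The
#' logarithmic decomposition operates on transmittance-free matrices, so this
#' is applied before [mueller_log()].
#'
#' @param M A 4x4 Mueller matrix with `m11 > 0`.
#' @return The normalized matrix.
#' @export
normalize_mueller <- function(M) {
  M <- as_mueller(M)
  if (!is.finite(M[1, 1]) || M[1, 1] <= 0) {
    stop("degenerate Mueller matrix: m11 must be positive", call. = FALSE)
  }
  M / M[1, 1]
}

#' Linear retarder
#'
#' Mueller matrix of an ideal linear retarder with retardance `delta` and
#' fast axis at azimuth `theta`. At `theta = 0` the matrix is the identity on
#' `(s0, s1)` and a `delta` rotation on the `(s2, s3)` block; a general axis
#' is obtained with [rotate_mueller()].
#'
#' @param delta Retardance in radians.
#' @param theta Fast-axis azimuth in radians.
#' @return A 4x4 Mueller matrix.
#' @examples
#' make_retarder(pi, 0) # half-wave plate: diag(1, 1, -1, -1)
#' @export
make_retarder <- function(delta, theta = 0) {
  cd <- cos(delta)
  sd <- sin(delta)
  M0 <- matrix(c(
    1, 0, 0, 0,
    0, 1, 0, 0,
    0, 0, cd, sd,
    0, 0, -sd, cd
  ), 4, 4, byrow = TRUE)
  if (theta == 0) M0 else rotate_mueller(M0, theta)
}

#' Linear diattenuator (generator-parameterized)
#'
#' Mueller matrix of a homogeneous linear diattenuator, parameterized by its
#' logarithmic-decomposition dichroism coefficient `d` rather than by a
#' transmittance ratio: the matrix is the exponential of a generator whose
#' only nonzero entries are `L12 = L21 = d`, rotated to azimuth `theta`. By
#' construction the total linear dichroism recovered by the decomposition
#' equals `abs(d)` for any axis.
#'
#' @param d Dichroism coefficient (dimensionless).
#' @param theta Transmission-axis azimuth in radians.
#' @return A 4x4 Mueller matrix.
#' @export
make_diattenuator <- function(d, theta = 0) {
  stopifnot(is.finite(d))
  L <- matrix(0, 4, 4)
  L[1, 2] <- L[2, 1] <- d
  if (theta != 0) L <- rotate_mueller(L, theta)
  mat_exp(L)
}

#' Diagonal depolarizer
#'
#' Mueller matrix `diag(1, exp(a22), exp(a33), exp(a44))` of a diagonal
#' depolarizer written through its depolarization generators. Non-positive
#' generators correspond to physical (intensity-preserving, polarization-
#' degrading) media.
#'
#' @param a22,a33,a44 Depolarization coefficients, each `<= 0` (linear 0-90,
#'   linear +/-45 and circular channels respectively).
#' @return A 4x4 Mueller matrix.
#' @export
make_depolarizer <- function(a22, a33, a44) {
  a <- c(a22, a33, a44)
  stopifnot(all(is.finite(a)))
  if (any(a > 0)) {
    stop("depolarization coefficients must be <= 0", call. = FALSE)
  }
  diag(c(1, exp(a)))
}

#' Random physical Mueller matrix
#'
#' Draws a random Mueller matrix as the exponential of a random generator
#' with entries bounded by `bound` (and zero intensity self-coupling), which
#' guarantees an invertible matrix whose principal logarithm exists and is
#' small. Intended as a property-test input generator.
#'
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @param bound Bound on the magnitude of the generator entries.
#' @return A 4x4 Mueller matrix.
#' @export
random_physical_mueller <- function(seed = NULL, bound = 0.3) {
  stopifnot(bound > 0, bound <= 0.5)
  draw <- function() {
    L <- matrix(runif(16, -bound, bound), 4, 4)
    L[1, 1] <- 0
    mat_exp(L)
  }
  if (is.null(seed)) {
    return(draw())
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  draw()
}

# ---------------------------------------------------------------------------
# Serialization: 4 lines x 4 whitespace-separated fields, or one 16-column
# row (m11..m44, row-major) in TSV with a one-line header.  The reader
# auto-detects the format.

#' Write a Mueller matrix to a plain-text file
#'
#' @param M A 4x4 Mueller matrix.
#' @param path Output file path.
#' @param format `"matrix"` for 4 lines of 4 fields, `"row"` for a one-row
#'   TSV with header `m11 ... m44` (row-major).
#' @return `path`, invisibly.
#' @export
write_mueller <- function(M, path, format = c("matrix", "row")) {
  M <- as_mueller(M)
  format <- match.arg(format)
  if (format == "matrix") {
    writeLines(apply(M, 1, function(r) paste(formatC(r, format = "g", digits = 17), collapse = "\t")), path)
  } else {
    hdr <- paste0("m", outer(1:4, 1:4, function(i, j) paste0(i, j)))
    hdr <- as.vector(t(matrix(hdr, 4, 4)))
    df <- as.data.frame(as.list(setNames(as.vector(t(M)), hdr)))
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a Mueller matrix from a plain-text file
#'
#' Auto-detects the two formats written by [write_mueller()].
#'
#' @param path Input file path.
#' @return A 4x4 Mueller matrix.
#' @export
read_mueller <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("m11", first, fixed = TRUE)) {
    df <- read.table(path, header = TRUE, sep = "\t")
    stopifnot(ncol(df) == 16)
    matrix(as.numeric(df[1, ]), 4, 4, byrow = TRUE)
  } else {
    M <- as.matrix(read.table(path, header = FALSE))
    stopifnot(all(dim(M) == c(4, 4)))
    unname(M)
  }
}
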