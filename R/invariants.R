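# Rotation invariants of the logarithmic decomposition.
#
# An in-plane rotation of the sample conjugates both M and L = ln M by the
# block rotation operator, so suitable combinations of the entries of L are
# unchanged by sample orientation.  The invariant set used throughout the
# package is {RT, DT, RC, DC, aL, a44, aLA}: total linear retardance and
# dichroism, circular birefringence and dichroism, isotropic linear
# depolarization, circular depolarization, and anisotropic linear
# depolarization.

#' @noRd
as_logm <- function(L) {
  if (inherits(L, "lmmd")) {
    return(L)
  }
  L <- as_mueller(L)
  sp <- g_split(L)
  structure(
    list(L = L, Lm = sp$Lm, Lu = sp$Lu, imag_residual = 0),
    class = "lmmd"
  )
}

#' Total linear retardance
#'
#' `RT = sqrt(Lm24^2 + Lm34^2) = sqrt((L24 - L42)^2 + (L34 - L43)^2) / 2`,
#' invariant under in-plane sample rotation; equals `delta` for a pure
#' retarder of retardance `delta` at any axis.
#'
#' @param L A real 4x4 logarithm matrix or an `"lmmd"` object.
#' @return Non-negative scalar, radians.
#' @export
total_linear_retardance <- function(L) {
  d <- as_logm(L)
  sqrt(d$Lm[2, 4]^2 + d$Lm[3, 4]^2)
}

#' Total linear dichroism
#'
#' `DT = sqrt(Lm12^2 + Lm13^2) = sqrt((L12 + L21)^2 + (L13 + L31)^2) / 2`,
#' rotation invariant; equals `abs(d)` for [make_diattenuator()] fixtures.
#'
#' @inheritParams total_linear_retardance
#' @return Non-negative scalar, dimensionless.
#' @export
total_linear_dichroism <- function(L) {
  d <- as_logm(L)
  sqrt(d$Lm[1, 2]^2 + d$Lm[1, 3]^2)
}

#' Circular birefringence
#'
#' `RC = (L23 - L32) / 2`, the circular-retardance generator (optical
#' activity); a pure rotator by azimuth `alpha` has `abs(RC) = 2 * alpha`.
#'
#' @inheritParams total_linear_retardance
#' @return Scalar, radians.
#' @export
circular_birefringence <- function(L) {
  d <- as_logm(L)
  d$Lm[2, 3]
}

#' Circular dichroism
#'
#' `DC = (L14 + L41) / 2`.
#'
#' @inheritParams total_linear_retardance
#' @return Scalar, dimensionless.
#' @export
circular_dichroism <- function(L) {
  d <- as_logm(L)
  d$Lm[1, 4]
}

#' Isotropic linear depolarization
#'
#' `aL = (a22 + a33) / 2 = (Lu22 + Lu33) / 2`, the rotation-invariant mean of
#' the two linear depolarization coefficients.
#'
#' @inheritParams total_linear_retardance
#' @return Scalar, dimensionless (typically `<= 0`).
#' @export
isotropic_linear_depolarization <- function(L) {
  d <- as_logm(L)
  (d$Lu[2, 2] + d$Lu[3, 3]) / 2
}

#' Circular depolarization
#'
#' `a44 = Lu44 = L44`, untouched by in-plane rotation.
#'
#' @inheritParams total_linear_retardance
#' @return Scalar, dimensionless (typically `<= 0`).
#' @export
circular_depolarization <- function(L) {
  d <- as_logm(L)
  d$Lu[4, 4]
}

#' Anisotropic linear depolarization
#'
#' `aLA = sqrt((a22 - a33)^2 + (Lu23 + Lu32)^2) / 2`, the rotation-invariant
#' magnitude of the anisotropy of linear depolarization, built from the
#' depolarization part `Lu` the same way the degree-of-anisotropy parameter
#' of Mueller matrix transformation theory is built from M. It vanishes for
#' isotropic depolarizers and is reported unsigned.
#'
#' @inheritParams total_linear_retardance
#' @return Non-negative scalar, dimensionless.
#' @export
anisotropic_linear_depolarization <- function(L) {
  d <- as_logm(L)
  sqrt((d$Lu[2, 2] - d$Lu[3, 3])^2 + (d$Lu[2, 3] + d$Lu[3, 2])^2) / 2
}

#' Rotation-invariant parameter set of a Mueller matrix
#'
#' Convenience composition: normalize, take the matrix logarithm, split, and
#' evaluate all seven rotation invariants. Accepts a single matrix or a list
#' of matrices (one output row each).
#'
#' @param M A 4x4 Mueller matrix (normalizable, with a principal logarithm),
#'   an `"lmmd"` object, or a list of either.
#' @param id Optional identifier column recycled along rows.
#' @param branch Branch handling passed to [mueller_log()]; the Monte Carlo
#'   pipeline uses `"boundary"` for noisy matrices near retardance `pi`.
#' @return A tibble with columns `RT, DT, RC, DC, aL, a44, aLA,
#'   imag_residual` (and `id` when supplied).
#' @examples
#' invariant_set(make_retarder(0.7, 0.2))
#' @export
invariant_set <- function(M, id = NULL, branch = c("error", "boundary")) {
  branch <- match.arg(branch)
  warn_at <- if (branch == "boundary") Inf else 1e-6
  one <- function(m) {
    d <- if (inherits(m, "lmmd")) {
      m
    } else {
      mueller_log(normalize_mueller(as_mueller(m)),
        warn_residual = warn_at, branch = branch
      )
    }
    tibble::tibble(
      RT = total_linear_retardance(d),
      DT = total_linear_dichroism(d),
      RC = circular_birefringence(d),
      DC = circular_dichroism(d),
      aL = isotropic_linear_depolarization(d),
      a44 = circular_depolarization(d),
      aLA = anisotropic_linear_depolarization(d),
      imag_residual = d$imag_residual
    )
  }
  is_single <- inherits(M, "lmmd") || (is.matrix(M) && all(dim(M) == c(4, 4)))
  out <- if (is_single) one(M) else purrr::map_dfr(M, one)
  if (!is.null(id)) {
    out <- tibble::add_column(out, id = rep_len(id, nrow(out)), .before = 1)
  }
  out
}

#' Write invariant sets as TSV
#'
#' Batch serialization: one row per input matrix with columns
#' `id, RT, DT, RC, DC, aL, a44, aLA, imag_residual`.
#'
#' @param M A list of Mueller matrices (or a single matrix).
#' @param path Output file path.
#' @param id Identifiers for the rows; defaults to `1..n`.
#' @return The tibble written, invisibly.
#' @export
write_invariants <- function(M, path, id = NULL) {
  if (is.matrix(M)) M <- list(M)
  if (is.null(id)) id <- seq_along(M)
  tab <- invariant_set(M, id = id)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
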