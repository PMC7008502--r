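# Logarithmic Mueller matrix decomposition (LMMD).
#
# The matrix logarithm L = ln M of a normalized Mueller matrix collects the
# differential optical properties accumulated through the medium.  Splitting
# L with the metric G = diag(1, -1, -1, -1) into a G-antisymmetric part Lm
# (retardance and dichroism generators) and a G-symmetric part Lu
# (depolarization generators) separates deterministic polarization effects
# from depolarization.

#' Matrix logarithm of a Mueller matrix
#'
#' Computes the principal matrix logarithm `L = ln(M)` through the complex
#' eigendecomposition of `M`, realifies it, and splits it into the
#' G-antisymmetric polarization part `Lm` and the G-symmetric depolarization
#' part `Lu` (see [g_split()]). The maximum imaginary magnitude discarded
#' during realification is recorded as `imag_residual` rather than silently
#' dropped; for analytic inputs it is at numerical noise level, while values
#' above ~1e-6 on Monte Carlo matrices trigger a warning.
#'
#' Only the principal branch is used, so a total retardance of `pi` or more
#' is not representable: inputs with eigenvalues on the closed negative real
#' axis raise an error instead of guessing a branch. Nearly defective inputs
#' fall back to an inverse scaling-and-squaring logarithm; the result is
#' validated by the `exp(L) = M` round trip, not by the algorithm used.
#'
#' @param M A normalized Mueller matrix (`m11 = 1`, see
#'   [normalize_mueller()]), invertible, with a principal logarithm.
#' @param warn_residual Threshold on `imag_residual` above which a warning is
#'   emitted (noisy simulated matrices).
#' @param branch `"error"` (default): eigenvalues on the negative real axis
#'   are a hard error. `"boundary"`: an even pair of negative real
#'   eigenvalues is assigned the limiting phases of a conjugate pair at
#'   `+/- pi` (retardance exactly `pi`, the principal-branch boundary);
#'   used by the Monte Carlo pipeline, where shot noise can park a
#'   high-retardance matrix exactly on the cut.
#' @return An object of class `"lmmd"`: a list with elements `L`, `Lm`, `Lu`
#'   (4x4 real matrices, `Lm + Lu == L`) and `imag_residual`.
#' @examples
#' dec <- mueller_log(make_retarder(0.5, 0))
#' dec$Lm[3, 4] # 0.5
#' @export
mueller_log <- function(M, warn_residual = 1e-6,
                        branch = c("error", "boundary")) {
  M <- as_mueller(M)
  if (abs(M[1, 1] - 1) > 1e-6) {
    stop("Mueller matrix must be normalized (m11 = 1); see normalize_mueller()",
      call. = FALSE
    )
  }
  lg <- mat_log_eigen(M, branch = match.arg(branch))
  if (lg$imag_residual > warn_residual) {
    warning(
      sprintf(
        "imaginary residual %.3g discarded when realifying ln(M); matrix may be strongly non-physical",
        lg$imag_residual
      ),
      call. = FALSE
    )
  }
  sp <- g_split(lg$L)
  structure(
    list(L = lg$L, Lm = sp$Lm, Lu = sp$Lu, imag_residual = lg$imag_residual),
    class = "lmmd"
  )
}

#' Split a logarithm into polarization and depolarization parts
#'
#' Decomposes a real 4x4 matrix `L` into its G-antisymmetric component
#' `Lm = (L - G t(L) G) / 2` (retardance/dichroism generators) and
#' G-symmetric component `Lu = (L + G t(L) G) / 2` (depolarization
#' generators), with `G = diag(1, -1, -1, -1)`. The split is exact:
#' `Lm + Lu == L`.
#'
#' @param L A real 4x4 matrix.
#' @return A list with components `Lm` and `Lu`.
#' @export
g_split <- function(L) {
  L <- as_mueller(L)
  G <- g_metric()
  GtG <- G %*% t(L) %*% G
  list(Lm = (L - GtG) / 2, Lu = (L + GtG) / 2)
}

#' Elementary LMMD coefficients
#'
#' Extracts the named elementary polarization and depolarization coefficients
#' from a decomposition: linear dichroism `LD` (0-90 frame) and `LDp` (+/-45
#' frame), circular dichroism `CD`, circular retardance `CB`, linear
#' retardance `LB` (0-90) and `LBp` (+/-45), and the diagonal depolarization
#' coefficients `a22`, `a33`, `a44`. Signs are fixed such that
#' `make_retarder(delta, 0)` yields `LB = +delta`.
#'
#' @param dec An `"lmmd"` object from [mueller_log()], or a 4x4 Mueller
#'   matrix (decomposed on the fly).
#' @return A one-row tibble with columns `LD, LDp, CD, CB, LB, LBp, a22,
#'   a33, a44`.
#' @examples
#' lmmd_coefficients(make_retarder(0.5, 0)) # LB = 0.5, all others 0
#' @export
lmmd_coefficients <- function(dec) {
  dec <- as_lmmd(dec)
  Lm <- dec$Lm
  Lu <- dec$Lu
  tibble::tibble(
    LD = Lm[1, 2], LDp = Lm[1, 3], CD = Lm[1, 4],
    CB = Lm[2, 3], LB = Lm[3, 4], LBp = Lm[4, 2],
    a22 = Lu[2, 2], a33 = Lu[3, 3], a44 = Lu[4, 4]
  )
}

#' @noRd
as_lmmd <- function(x) {
  if (inherits(x, "lmmd")) {
    return(x)
  }
  mueller_log(as_mueller(x))
}

#' @export
print.lmmd <- function(x, digits = 4, ...) {
  cat("Logarithmic Mueller matrix decomposition\n")
  cat("  imag residual:", format(x$imag_residual, digits = 3), "\n")
  cat("  L:\n")
  print(round(x$L, digits))
  co <- lmmd_coefficients(x)
  cat("  coefficients:\n")
  print(as.data.frame(co), row.names = FALSE, digits = digits)
  invisible(x)
}

#' Tidy an LMMD decomposition
#'
#' @param x An `"lmmd"` object.
#' @param ... Unused.
#' @return A tibble with one row per elementary coefficient (`term`,
#'   `estimate`).
#' @method tidy lmmd
#' @export
tidy.lmmd <- function(x, ...) {
  co <- lmmd_coefficients(x)
  tibble::tibble(term = names(co), estimate = as.numeric(co[1, ]))
}

#' One-row decomposition summary
#'
#' @param x An `"lmmd"` object.
#' @param ... Unused.
#' @return A one-row tibble with the imaginary residual and the round-trip
#'   reconstruction error `max(abs(exp(L) - M))` when `M` is reconstructable.
#' @method glance lmmd
#' @export
glance.lmmd <- function(x, ...) {
  rt <- max(abs(mat_exp(x$L) - mat_exp(x$Lm + x$Lu)))
  tibble::tibble(imag_residual = x$imag_residual, split_closure = rt)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write a decomposition as a flat JSON record
#'
#' Serializes `L`, `Lm`, `Lu` as 16-element row-major arrays together with
#' the named elementary coefficients and the imaginary residual.
#'
#' @param dec An `"lmmd"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lmmd <- function(dec, path) {
  stopifnot(inherits(dec, "lmmd"))
  co <- lmmd_coefficients(dec)
  rec <- c(
    list(
      L = as.vector(t(dec$L)),
      Lm = as.vector(t(dec$Lm)),
      Lu = as.vector(t(dec$Lu)),
      imag_residual = dec$imag_residual
    ),
    as.list(co)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
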