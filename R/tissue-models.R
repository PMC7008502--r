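# Named optical models of the skin dermal layer.
#
# SC:  spheres + cylinders in an isotropic host (no birefringence)
# SB:  spheres in a uniaxial linearly birefringent host (no cylinders)
# SCB: spheres + cylinders in a birefringent host
#
# Spheres stand for isotropic scattering on cells and organelles; aligned
# infinite cylinders for collagen fibrils (form birefringence); the host
# birefringence for the intrinsic anisotropy of the aligned extracellular
# matrix.  Defaults follow the best-fit dermal parameterization: indices
# 1.45 (scatterers) / 1.33 (host), wavelength 0.533 um, sphere radius
# 0.05 um, mu_s = 1500 cm^-1, delta_n = 0.009, cylinder radius 0.05 um with
# the cylinder and optic axes along laboratory X.

#' @noRd
preset_defaults <- function() {
  list(
    SC = list(delta_n = 0, mu_s_cm = 1500, mu_c_cm = 1500),
    SB = list(delta_n = 0.009, mu_s_cm = 1500, mu_c_cm = 0),
    SCB = list(delta_n = 0.009, mu_s_cm = 1500, mu_c_cm = 1500)
  )
}

#' Studied parameter envelope (warnings outside, not errors)
#' @noRd
check_envelope <- function(cfg) {
  warn <- function(...) warning(..., call. = FALSE)
  dia <- c(2 * cfg$radius_sphere_um, if (cfg$mu_c_cm > 0) 2 * cfg$radius_cylinder_um)
  if (any(dia < 0.01 | dia > 4)) {
    warn("scatterer diameter outside the studied 0.01-4 um envelope")
  }
  mus <- c(cfg$mu_s_cm, cfg$mu_c_cm)
  mus <- mus[mus > 0]
  if (any(mus < 5 | mus > 5000)) {
    warn("scattering coefficient outside the studied 5-5000 cm^-1 envelope")
  }
  if (cfg$delta_n > 0 && (cfg$delta_n < 1e-5 || cfg$delta_n > 0.01)) {
    warn("host birefringence outside the studied envelope (1e-5 to 1e-3, best fit 0.009)")
  }
  invisible(cfg)
}

#' Preset dermal-layer optical models
#'
#' Builds a fully populated [model_config()] for one of the named optical
#' models of the dermal layer and a given slab thickness. Overrides are
#' shallow-merged over the preset defaults; an override that contradicts
#' the model class (cylinders in SB, birefringence in SC) is an error.
#'
#' @param name `"SC"`, `"SB"` or `"SCB"`.
#' @param thickness_um Slab thickness, micrometers (default 30).
#' @param ... Named overrides passed to [model_config()].
#' @return A `"model_config"` with attribute `model` set to `name`.
#' @examples
#' make_preset("SB", thickness_um = 10)
#' @export
make_preset <- function(name, thickness_um = 30, ...) {
  name <- match.arg(name, c("SC", "SB", "SCB"))
  over <- list(...)
  base <- preset_defaults()[[name]]
  args <- modifyList(c(list(thickness_um = thickness_um), base), over)
  cfg <- suppressWarnings(do.call(model_config, args))
  if (name == "SC" && cfg$delta_n > 0) {
    stop("SC model has an isotropic host: delta_n must be 0", call. = FALSE)
  }
  if (name == "SB" && cfg$mu_c_cm > 0) {
    stop("SB model has no cylindrical scatterers: mu_c must be 0", call. = FALSE)
  }
  if (name == "SCB" && !(cfg$mu_c_cm > 0 && cfg$delta_n > 0)) {
    stop("SCB model requires cylinders (mu_c > 0) and a birefringent host (delta_n > 0)",
      call. = FALSE
    )
  }
  check_envelope(cfg)
  attr(cfg, "model") <- name
  cfg
}

#' List the available model presets
#'
#' @return A tibble with the model names, their defining constraints and
#'   default scattering parameters.
#' @export
list_presets <- function() {
  d <- preset_defaults()
  tibble::tibble(
    model = names(d),
    delta_n = unname(vapply(d, `[[`, numeric(1), "delta_n")),
    mu_s_cm = unname(vapply(d, `[[`, numeric(1), "mu_s_cm")),
    mu_c_cm = unname(vapply(d, `[[`, numeric(1), "mu_c_cm")),
    description = c(
      "spheres + cylinders, isotropic host",
      "spheres in uniaxial birefringent host",
      "spheres + cylinders in uniaxial birefringent host"
    )
  )
}
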