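# Polarized Monte Carlo transport through a slab: configuration, the
# simulation driver, spatial averaging and batch standard errors.

#' Slab model configuration
#'
#' Full parameterization of one transmission simulation: a slab of thickness
#' `thickness_um` containing monodisperse spherical and/or infinitely long
#' cylindrical scatterers, embedded in an isotropic (`delta_n = 0`) or
#' uniaxial linearly birefringent host with in-plane optic axis. A pencil
#' beam enters at normal incidence; transmitted photons are binned on a
#' square pixel grid and averaged over a central detection circle.
#'
#' Scattering coefficients are given directly as inverse mean free paths in
#' cm^-1 (the conventional unit of the field) and converted internally to
#' um^-1; number densities are never computed. The slab is index-matched
#' (no Fresnel reflection or refraction at the faces) and non-absorbing.
#'
#' @param thickness_um Slab thickness, micrometers.
#' @param wavelength_um Vacuum wavelength, micrometers.
#' @param mu_s_cm,mu_c_cm Scattering coefficients of spheres and cylinders,
#'   cm^-1 (inverse mean free path).
#' @param radius_sphere_um,radius_cylinder_um Scatterer radii, micrometers.
#' @param n_sphere,n_cylinder,n_host Absolute refractive indices; `n_host`
#'   is the ordinary index of the host.
#' @param delta_n Host birefringence: extraordinary index is
#'   `n_host + delta_n`.
#' @param optic_axis,cylinder_axis In-plane unit vectors (z component must
#'   be 0); defaults are the laboratory X axis.
#' @param n_photons Photons launched per input polarization state.
#' @param n_batches Number of independent batches used for Monte Carlo
#'   standard errors; `n_photons` must be divisible by it.
#' @param seed Base integer seed; every (state, batch) pair derives its own
#'   substream deterministically from it.
#' @param detector_diameter_um Diameter of the central averaging circle.
#' @param image_pixels,image_pitch_um Detection grid size (odd) and pixel
#'   pitch.
#' @param lateral_halfwidth_um Photons leaving this lateral half-width are
#'   dropped and counted as lost.
#' @param max_events Safety cap on scattering events per photon.
#' @return An object of class `"model_config"` (a named list).
#' @export
model_config <- function(thickness_um,
                         wavelength_um = 0.533,
                         mu_s_cm = 0,
                         mu_c_cm = 0,
                         radius_sphere_um = 0.05,
                         radius_cylinder_um = 0.05,
                         n_sphere = 1.45,
                         n_cylinder = 1.45,
                         n_host = 1.33,
                         delta_n = 0,
                         optic_axis = c(1, 0, 0),
                         cylinder_axis = c(1, 0, 0),
                         n_photons = 1e5,
                         n_batches = 10,
                         seed = 1,
                         detector_diameter_um = 600,
                         image_pixels = 81,
                         image_pitch_um = 25,
                         lateral_halfwidth_um = 3000,
                         max_events = 1e5) {
  stopifnot(
    thickness_um > 0, wavelength_um > 0, mu_s_cm >= 0, mu_c_cm >= 0,
    radius_sphere_um > 0, radius_cylinder_um > 0,
    n_sphere > 0, n_cylinder > 0, n_host > 0, delta_n >= 0,
    n_photons >= 1, n_batches >= 1, detector_diameter_um >= 0,
    image_pixels >= 1, image_pitch_um > 0, lateral_halfwidth_um > 0,
    max_events > 0
  )
  norm_axis <- function(a, what) {
    stopifnot(length(a) == 3)
    if (abs(a[3]) > 1e-9) {
      stop(what, " must lie in the slab plane (z component 0)", call. = FALSE)
    }
    a / sqrt(sum(a^2))
  }
  optic_axis <- norm_axis(optic_axis, "optic_axis")
  cylinder_axis <- norm_axis(cylinder_axis, "cylinder_axis")
  if (detector_diameter_um > image_pixels * image_pitch_um) {
    stop("detection circle exceeds the image grid extent", call. = FALSE)
  }
  cfg <- list(
    thickness_um = thickness_um, wavelength_um = wavelength_um,
    mu_s_cm = mu_s_cm, mu_c_cm = mu_c_cm,
    radius_sphere_um = radius_sphere_um,
    radius_cylinder_um = radius_cylinder_um,
    n_sphere = n_sphere, n_cylinder = n_cylinder, n_host = n_host,
    delta_n = delta_n, optic_axis = optic_axis,
    cylinder_axis = cylinder_axis,
    n_photons = as.integer(n_photons), n_batches = as.integer(n_batches),
    seed = as.integer(seed),
    detector_diameter_um = detector_diameter_um,
    image_pixels = as.integer(image_pixels),
    image_pitch_um = image_pitch_um,
    lateral_halfwidth_um = lateral_halfwidth_um,
    max_events = as.integer(max_events)
  )
  structure(cfg, class = "model_config")
}

# Internal: engine-facing parameter list with unit conversions applied once.
#' @noRd
engine_params <- function(cfg) {
  list(
    thickness_um = cfg$thickness_um,
    mu_s_um = cfg$mu_s_cm * 1e-4,
    mu_c_um = cfg$mu_c_cm * 1e-4,
    wavelength_um = cfg$wavelength_um,
    x_sphere = 2 * pi * cfg$radius_sphere_um * cfg$n_host / cfg$wavelength_um,
    m_sphere = cfg$n_sphere / cfg$n_host,
    x_cylinder = 2 * pi * cfg$radius_cylinder_um * cfg$n_host / cfg$wavelength_um,
    m_cylinder = cfg$n_cylinder / cfg$n_host,
    delta_n = cfg$delta_n,
    n_host = cfg$n_host,
    optic_axis = cfg$optic_axis,
    cylinder_axis = cfg$cylinder_axis,
    image_pixels = cfg$image_pixels,
    image_pitch_um = cfg$image_pitch_um,
    detector_diameter_um = cfg$detector_diameter_um,
    lateral_halfwidth_um = cfg$lateral_halfwidth_um,
    max_events = cfg$max_events
  )
}

# The four input polarization states used to assemble a Mueller matrix.
#' @noRd
input_states <- function() {
  list(
    H = c(1, 1, 0, 0),
    V = c(1, -1, 0, 0),
    P = c(1, 0, 1, 0),
    R = c(1, 0, 0, 1)
  )
}

#' @noRd
derive_seed <- function(seed, state_idx, batch_idx, extra = 0L) {
  # keep the derived stream seeds positive and below 2^31
  s <- (as.numeric(seed) * 1000003 + state_idx * 7919 + batch_idx * 104729 +
    extra * 15485863) %% 2147483629
  s + 1
}

#' Sample exponential free paths
#'
#' Draws propagation distances `s = -log(U) / mu` between interaction
#' events, converted to micrometers from a scattering coefficient in cm^-1.
#' Uses R's RNG stream.
#'
#' @param n Number of draws.
#' @param mu_cm Total scattering coefficient, cm^-1 (`> 0`).
#' @return Numeric vector of path lengths in micrometers.
#' @examples
#' set.seed(1)
#' mean(sample_free_path(1e4, 1500)) # ~ 6.67 um
#' @export
sample_free_path <- function(n, mu_cm) {
  if (!(mu_cm > 0)) {
    stop("mu must be positive; mu = 0 means ballistic flight to the boundary",
      call. = FALSE
    )
  }
  -log(runif(n)) / (mu_cm * 1e-4)
}

#' Sample the scatterer type for an interaction
#'
#' Competing-interaction rule: the event is a sphere with probability
#' `mu_s / (mu_s + mu_c)`.
#'
#' @param n Number of draws.
#' @param mu_s_cm,mu_c_cm Sphere and cylinder scattering coefficients.
#' @return Character vector of `"sphere"` / `"cylinder"`.
#' @export
sample_scatterer_type <- function(n, mu_s_cm, mu_c_cm) {
  if (mu_s_cm + mu_c_cm <= 0) {
    stop("at least one scattering coefficient must be positive", call. = FALSE)
  }
  ifelse(runif(n) < mu_s_cm / (mu_s_cm + mu_c_cm), "sphere", "cylinder")
}

#' Birefringence retarder for a straight flight segment
#'
#' The uniaxial host acts on each straight segment as a linear retarder with
#' retardance `delta = (2 pi / lambda) (n_e(theta_p) - n_o) s`, where
#' `theta_p` is the angle between the propagation direction and the optic
#' axis, `1 / n_e(theta_p)^2 = cos^2(theta_p) / n_o^2 + sin^2(theta_p) /
#' n_e^2`, and the retarder axis is the projection of the optic axis onto
#' the plane transverse to propagation. Ray splitting, walk-off and
#' direction-dependent refraction are neglected (justified for
#' `delta_n <= ~0.01` at tissue-cut thicknesses).
#'
#' @param direction Unit propagation direction (length 3).
#' @param path_um Segment length, micrometers.
#' @param config A [model_config()].
#' @return A list with `delta` (radians), `axis_angle` (radians, in the
#'   transverse plane measured from the laboratory-X meridian convention of
#'   the caller) and `mueller`, the 4x4 retarder referenced to a frame whose
#'   first basis vector is the transverse optic-axis projection.
#' @export
birefringence_retarder <- function(direction, path_um, config) {
  stopifnot(inherits(config, "model_config"), length(direction) == 3)
  v <- direction / sqrt(sum(direction^2))
  nmo <- config$n_host
  nme <- nmo + config$delta_n
  cth <- sum(v * config$optic_axis)
  sth2 <- max(0, 1 - cth^2)
  if (config$delta_n == 0 || sth2 < 1e-24) {
    return(list(delta = 0, axis_angle = 0, mueller = diag(4)))
  }
  ne_th <- 1 / sqrt(cth^2 / nmo^2 + sth2 / nme^2)
  delta <- 2 * pi / config$wavelength_um * (ne_th - nmo) * path_um
  p <- config$optic_axis - cth * v
  p <- p / sqrt(sum(p^2))
  list(
    delta = delta,
    axis_angle = atan2(p[2], p[1]),
    mueller = make_retarder(delta, 0)
  )
}

#' Run a polarized Monte Carlo transmission simulation
#'
#' Transports `n_photons` photons per input polarization state (H, V, +45,
#' right-circular) through the slab described by `config`, assembles the
#' transmission Mueller matrix image from the four runs, and averages it
#' over the central detection circle. Each (state, batch) pair uses its own
#' deterministic RNG substream, so results are exactly reproducible for a
#' given `(config, seed)`.
#'
#' @param config A [model_config()].
#' @return An object of class `"mc_result"`: a list with elements
#'   * `mueller`: the averaged, normalized 4x4 Mueller matrix;
#'   * `m11_raw`: detected-intensity scale of the average before
#'     normalization (per launched photon);
#'   * `image`: a `"mueller_image"` object (per-pixel 16-component sums);
#'   * `batch_mueller`: list of per-batch averaged matrices;
#'   * `counts`: tibble of photon fates (each launched photon is classified
#'     exactly once);
#'   * `invariants`: one-row tibble of rotation invariants with batch
#'     standard errors;
#'   * `config`: the input configuration.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "model_config"))
  par <- engine_params(config)
  states <- input_states()
  nb <- config$n_batches
  np <- config$n_photons
  per_batch <- np %/% nb
  if (per_batch * nb != np) {
    stop("n_photons must be divisible by n_batches", call. = FALSE)
  }
  nx <- config$image_pixels
  state_imgs <- lapply(states, function(s) array(0, c(nx, nx, 4)))
  batch_sums <- array(0, c(4, nb, 4),
    dimnames = list(names(states), NULL, c("I", "Q", "U", "V"))
  )
  counts <- c(
    transmitted_detected = 0, transmitted_undetected = 0,
    reflected = 0, lost = 0
  )
  mask <- circle_mask(nx, config$image_pitch_um, config$detector_diameter_um)
  for (i in seq_along(states)) {
    for (b in seq_len(nb)) {
      sd_i <- derive_seed(config$seed, i, b)
      res <- cpp_transport(par, states[[i]], per_batch, sd_i)
      state_imgs[[i]] <- state_imgs[[i]] + res$image
      counts <- counts + res$counts
      batch_sums[i, b, ] <- apply(res$image, 3, function(sl) sum(sl[mask]))
    }
  }
  if (counts[["transmitted_detected"]] == 0) {
    stop("no photons reached the detector; increase n_photons or check the configuration",
      call. = FALSE
    )
  }
  # columns of M from the four state responses (per launched photon)
  assemble <- function(sH, sV, sP, sR) {
    c1 <- (sH + sV) / 2
    cbind(c1, (sH - sV) / 2, sP - c1, sR - c1)
  }
  state_tot <- sapply(seq_along(states), function(i) {
    apply(state_imgs[[i]], 3, function(sl) sum(sl[mask])) / np
  }) # 4 (stokes) x 4 (states)
  M_raw <- assemble(state_tot[, 1], state_tot[, 2], state_tot[, 3], state_tot[, 4])
  m11_raw <- M_raw[1, 1]
  M <- normalize_mueller(M_raw)
  batch_mueller <- lapply(seq_len(nb), function(b) {
    sb <- t(batch_sums[, b, ]) / per_batch # stokes x state
    Mb <- assemble(sb[, 1], sb[, 2], sb[, 3], sb[, 4])
    normalize_mueller(Mb)
  })
  # per-pixel Mueller image (sums; normalized per launched photon on use)
  img16 <- array(0, c(nx, nx, 16))
  for (r in 1:4) {
    cols <- assemble_pixel(state_imgs, r)
    for (cc in 1:4) img16[, , 4 * (r - 1) + cc] <- cols[[cc]]
  }
  image <- structure(
    list(
      sums = img16, pitch_um = config$image_pitch_um,
      n_per_state = np
    ),
    class = "mueller_image"
  )
  se <- mc_standard_error(batch_mueller, min_batches = min(10, nb))
  inv <- invariant_set(M, branch = "boundary")
  out <- list(
    mueller = M, m11_raw = m11_raw, image = image,
    batch_mueller = batch_mueller,
    counts = tibble::tibble(class = names(counts), n = as.numeric(counts)),
    invariants = inv, se = se, config = config
  )
  structure(out, class = "mc_result")
}

# per-pixel column assembly for Stokes component r (1=I, .., 4=V)
#' @noRd
assemble_pixel <- function(state_imgs, r) {
  sH <- state_imgs[[1]][, , r]
  sV <- state_imgs[[2]][, , r]
  sP <- state_imgs[[3]][, , r]
  sR <- state_imgs[[4]][, , r]
  c1 <- (sH + sV) / 2
  list(c1, (sH - sV) / 2, sP - c1, sR - c1)
}

#' @noRd
circle_mask <- function(nx, pitch, diameter) {
  half <- nx * pitch / 2
  centers <- (seq_len(nx) - 0.5) * pitch - half
  r2 <- outer(centers^2, centers^2, "+")
  if (diameter <= 0) {
    # degenerate circle: the central pixel
    m <- matrix(FALSE, nx, nx)
    m[(nx + 1) %/% 2, (nx + 1) %/% 2] <- TRUE
    return(m)
  }
  r2 <= (diameter / 2)^2
}

#' Spatially average a Mueller image over a central circle
#'
#' Intensity-weighted mean of the 16 per-pixel accumulators over pixels
#' whose centers lie within the circle of the given diameter, followed by
#' normalization to `m11 = 1`. `diameter = 0` degenerates to the central
#' pixel.
#'
#' @param image A `"mueller_image"` from [run_simulation()].
#' @param diameter_um Averaging-circle diameter, micrometers (must fit in
#'   the grid).
#' @return A normalized 4x4 Mueller matrix.
#' @export
spatial_average <- function(image, diameter_um) {
  stopifnot(inherits(image, "mueller_image"))
  nx <- dim(image$sums)[1]
  if (diameter_um > nx * image$pitch_um) {
    stop("averaging circle exceeds the image grid", call. = FALSE)
  }
  mask <- circle_mask(nx, image$pitch_um, diameter_um)
  s <- apply(image$sums, 3, function(sl) sum(sl[mask]))
  if (s[1] <= 0) stop("empty averaging region", call. = FALSE)
  normalize_mueller(matrix(s, 4, 4, byrow = TRUE))
}

#' Monte Carlo standard errors of the rotation invariants
#'
#' Estimates per-invariant standard errors from independent batches. For the
#' signed invariants (RC, DC, aL, a44) the SE is the batch standard
#' deviation over `sqrt(n_batches)`. The square-root invariants (RT, DT,
#' aLA) are positively biased under their null, so their SEs are propagated
#' from the batch SEs of the underlying *signed* components (e.g. for aLA
#' from `a22 - a33` and `Lu23 + Lu32`); this gives the correct null
#' distribution for "consistent with zero" checks and reduces to the
#' delta-method SE when the signal dominates.
#'
#' @param batch_mueller A list of at least `min_batches` independent
#'   normalized Mueller matrices (one per batch).
#' @param min_batches Minimum number of batches required (default 10).
#' @return A tibble with columns `invariant`, `estimate` (from the averaged
#'   components), `se`.
#' @export
mc_standard_error <- function(batch_mueller, min_batches = 10) {
  nb <- length(batch_mueller)
  if (nb < min_batches) {
    stop("need at least ", min_batches, " independent batches", call. = FALSE)
  }
  comp <- purrr::map_dfr(batch_mueller, function(M) {
    d <- mueller_log(normalize_mueller(M), warn_residual = Inf, branch = "boundary")
    tibble::tibble(
      RT_x = d$Lm[2, 4], RT_y = d$Lm[3, 4],
      DT_x = d$Lm[1, 2], DT_y = d$Lm[1, 3],
      RC = d$Lm[2, 3], DC = d$Lm[1, 4],
      aL = (d$Lu[2, 2] + d$Lu[3, 3]) / 2, a44 = d$Lu[4, 4],
      aLA_x = (d$Lu[2, 2] - d$Lu[3, 3]) / 2,
      aLA_y = (d$Lu[2, 3] + d$Lu[3, 2]) / 2
    )
  })
  m <- colMeans(comp)
  s <- vapply(comp, sd, numeric(1)) / sqrt(nb)
  root_est <- function(a, b) sqrt(m[[a]]^2 + m[[b]]^2)
  root_se <- function(a, b) sqrt(s[[a]]^2 + s[[b]]^2)
  tibble::tibble(
    invariant = c("RT", "DT", "RC", "DC", "aL", "a44", "aLA"),
    estimate = c(
      root_est("RT_x", "RT_y"), root_est("DT_x", "DT_y"),
      m[["RC"]], m[["DC"]], m[["aL"]], m[["a44"]],
      root_est("aLA_x", "aLA_y")
    ),
    se = c(
      root_se("RT_x", "RT_y"), root_se("DT_x", "DT_y"),
      s[["RC"]], s[["DC"]], s[["aL"]], s[["a44"]],
      root_se("aLA_x", "aLA_y")
    )
  )
}

#' @export
print.mc_result <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat(sprintf(
    "Monte Carlo transmission simulation: d = %g um, mu_s = %g cm^-1, mu_c = %g cm^-1, delta_n = %g\n",
    cfg$thickness_um, cfg$mu_s_cm, cfg$mu_c_cm, cfg$delta_n
  ))
  cat(sprintf(
    "  %d photons/state in %d batches, seed %d\n",
    cfg$n_photons, cfg$n_batches, cfg$seed
  ))
  cat("  photon fates:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("  averaged Mueller matrix (normalized):\n")
  print(round(x$mueller, digits))
  cat("  invariants:\n")
  print(as.data.frame(x$invariants), row.names = FALSE, digits = digits)
  invisible(x)
}

#' Tidy a simulation result
#'
#' @param x An `"mc_result"`.
#' @param ... Unused.
#' @return A tibble with one row per invariant: `invariant`, `estimate`,
#'   `se`.
#' @method tidy mc_result
#' @export
tidy.mc_result <- function(x, ...) {
  x$se
}

#' One-row simulation summary
#'
#' @param x An `"mc_result"`.
#' @param ... Unused.
#' @return A one-row tibble: detected fraction, raw transmittance scale and
#'   the decomposition imaginary residual.
#' @method glance mc_result
#' @export
glance.mc_result <- function(x, ...) {
  det <- x$counts$n[x$counts$class == "transmitted_detected"]
  tibble::tibble(
    detected_fraction = det / (4 * x$config$n_photons),
    m11_raw = x$m11_raw,
    imag_residual = x$invariants$imag_residual[1]
  )
}

# ---------------------------------------------------------------------------
# configuration and image serialization

#' Write / read a model configuration
#'
#' JSON or YAML, keyed as the arguments of [model_config()]; the format is
#' chosen from the file extension.
#'
#' @param config A `"model_config"`.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `path` (write) or the configuration (read).
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  rec <- unclass(config)
  if (!is.null(attr(config, "model"))) rec$model <- attr(config, "model")
  attributes(rec) <- list(names = names(rec))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(rec, path)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  model <- rec$model
  rec$model <- NULL
  cfg <- do.call(model_config, rec)
  if (!is.null(model)) attr(cfg, "model") <- model
  cfg
}

#' Write a Mueller image as TSV
#'
#' One row per pixel: `x_um, y_um, m11..m44` (per launched photon) and the
#' detected intensity sum.
#'
#' @param image A `"mueller_image"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mueller_image <- function(image, path) {
  stopifnot(inherits(image, "mueller_image"))
  nx <- dim(image$sums)[1]
  half <- nx * image$pitch_um / 2
  centers <- (seq_len(nx) - 0.5) * image$pitch_um - half
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(nx))
  vals <- apply(image$sums, 3, function(sl) sl[cbind(grid$ix, grid$iy)])
  colnames(vals) <- paste0("m", as.vector(t(outer(1:4, 1:4, paste0))))
  df <- data.frame(
    x_um = centers[grid$ix], y_um = centers[grid$iy],
    vals / image$n_per_state,
    intensity = vals[, 1]
  )
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
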