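# Thickness/parameter sweeps, trend fits and the model-discrimination
# report.

#' Thickness sweep of a model preset
#'
#' Runs one transmission simulation per thickness and collects the rotation
#' invariants of the averaged Mueller matrix together with their batch
#' standard errors.
#'
#' @param preset A `"model_config"` (typically from [make_preset()]).
#' @param thicknesses_um Thicknesses to simulate, micrometers.
#' @param n_photons Photons per input polarization state and thickness
#'   (overrides the preset value when given).
#' @param seed Base seed; each thickness derives its own substream.
#' @param keep_results Keep the full `"mc_result"` objects as an attribute
#'   (`attr(x, "results")`); off by default to save memory.
#' @return A `"sweep_result"` tibble with one row per thickness: `model`,
#'   `d_um`, invariant columns `RT..aLA`, `se_*` columns, `m11_raw`,
#'   `imag_residual`, `n_photons`, `seed`.
#' @export
thickness_sweep <- function(preset, thicknesses_um, n_photons = NULL,
                            seed = NULL, keep_results = FALSE) {
  stopifnot(inherits(preset, "model_config"), length(thicknesses_um) >= 1)
  model <- attr(preset, "model") %||% "custom"
  results <- list()
  rows <- purrr::imap_dfr(as.numeric(thicknesses_um), function(d, k) {
    cfg <- preset
    cfg$thickness_um <- d
    if (!is.null(n_photons)) cfg$n_photons <- as.integer(n_photons)
    if (!is.null(seed)) cfg$seed <- as.integer(derive_seed(seed, 0L, 0L, k))
    if (d <= 0) {
      # degenerate zero-thickness sample: identity medium
      return(tibble::tibble(
        model = model, d_um = d,
        RT = 0, DT = 0, RC = 0, DC = 0, aL = 0, a44 = 0, aLA = 0,
        se_RT = 0, se_DT = 0, se_RC = 0, se_DC = 0, se_aL = 0,
        se_a44 = 0, se_aLA = 0,
        m11_raw = 1, imag_residual = 0,
        n_photons = cfg$n_photons, seed = cfg$seed
      ))
    }
    res <- run_simulation(cfg)
    if (keep_results) results[[length(results) + 1]] <<- res
    inv <- res$invariants
    se <- setNames(res$se$se, paste0("se_", res$se$invariant))
    tibble::tibble(
      model = model, d_um = d,
      RT = inv$RT, DT = inv$DT, RC = inv$RC, DC = inv$DC,
      aL = inv$aL, a44 = inv$a44, aLA = inv$aLA,
      !!!as.list(se),
      m11_raw = res$m11_raw, imag_residual = inv$imag_residual,
      n_photons = cfg$n_photons, seed = cfg$seed
    )
  })
  out <- structure(rows, class = c("sweep_result", class(rows)))
  if (keep_results) attr(out, "results") <- results
  out
}

#' Polynomial trend fit
#'
#' Least-squares polynomial fit of an invariant against thickness (or any
#' abscissa), with free intercept. Degree 1 tests the linear thickness laws
#' of the retardance/dichroism parameters, degree 2 the quadratic laws of
#' the depolarization parameters.
#'
#' @param x,y Numeric vectors (at least `degree + 2` points).
#' @param degree Polynomial degree, 1 or 2.
#' @return A `"trend_fit"` object wrapping the `lm` fit with `degree`,
#'   `coefficients`, `r_squared` and `residuals`; see [tidy.trend_fit()] and
#'   [glance.trend_fit()].
#' @examples
#' fit_trend(1:6, 2 * (1:6), degree = 1)$r_squared # exact line: 1
#' @export
fit_trend <- function(x, y, degree = 1) {
  stopifnot(degree %in% c(1, 2))
  if (length(x) < degree + 2) {
    stop("underdetermined fit: need at least degree + 2 points", call. = FALSE)
  }
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  sm <- suppressWarnings(summary(fit)) # exact fits: summary warns, harmlessly
  structure(
    list(
      degree = degree,
      coefficients = setNames(coef(fit), c("intercept", paste0("x^", seq_len(degree)))),
      r_squared = sm$r.squared,
      residuals = unname(fit$residuals),
      data = tibble::tibble(x = as.numeric(x), y = as.numeric(y)),
      fit = fit
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Polynomial trend fit (degree %d), R^2 = %.5f\n", x$degree, x$r_squared))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x A `"trend_fit"`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4])
  )
}

#' One-row trend-fit summary
#'
#' @param x A `"trend_fit"`.
#' @param ... Unused.
#' @return A one-row tibble with `degree`, `r.squared`, `sigma`, `df.residual`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    degree = x$degree, r.squared = sm$r.squared,
    sigma = sm$sigma, df.residual = x$fit$df.residual
  )
}

#' Model-discrimination report
#'
#' Evaluates each supplied sweep against the four qualitative criteria that
#' separate the dermal-layer optical models: (i) total linear retardance RT
#' grows linearly with thickness (R^2 >= 0.99 and slope above 3 standard
#' errors), (ii) the depolarization parameters aL and a44 follow a
#' quadratic thickness law (R^2 >= 0.98), (iii) total linear dichroism DT
#' is present (DT at the largest thickness above 3 Monte Carlo SE), and
#' (iv) anisotropic linear depolarization aLA is present (same test). A
#' model reproducing the dermal measurements must pass all four; the SB
#' model fails (iii) and (iv), the SC model lacks a retardance source at
#' low cylinder density.
#'
#' The report is a pure function of the sweep tables: re-running it on the
#' same rows reproduces it exactly.
#'
#' @param sweeps A named list of `"sweep_result"` tables (names are used as
#'   model labels when the tables carry none).
#' @param r2_linear,r2_quadratic Fit-quality thresholds.
#' @return A `"discrimination_report"`: list with `criteria` (tibble:
#'   `model`, `criterion`, `pass`, `statistic`) and `verdict` (tibble:
#'   `model`, `passes_all`).
#' @export
discrimination_report <- function(sweeps, r2_linear = 0.99, r2_quadratic = 0.98) {
  if (inherits(sweeps, "sweep_result")) sweeps <- list(sweeps)
  if (is.null(names(sweeps)) || any(!nzchar(names(sweeps)))) {
    names(sweeps) <- vapply(sweeps, function(s) s$model[1], character(1))
  }
  crit <- purrr::imap_dfr(sweeps, function(sw, label) {
    sw <- dplyr::filter(sw, .data$d_um > 0)
    if (nrow(sw) < 3) stop("sweep for ", label, " has too few rows", call. = FALSE)
    top <- sw[which.max(sw$d_um), ]
    f_rt <- fit_trend(sw$d_um, sw$RT, 1)
    slope_t <- tidy(f_rt)$estimate[2] / tidy(f_rt)$std.error[2]
    f_al <- fit_trend(sw$d_um, sw$aL, 2)
    f_a44 <- fit_trend(sw$d_um, sw$a44, 2)
    tibble::tibble(
      model = label,
      criterion = c("RT_linear_in_d", "depolarization_quadratic_in_d", "DT_positive", "aLA_positive"),
      pass = c(
        f_rt$r_squared >= r2_linear && is.finite(slope_t) && slope_t > 3 &&
          tidy(f_rt)$estimate[2] > 0,
        f_al$r_squared >= r2_quadratic && f_a44$r_squared >= r2_quadratic,
        top$DT > 3 * top$se_DT,
        top$aLA > 3 * top$se_aLA
      ),
      statistic = c(
        f_rt$r_squared,
        min(f_al$r_squared, f_a44$r_squared),
        ifelse(top$se_DT > 0, top$DT / top$se_DT, NA_real_),
        ifelse(top$se_aLA > 0, top$aLA / top$se_aLA, NA_real_)
      )
    )
  })
  verdict <- crit |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(passes_all = all(.data$pass), .groups = "drop")
  structure(list(criteria = crit, verdict = verdict),
    class = "discrimination_report"
  )
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Optical-model discrimination report\n")
  tab <- tidyr::pivot_wider(
    x$criteria[, c("model", "criterion", "pass")],
    names_from = "criterion", values_from = "pass"
  )
  print(as.data.frame(tab), row.names = FALSE)
  cat("\nverdict:\n")
  print(as.data.frame(x$verdict), row.names = FALSE)
  invisible(x)
}

#' Write a discrimination report as JSON
#'
#' @param report A `"discrimination_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "discrimination_report"))
  jsonlite::write_json(
    list(criteria = report$criteria, verdict = report$verdict),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write / read a sweep result as TSV
#'
#' @param sweep A `"sweep_result"` tibble.
#' @param path File path.
#' @return `path` (write) or the sweep tibble (read).
#' @export
write_sweep <- function(sweep, path) {
  write.table(sweep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  df <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t"))
  structure(df, class = c("sweep_result", class(df)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
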