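# ggplot2 visualization methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a thickness sweep
#'
#' One panel per rotation invariant against thickness, with 3-SE error bars
#' and (optionally) the linear/quadratic trend expected for each parameter
#' family: linear for RT and DT, quadratic for the depolarization
#' parameters.
#'
#' @param object A `"sweep_result"` tibble.
#' @param invariants Which invariant columns to show.
#' @param trends Overlay least-squares trend curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object,
                                  invariants = c("RT", "DT", "aL", "a44", "aLA"),
                                  trends = TRUE, ...) {
  long <- tidyr::pivot_longer(object,
    cols = dplyr::all_of(invariants),
    names_to = "invariant", values_to = "value"
  )
  se_long <- tidyr::pivot_longer(object,
    cols = dplyr::all_of(paste0("se_", invariants)),
    names_to = "invariant", values_to = "se"
  ) |>
    dplyr::mutate(invariant = sub("^se_", "", .data$invariant))
  long$se <- se_long$se
  long$invariant <- factor(long$invariant, levels = invariants)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$d_um, .data$value, colour = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$value - 3 * .data$se,
        ymax = .data$value + 3 * .data$se
      ),
      width = 0
    ) +
    ggplot2::facet_wrap(~invariant, scales = "free_y") +
    ggplot2::labs(
      x = "layer thickness (µm)", y = NULL,
      colour = "model"
    ) +
    ggplot2::theme_minimal()
  if (trends) {
    p <- p + ggplot2::geom_smooth(
      data = dplyr::filter(long, .data$invariant %in% c("RT", "DT")),
      method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4
    ) +
      ggplot2::geom_smooth(
        data = dplyr::filter(long, !.data$invariant %in% c("RT", "DT")),
        method = "lm", formula = y ~ poly(x, 2, raw = TRUE), se = FALSE,
        linewidth = 0.4
      )
  }
  p
}

#' Plot a trend fit
#'
#' @param object A `"trend_fit"`.
#' @param ... Unused.
#' @return A ggplot object showing the data and fitted polynomial.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  dat <- object$data
  xs <- seq(min(dat$x), max(dat$x), length.out = 200)
  co <- object$coefficients
  pred <- data.frame(
    x = xs,
    y = as.numeric(outer(xs, 0:object$degree, `^`) %*% co)
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::labs(
      title = sprintf("degree-%d fit, R² = %.4f", object$degree, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Mueller matrix image
#'
#' Heat-map facets of the 16 per-pixel Mueller elements (normalized to the
#' per-pixel m11 where it is positive).
#'
#' @param image A `"mueller_image"` from [run_simulation()].
#' @param normalize Divide each element image by the per-pixel m11.
#' @return A ggplot object.
#' @export
plot_mueller_image <- function(image, normalize = TRUE) {
  stopifnot(inherits(image, "mueller_image"))
  nx <- dim(image$sums)[1]
  half <- nx * image$pitch_um / 2
  centers <- (seq_len(nx) - 0.5) * image$pitch_um - half
  labs16 <- as.vector(t(outer(1:4, 1:4, function(i, j) paste0("m", i, j))))
  m11 <- image$sums[, , 1]
  df <- purrr::map_dfr(seq_len(16), function(k) {
    v <- image$sums[, , k]
    if (normalize && k > 1) v <- ifelse(m11 > 0, v / m11, NA_real_)
    if (!normalize || k == 1) v <- v / image$n_per_state
    data.frame(
      x_um = rep(centers, times = nx), y_um = rep(centers, each = nx),
      element = labs16[k], value = as.vector(v)
    )
  })
  df$element <- factor(df$element, levels = labs16)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~element, nrow = 4) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = NULL) +
    ggplot2::theme_minimal()
}
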