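#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MLAA fit
#'
#' When the fit carries a convergence trace, returns the final per-tissue
#' mean percentage differences; pass `truth` to recompute the full metrics
#' report instead.
#'
#' @param x An `mlaa_fit`.
#' @param truth Optional list with true `activity` and `tissue_masks`, as
#'   from [make_thorax_phantom()].
#' @param ... Unused.
#' @return A tibble, one row per tissue.
#' @method tidy mlaa_fit
#' @export
tidy.mlaa_fit <- function(x, truth = NULL, ...) {
  if (!is.null(truth)) {
    return(metrics_report(x$lambda, truth$activity, truth$tissue_masks))
  }
  if (is.null(x$trace)) {
    stop("fit has no trace; supply truth = to compute metrics")
  }
  dplyr::filter(x$trace, .data$iteration == max(.data$iteration))
}

#' One-row summary of an MLAA fit
#'
#' @param x An `mlaa_fit`.
#' @param ... Unused.
#' @return A tibble with the mode, iteration counts, the final
#'   bias-correction constant and the total reconstructed activity.
#' @method glance mlaa_fit
#' @export
glance.mlaa_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    n_mlem_iters = x$config$n_mlem_iters,
    n_mu_updates = max(length(x$K_history),
                       x$config$n_mlem_iters %/% x$config$mu_update_interval),
    final_K = if (length(x$K_history)) x$K_history[length(x$K_history)] else NA_real_,
    total_activity = sum(x$lambda$values),
    n_zero_den_skipped = x$diagnostics$n_zero_den_skipped
  )
}

#' Plot a PET image
#'
#' @param object A [pet_image()].
#' @param ... Unused.
#' @return A ggplot2 raster plot in mm coordinates.
#' @method autoplot pet_image
#' @export
autoplot.pet_image <- function(object, ...) {
  df <- as_tibble.pet_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(
      name = if (object$kind == "attenuation") "μ (1/mm)" else "activity (a.u.)") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Plot a sinogram
#'
#' TOF sinograms are summed over TOF bins before display.
#'
#' @param object A [tof_sinogram()] or [nontof_sinogram()].
#' @param ... Unused.
#' @return A ggplot2 raster plot (angle index vs radial offset).
#' @method autoplot nontof_sinogram
#' @export
autoplot.nontof_sinogram <- function(object, ...) {
  lc <- lor_coordinates(object$geometry)
  df <- tibble::tibble(
    angle = rep(lc$theta * 180 / pi, times = object$geometry$n_radial),
    radial = rep(lc$offset, each = object$geometry$n_angles),
    value = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radial, y = .data$angle,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "counts") +
    ggplot2::labs(x = "radial offset (mm)", y = "angle (deg)")
}

#' @rdname autoplot.nontof_sinogram
#' @method autoplot tof_sinogram
#' @export
autoplot.tof_sinogram <- function(object, ...) {
  autoplot.nontof_sinogram(sum_tof(object), ...)
}

#' Plot MLAA convergence curves
#'
#' @param object An `mlaa_fit` run with `truth` supplied.
#' @param ... Unused.
#' @return A ggplot2 line plot of per-tissue mean percentage difference vs
#'   iteration.
#' @method autoplot mlaa_fit
#' @export
autoplot.mlaa_fit <- function(object, ...) {
  tr <- convergence_curve(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$delta,
                                   colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "MLEM iteration",
                  y = "mean percentage difference (%)",
                  colour = "tissue")
}

#' Plot a percentage-difference map
#'
#' @param x Reconstructed [pet_image()].
#' @param x_true True [pet_image()].
#' @param limits Symmetric colour limits in percent (default 100).
#' @return A ggplot2 raster plot of [difference_map()].
#' @export
plot_difference_map <- function(x, x_true, limits = 100) {
  dm <- difference_map(x, x_true)
  cc <- grid_coords(x$grid)
  df <- tibble::tibble(
    x = rep(cc$x, times = x$grid$ny),
    y = rep(cc$y, each = x$grid$nx),
    value = pmin(pmax(as.vector(dm), -limits), limits)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradient2(name = "% diff", limits = c(-limits, limits)) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
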