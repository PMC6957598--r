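#' Segment tissues from a true attenuation map
#'
#' Partitions the body into lung, adipose, soft tissue and bone by
#' nearest-attenuation assignment: each body pixel is labelled with the
#' tissue whose reference attenuation coefficient is closest to the pixel's
#' value (i.e. thresholds sit midway between adjacent tissue values).  On
#' synthetic phantoms with exact tissue values this reproduces the
#' construction masks.  Tissues with no pixels are reported empty with a
#' warning.
#'
#' @param mu_true True attenuation [pet_image()].
#' @param body_mask Logical matrix, non-empty.
#' @param tissue_mu Named numeric vector of reference attenuation values
#'   (1/mm); defaults to the phantom materials.
#' @return Named list of logical masks partitioning `body_mask`.
#' @export
segment_tissues <- function(mu_true, body_mask,
                            tissue_mu = c(lung = 2.76e-3, adipose = 9.0e-3,
                                          soft = 9.6e-3, bone = 12.01e-3)) {
  if (!any(body_mask)) stop("body_mask is empty")
  vals <- mu_true$values[body_mask]
  nearest <- names(tissue_mu)[apply(abs(outer(vals, tissue_mu, `-`)), 1L,
                                    which.min)]
  masks <- lapply(names(tissue_mu), function(t) {
    m <- matrix(FALSE, nrow(body_mask), ncol(body_mask))
    m[body_mask][nearest == t] <- TRUE
    m
  })
  names(masks) <- names(tissue_mu)
  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty)) {
    warning("no pixels classified as: ", paste(empty, collapse = ", "))
  }
  masks
}

#' Mean percentage difference over a mask
#'
#' The per-tissue accuracy metric: `delta = mean(100 * (x - x_true) /
#' x_true)` over mask pixels with positive truth, together with the
#' standard deviation of the per-pixel percentages and the pixel count
#' used.  Pixels with `x_true == 0` are excluded (the ratio is undefined
#' there) and counted separately.
#'
#' @param x Reconstructed [pet_image()] (or matrix).
#' @param x_true True [pet_image()] (or matrix).
#' @param mask Logical matrix.
#' @return A list with `delta` (%), `sd` (%), `n` and `n_excluded`.
#' @export
#' @examples
#' g <- image_grid(4, 4, 5)
#' truth <- activity_image(matrix(1, 4, 4), g)
#' recon <- activity_image(matrix(1.1, 4, 4), g)
#' mean_percent_difference(recon, truth, matrix(TRUE, 4, 4))$delta  # 10
mean_percent_difference <- function(x, x_true, mask) {
  xv <- if (inherits(x, "pet_image")) x$values else x
  tv <- if (inherits(x_true, "pet_image")) x_true$values else x_true
  use <- mask & tv > 0
  n_excluded <- sum(mask) - sum(use)
  if (!any(use)) stop("no mask pixels with positive truth")
  pct <- 100 * (xv[use] - tv[use]) / tv[use]
  list(delta = mean(pct),
       sd = if (sum(use) > 1L) stats::sd(pct) else 0,
       n = sum(use), n_excluded = n_excluded)
}

#' Pixel-wise percentage difference map
#'
#' `100 * (x - x_true) / x_true` where the truth is positive; `NA`
#' elsewhere (flagged, not infinite).
#'
#' @param x,x_true Reconstructed and true [pet_image()]s (or matrices).
#' @return Numeric matrix of percentages with `NA` at undefined pixels.
#' @export
difference_map <- function(x, x_true) {
  xv <- if (inherits(x, "pet_image")) x$values else x
  tv <- if (inherits(x_true, "pet_image")) x_true$values else x_true
  out <- matrix(NA_real_, nrow(xv), ncol(xv))
  ok <- tv > 0
  out[ok] <- 100 * (xv[ok] - tv[ok]) / tv[ok]
  out
}

#' Per-tissue accuracy report
#'
#' Computes [mean_percent_difference()] for each tissue mask, mirroring the
#' per-configuration rows of a results table.
#'
#' @param x Reconstructed activity [pet_image()].
#' @param x_true True activity [pet_image()].
#' @param tissue_masks Named list of logical masks (e.g. from
#'   [make_thorax_phantom()] or [segment_tissues()]).
#' @return A tibble with columns `tissue`, `delta`, `sd`, `n`,
#'   `n_excluded`.
#' @export
metrics_report <- function(x, x_true, tissue_masks) {
  rows <- lapply(names(tissue_masks), function(t) {
    if (!any(tissue_masks[[t]] & x_true$values > 0)) {
      warning("tissue ", t, " has no pixels with positive truth; skipped")
      return(NULL)
    }
    m <- mean_percent_difference(x, x_true, tissue_masks[[t]])
    tibble::tibble(tissue = t, delta = m$delta, sd = m$sd, n = m$n,
                   n_excluded = m$n_excluded)
  })
  dplyr::bind_rows(rows)
}

#' Convergence curve of an MLAA fit
#'
#' The traced per-tissue mean percentage difference as a function of the
#' MLEM iteration, in tidy long format.
#'
#' @param fit An `mlaa_fit` run with `truth` supplied, or its `trace`
#'   tibble.
#' @return A tibble with columns `iteration`, `tissue`, `delta`.
#' @export
convergence_curve <- function(fit) {
  trace <- if (inherits(fit, "mlaa_fit")) fit$trace else fit
  if (is.null(trace)) stop("fit has no convergence trace (run with truth =)")
  dplyr::arrange(trace, .data$iteration, .data$tissue)
}
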