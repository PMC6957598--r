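#' Define a 2D reconstruction pixel lattice
#'
#' The grid is a square lattice of `nx` by `ny` pixels of side `pixel_size`
#' (mm), centred on the origin.  Pixel centres define the coordinate system:
#' pixel (1, 1) sits at the most negative x and y.  The default matches a
#' whole-body PET slice: 128 x 128 pixels of 5 mm, i.e. a 640 mm field of
#' view.
#'
#' @param nx,ny Pixel counts along x and y.
#' @param pixel_size Pixel side length in mm.
#' @return An object of class `image_grid`.
#' @export
#' @examples
#' g <- image_grid()
#' grid_fov(g)  # 640 mm
image_grid <- function(nx = 128L, ny = 128L, pixel_size = 5) {
  stopifnot(nx >= 1, ny >= 1, pixel_size > 0)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), pixel_size = pixel_size),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, %.3g mm/pixel (FOV %.4g x %.4g mm)\n",
              x$nx, x$ny, x$pixel_size, x$nx * x$pixel_size, x$ny * x$pixel_size))
  invisible(x)
}

#' Field of view of a grid
#'
#' @param grid An [image_grid()].
#' @return Extent of the grid along x, in mm.
#' @export
grid_fov <- function(grid) grid$nx * grid$pixel_size

#' Pixel-centre coordinates
#'
#' @param grid An [image_grid()].
#' @return A list with numeric vectors `x` and `y` of pixel-centre
#'   coordinates in mm (origin at the grid centre).
#' @export
grid_coords <- function(grid) {
  list(
    x = (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$pixel_size,
    y = (seq_len(grid$ny) - (grid$ny + 1) / 2) * grid$pixel_size
  )
}

same_grid <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny && isTRUE(all.equal(a$pixel_size, b$pixel_size))
}

#' Activity and attenuation images
#'
#' A `pet_image` wraps an `nx` x `ny` matrix of pixel values on an
#' [image_grid()].  `kind = "activity"` holds emission activity in arbitrary
#' units (non-negative); `kind = "attenuation"` holds linear attenuation
#' coefficients in 1/mm.  True attenuation maps are non-negative, but
#' intermediate reconstructed maps may dip below zero: the additive bias
#' correction relies on the map being free to shift, so no clamping is
#' applied here.
#'
#' @param values Numeric matrix of dimension `c(grid$nx, grid$ny)` (rows are
#'   x, columns are y), or a single number to fill the image.
#' @param grid An [image_grid()].
#' @param kind `"activity"` or `"attenuation"`.
#' @return An object of class `pet_image`.
#' @export
pet_image <- function(values, grid, kind = c("activity", "attenuation")) {
  kind <- match.arg(kind)
  if (length(values) == 1L) values <- matrix(values, grid$nx, grid$ny)
  stopifnot(is.matrix(values), nrow(values) == grid$nx, ncol(values) == grid$ny)
  if (!all(is.finite(values))) stop("image values must be finite")
  if (kind == "activity" && any(values < 0)) {
    stop("activity values must be non-negative")
  }
  structure(list(values = values, grid = grid, kind = kind),
            class = "pet_image")
}

#' @rdname pet_image
#' @export
activity_image <- function(values, grid) pet_image(values, grid, "activity")

#' @rdname pet_image
#' @export
attenuation_image <- function(values, grid) pet_image(values, grid, "attenuation")

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("<pet_image: %s> %d x %d px, range [%.4g, %.4g]%s\n",
              x$kind, x$grid$nx, x$grid$ny, min(x$values), max(x$values),
              if (x$kind == "attenuation") " 1/mm" else " a.u."))
  invisible(x)
}

#' @export
as.matrix.pet_image <- function(x, ...) x$values

#' Convert an image to a tidy tibble
#'
#' One row per pixel with centre coordinates in mm, ready for ggplot2.
#'
#' @param x A [pet_image()].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (mm), `value`.
#' @method as_tibble pet_image
#' @export
as_tibble.pet_image <- function(x, ...) {
  cc <- grid_coords(x$grid)
  tibble::tibble(
    x = rep(cc$x, times = x$grid$ny),
    y = rep(cc$y, each = x$grid$nx),
    value = as.vector(x$values)
  )
}
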