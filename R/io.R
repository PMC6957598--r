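# Plain-text array container: a TSV of values plus a JSON metadata sidecar
# (<path>.json).  Portable and diff-able; images store pixel size and kind,
# sinograms store the full geometry.

#' Read and write images and sinograms
#'
#' Images are written as a tab-separated matrix of pixel values (rows are
#' x) with a `<path>.json` sidecar holding the grid and units; TOF
#' sinograms as a long-format TSV (`angle`, `radial`, `tof`, `value`) with
#' the geometry in the sidecar.
#'
#' @param img A [pet_image()].
#' @param s A [tof_sinogram()].
#' @param path Output file path.
#' @return `read_image()` returns a [pet_image()]; `read_sinogram()` a
#'   [tof_sinogram()]; the writers return `path` invisibly.
#' @name array_io
NULL

#' @rdname array_io
#' @export
write_image <- function(img, path) {
  utils::write.table(img$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(container = "tofmlaa_image", kind = img$kind,
               nx = img$grid$nx, ny = img$grid$ny,
               pixel_size_mm = img$grid$pixel_size,
               units = if (img$kind == "attenuation") "1/mm" else "a.u.")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname array_io
#' @export
read_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  pet_image(vals, image_grid(meta$nx, meta$ny, meta$pixel_size_mm),
            kind = meta$kind)
}

#' @rdname array_io
#' @export
write_sinogram <- function(s, path) {
  g <- s$geometry
  dims <- dim(s$values)
  df <- data.frame(
    angle = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
    radial = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    tof = rep(seq_len(dims[3]), each = dims[1] * dims[2]),
    value = as.vector(s$values)
  )
  df <- df[df$value != 0, , drop = FALSE]  # sparse rows only
  utils::write.table(df, path, sep = "\t", row.names = FALSE)
  meta <- list(container = "tofmlaa_tof_sinogram",
               n_angles = g$n_angles, n_radial = g$n_radial,
               radial_bin_mm = g$radial_bin, n_tof = g$n_tof,
               crt_ps = g$crt_ps, scanner_diameter_mm = g$scanner_diameter)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname array_io
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- sinogram_geometry(meta$n_angles, meta$n_radial,
                         as.numeric(meta$radial_bin_mm),
                         crt_ps = as.numeric(meta$crt_ps),
                         n_tof = meta$n_tof,
                         scanner_diameter = as.numeric(meta$scanner_diameter_mm))
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  vals <- array(0, dim = c(g$n_angles, g$n_radial, g$n_tof))
  vals[cbind(df$angle, df$radial, df$tof)] <- df$value
  tof_sinogram(vals, g)
}
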