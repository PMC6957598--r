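#' Sinogram geometry
#'
#' Describes the 2D TOF sinogram sampling: parallel-beam LORs indexed by
#' (angle, radial offset) with an odd number of TOF bins, on a scanner ring
#' of diameter `scanner_diameter`.  Angles are `theta_m = m * 180 / n_angles`
#' degrees for `m = 0 .. n_angles - 1`; radial offsets are centred on zero
#' with spacing `radial_bin`.  The TOF bin count pairs with the coincidence
#' resolving time (CRT): 540 ps -> 13 bins, 300 ps -> 27, 100 ps -> 81;
#' other combinations may be set explicitly.
#'
#' @param n_angles Angular samples over 180 degrees (default 90).
#' @param n_radial Radial samples (default 256).
#' @param radial_bin Radial bin size in mm (default 2.5).
#' @param crt_ps Coincidence resolving time FWHM in ps (default 300).
#' @param n_tof Odd TOF bin count; defaults from `crt_ps` when it is one of
#'   540/300/100.
#' @param scanner_diameter PET ring diameter D in mm (default 903).
#' @return An object of class `sinogram_geometry`.
#' @export
#' @examples
#' sinogram_geometry()          # 90 x 256 x 27 at 300 ps
#' sinogram_geometry(crt_ps = 540)$n_tof  # 13
sinogram_geometry <- function(n_angles = 90L, n_radial = 256L, radial_bin = 2.5,
                              crt_ps = 300, n_tof = NULL,
                              scanner_diameter = 903) {
  if (is.null(n_tof)) {
    n_tof <- switch(as.character(crt_ps), "540" = 13L, "300" = 27L, "100" = 81L,
                    stop("no default TOF bin count for CRT = ", crt_ps,
                         " ps; supply n_tof"))
  }
  n_tof <- as.integer(n_tof)
  if (n_tof %% 2L == 0L) stop("n_tof must be odd")
  if (crt_ps <= 0) stop("crt_ps must be positive")
  stopifnot(n_angles >= 1, n_radial >= 1, radial_bin > 0, scanner_diameter > 0)
  structure(
    list(n_angles = as.integer(n_angles), n_radial = as.integer(n_radial),
         radial_bin = radial_bin, crt_ps = crt_ps, n_tof = n_tof,
         scanner_diameter = scanner_diameter),
    class = "sinogram_geometry"
  )
}

#' @export
print.sinogram_geometry <- function(x, ...) {
  cat(sprintf(
    "<sinogram_geometry> %d angles x %d radial (%.3g mm) x %d TOF bins, CRT %g ps, D = %g mm\n",
    x$n_angles, x$n_radial, x$radial_bin, x$n_tof, x$crt_ps, x$scanner_diameter))
  invisible(x)
}

n_lors <- function(geometry) geometry$n_angles * geometry$n_radial

#' LOR angles and radial offsets
#'
#' @param geometry A [sinogram_geometry()].
#' @return List with `theta` (radians, length `n_angles`) and `offset`
#'   (mm, length `n_radial`, centred on zero).
#' @export
lor_coordinates <- function(geometry) {
  list(
    theta = (seq_len(geometry$n_angles) - 1) * pi / geometry$n_angles,
    offset = (seq_len(geometry$n_radial) - (geometry$n_radial + 1) / 2) *
      geometry$radial_bin
  )
}

# Speed of light in mm/ps.
C_MM_PER_PS <- 0.2998

#' Spatial TOF resolution
#'
#' A coincidence timing spread of CRT (FWHM, ps) localises the annihilation
#' point along the LOR with FWHM `c * CRT / 2` mm; this returns the Gaussian
#' sigma of that kernel (e.g. 19.1 mm at 300 ps).
#'
#' @param crt_ps Coincidence resolving time FWHM in ps.
#' @return Gaussian sigma in mm.
#' @export
tof_sigma_mm <- function(crt_ps) {
  if (crt_ps <= 0) stop("crt_ps must be positive")
  C_MM_PER_PS * crt_ps / 2 / (2 * sqrt(2 * log(2)))
}

#' TOF bin edges along a LOR
#'
#' Bins tile the field of view `[-FOV/2, +FOV/2]` along each LOR, measured
#' from the chord midpoint (the point of closest approach to the scanner
#' axis), with uniform width `FOV / n_tof`.
#'
#' @param geometry A [sinogram_geometry()].
#' @param grid An [image_grid()].
#' @return Numeric vector of `n_tof + 1` edges in mm.
#' @export
tof_bin_edges <- function(geometry, grid) {
  half <- grid_fov(grid) / 2
  seq(-half, half, length.out = geometry$n_tof + 1L)
}

#' Gaussian TOF bin weights for a position along a LOR
#'
#' The probability that an event at signed position `s` (mm from the chord
#' midpoint) is recorded in each TOF bin: the Gaussian of sigma
#' [tof_sigma_mm()] centred at `s`, integrated over the bin.  Bins that do
#' not overlap `s +/- trunc * sigma` are truncated to zero, so the weights
#' sum to at most 1 (equal to 1 up to edge and tail truncation).
#'
#' @param s Numeric vector of positions along the LOR (mm).
#' @param sigma Gaussian sigma (mm).
#' @param edges Bin edges from [tof_bin_edges()].
#' @param trunc Truncation half-width in sigmas (default 4).
#' @return Matrix `length(s)` x `n_tof` of weights.
#' @export
tof_bin_weights <- function(s, sigma, edges, trunc = 4) {
  n_tof <- length(edges) - 1L
  w <- matrix(0, length(s), n_tof)
  for (t in seq_len(n_tof)) {
    lo <- edges[t]; hi <- edges[t + 1L]
    sel <- s > lo - trunc * sigma & s < hi + trunc * sigma
    if (any(sel)) {
      w[sel, t] <- stats::pnorm((hi - s[sel]) / sigma) -
        stats::pnorm((lo - s[sel]) / sigma)
    }
  }
  w
}

# ---- Siddon ray tracing -----------------------------------------------------

#' Trace one LOR through the pixel grid
#'
#' Siddon-style exact ray tracing: the LOR is the chord of the scanner ring
#' at angle `theta` and signed radial offset `r`, clipped to the square
#' image support.  Returns the traversed pixels in order with exact
#' intersection lengths, and the signed position of each intersection
#' midpoint along the LOR (zero at the chord midpoint), which drives the
#' TOF weighting.
#'
#' @param theta LOR angle in radians (normal direction).
#' @param r Signed radial offset in mm.
#' @param grid An [image_grid()].
#' @param scanner_diameter Ring diameter in mm.
#' @return A list with integer vector `j` (1-based pixel index, x fastest),
#'   `length` (mm) and `s` (mm), or `NULL` if the LOR misses the image.
#' @export
siddon_trace <- function(theta, r, grid, scanner_diameter) {
  R <- scanner_diameter / 2
  if (abs(r) >= R) return(NULL)
  half_chord <- sqrt(R^2 - r^2)
  nx <- grid$nx; ny <- grid$ny; px <- grid$pixel_size
  X <- nx * px / 2; Y <- ny * px / 2
  ux <- -sin(theta); uy <- cos(theta)
  p0x <- r * cos(theta); p0y <- r * sin(theta)

  tmin <- -half_chord; tmax <- half_chord
  eps <- 1e-12
  if (abs(ux) > eps) {
    tx <- c((-X - p0x) / ux, (X - p0x) / ux)
    tmin <- max(tmin, min(tx)); tmax <- min(tmax, max(tx))
  } else if (abs(p0x) >= X) return(NULL)
  if (abs(uy) > eps) {
    ty <- c((-Y - p0y) / uy, (Y - p0y) / uy)
    tmin <- max(tmin, min(ty)); tmax <- min(tmax, max(ty))
  } else if (abs(p0y) >= Y) return(NULL)
  if (tmax - tmin <= 1e-9) return(NULL)

  ts <- c(tmin, tmax)
  if (abs(ux) > eps) {
    tx <- (seq(-X, X, by = px) - p0x) / ux
    ts <- c(ts, tx[tx > tmin & tx < tmax])
  }
  if (abs(uy) > eps) {
    ty <- (seq(-Y, Y, by = px) - p0y) / uy
    ts <- c(ts, ty[ty > tmin & ty < tmax])
  }
  ts <- sort(ts)
  len <- diff(ts)
  keep <- len > 1e-9
  if (!any(keep)) return(NULL)
  mid <- (ts[-length(ts)] + ts[-1])[keep] / 2
  len <- len[keep]
  ix <- floor((p0x + mid * ux + X) / px) + 1
  iy <- floor((p0y + mid * uy + Y) / px) + 1
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  if (!all(ok)) { ix <- ix[ok]; iy <- iy[ok]; len <- len[ok]; mid <- mid[ok] }
  if (length(len) == 0L) return(NULL)
  list(j = as.integer(ix + (iy - 1) * nx), length = len, s = mid)
}

# ---- system matrix ----------------------------------------------------------

# In-session cache for built system matrices, keyed by the configuration
# string; a disk cache is optional and opt-in.
.matrix_cache <- new.env(parent = emptyenv())

.config_key <- function(geometry, grid, trunc) {
  paste(geometry$n_angles, geometry$n_radial, geometry$radial_bin,
        geometry$crt_ps, geometry$n_tof, geometry$scanner_diameter,
        grid$nx, grid$ny, grid$pixel_size, trunc, sep = "_")
}

#' Build the sparse TOF system matrix
#'
#' Traces every LOR with [siddon_trace()] and assembles two sparse
#' operators: `L`, the `n_lor x n_pix` matrix of intersection lengths
#' `l_ij` (mm), and `Mtof`, the `(n_lor * n_tof) x n_pix` matrix of
#' TOF-weighted coefficients `c_ij^TOF = l_ij * w_TOF(j | i)` with the
#' Gaussian timing kernel of [tof_sigma_mm()] truncated at `trunc` sigmas.
#' Row `(i - 1) * n_tof + t` of `Mtof` is LOR `i`
#' (`i = (angle - 1) * n_radial + radial`), TOF bin `t`.  Transposes are
#' stored for fast back projection.  The build is deterministic; results
#' are cached in-session (and on disk under `cache_dir` if given) keyed by
#' the full configuration, and a corrupt disk cache entry triggers a
#' rebuild.
#'
#' @param geometry A [sinogram_geometry()].
#' @param grid An [image_grid()].
#' @param trunc TOF Gaussian truncation in sigmas (default 4).
#' @param cache_dir Optional directory for an on-disk cache.
#' @param verbose Print progress.
#' @return An object of class `pet_system_matrix` with elements `L`, `Lt`,
#'   `Mtof`, `Mt`, `geometry`, `grid`.
#' @export
build_system_matrix <- function(geometry, grid, trunc = 4, cache_dir = NULL,
                                verbose = FALSE) {
  key <- .config_key(geometry, grid, trunc)
  if (!is.null(.matrix_cache[[key]])) return(.matrix_cache[[key]])
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0("sysmat_", key, ".rds"))
    if (file.exists(f)) {
      M <- tryCatch(readRDS(f), error = function(e) NULL)
      if (inherits(M, "pet_system_matrix")) {
        .matrix_cache[[key]] <- M
        return(M)
      }
      # corrupt cache entry: fall through and rebuild
    }
  }

  lc <- lor_coordinates(geometry)
  n_ang <- geometry$n_angles; n_rad <- geometry$n_radial
  nlor <- n_ang * n_rad
  npix <- grid$nx * grid$ny
  if (verbose) message("tracing ", nlor, " LORs ...")

  traces <- vector("list", nlor)
  for (ia in seq_len(n_ang)) {
    th <- lc$theta[ia]
    base <- (ia - 1L) * n_rad
    for (ir in seq_len(n_rad)) {
      tr <- siddon_trace(th, lc$offset[ir], grid, geometry$scanner_diameter)
      if (!is.null(tr)) traces[[base + ir]] <- tr
    }
  }
  nz <- !vapply(traces, is.null, logical(1))
  counts <- integer(nlor)
  counts[nz] <- vapply(traces[nz], function(t) length(t$j), integer(1))
  lor <- rep.int(seq_len(nlor), counts)
  jj <- unlist(lapply(traces[nz], `[[`, "j"), use.names = FALSE)
  ll <- unlist(lapply(traces[nz], `[[`, "length"), use.names = FALSE)
  ss <- unlist(lapply(traces[nz], `[[`, "s"), use.names = FALSE)
  traces <- NULL

  L <- Matrix::sparseMatrix(i = lor, j = jj, x = ll, dims = c(nlor, npix))

  if (verbose) message("TOF-weighting ", length(ll), " intersections ...")
  sigma <- tof_sigma_mm(geometry$crt_ps)
  edges <- tof_bin_edges(geometry, grid)
  n_tof <- geometry$n_tof
  ti <- vector("list", n_tof); tj <- vector("list", n_tof); tx <- vector("list", n_tof)
  for (t in seq_len(n_tof)) {
    lo <- edges[t]; hi <- edges[t + 1L]
    sel <- which(ss > lo - trunc * sigma & ss < hi + trunc * sigma)
    if (length(sel)) {
      w <- stats::pnorm((hi - ss[sel]) / sigma) - stats::pnorm((lo - ss[sel]) / sigma)
      keep <- w > 1e-14
      sel <- sel[keep]
      ti[[t]] <- (lor[sel] - 1) * n_tof + t
      tj[[t]] <- jj[sel]
      tx[[t]] <- ll[sel] * w[keep]
    }
  }
  Mtof <- Matrix::sparseMatrix(
    i = unlist(ti, use.names = FALSE),
    j = unlist(tj, use.names = FALSE),
    x = unlist(tx, use.names = FALSE),
    dims = c(nlor * n_tof, npix)
  )
  ti <- tj <- tx <- NULL

  M <- structure(
    list(L = L, Lt = Matrix::t(L), Mtof = Mtof, Mt = Matrix::t(Mtof),
         geometry = geometry, grid = grid, trunc = trunc, key = key),
    class = "pet_system_matrix"
  )
  .matrix_cache[[key]] <- M
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(M, file.path(cache_dir, paste0("sysmat_", key, ".rds")))
  }
  M
}

#' @export
print.pet_system_matrix <- function(x, ...) {
  cat(sprintf(
    "<pet_system_matrix> %d LORs x %d pixels; nnz(L) = %d, nnz(Mtof) = %d\n",
    nrow(x$L), ncol(x$L), Matrix::nnzero(x$L), Matrix::nnzero(x$Mtof)))
  invisible(x)
}

# ---- sinogram containers ----------------------------------------------------

#' TOF and non-TOF sinograms
#'
#' `tof_sinogram` wraps a 3D array indexed `(angle, radial, tof)`;
#' `nontof_sinogram` wraps a matrix `(angle, radial)`.  Internally the
#' projectors use a flat vector with TOF fastest, then radial, then angle,
#' matching the system-matrix row ordering.
#'
#' @param values Array `c(n_angles, n_radial, n_tof)` (or matrix
#'   `c(n_angles, n_radial)` for non-TOF).
#' @param geometry A [sinogram_geometry()].
#' @return An object of class `tof_sinogram` or `nontof_sinogram`.
#' @export
tof_sinogram <- function(values, geometry) {
  stopifnot(length(dim(values)) == 3,
            all(dim(values) == c(geometry$n_angles, geometry$n_radial,
                                 geometry$n_tof)))
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("TOF sinogram values must be finite and non-negative")
  }
  structure(list(values = values, geometry = geometry), class = "tof_sinogram")
}

#' @rdname tof_sinogram
#' @export
nontof_sinogram <- function(values, geometry) {
  stopifnot(is.matrix(values),
            all(dim(values) == c(geometry$n_angles, geometry$n_radial)))
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  structure(list(values = values, geometry = geometry), class = "nontof_sinogram")
}

#' @export
print.tof_sinogram <- function(x, ...) {
  cat(sprintf("<tof_sinogram> %d x %d x %d, total %.6g\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values)))
  invisible(x)
}

#' @export
print.nontof_sinogram <- function(x, ...) {
  cat(sprintf("<nontof_sinogram> %d x %d, range [%.4g, %.4g]\n",
              dim(x$values)[1], dim(x$values)[2], min(x$values), max(x$values)))
  invisible(x)
}

# flat vector in system-matrix ordering: tof fastest, then radial, then angle
sino_vec <- function(s) {
  if (inherits(s, "tof_sinogram")) as.vector(aperm(s$values, c(3, 2, 1)))
  else as.vector(t(s$values))
}

vec_to_tof_sino <- function(v, geometry) {
  a <- aperm(array(v, dim = c(geometry$n_tof, geometry$n_radial,
                              geometry$n_angles)), c(3, 2, 1))
  tof_sinogram(a, geometry)
}

vec_to_nontof_sino <- function(v, geometry) {
  nontof_sinogram(t(matrix(v, geometry$n_radial, geometry$n_angles)), geometry)
}

# ---- forward / backward operators ------------------------------------------

.check_img <- function(img, M) {
  if (!same_grid(img$grid, M$grid)) stop("image grid does not match system matrix")
}

#' TOF forward projection
#'
#' Computes the expected TOF emission sinogram `b_{i,TOF} = sum_j c_ij^TOF
#' lambda_j` for an activity image.
#'
#' @param act An activity [pet_image()].
#' @param M A [build_system_matrix()] result.
#' @return A [tof_sinogram()].
#' @export
forward_project_tof <- function(act, M) {
  .check_img(act, M)
  v <- as.numeric(M$Mtof %*% as.vector(act$values))
  vec_to_tof_sino(v, M$geometry)
}

#' Attenuation sinogram
#'
#' Per-LOR survival probability `a_i = exp(-sum_j l_ij mu_j)` from an
#' attenuation image; values lie in (0, 1] when `mu >= 0`.
#'
#' @param att An attenuation [pet_image()].
#' @param M A [build_system_matrix()] result.
#' @return A [nontof_sinogram()].
#' @export
attenuation_sinogram <- function(att, M) {
  .check_img(att, M)
  v <- exp(-as.numeric(M$L %*% as.vector(att$values)))
  vec_to_nontof_sino(v, M$geometry)
}

#' Apply attenuation to a TOF sinogram
#'
#' Elementwise product `y_{i,TOF} = b_{i,TOF} * a_i`, the attenuation factor
#' broadcast over TOF bins.
#'
#' @param b A [tof_sinogram()] of unattenuated emission data.
#' @param a A [nontof_sinogram()] of attenuation factors.
#' @return A [tof_sinogram()].
#' @export
attenuate <- function(b, a) {
  stopifnot(identical(dim(b$values)[1:2], dim(a$values)))
  vals <- b$values * as.vector(a$values)  # (angle, radial) recycles over tof
  tof_sinogram(vals, b$geometry)
}

#' Non-TOF forward projection (line integrals)
#'
#' @param img A [pet_image()].
#' @param M A [build_system_matrix()] result.
#' @return A [nontof_sinogram()] of line integrals `sum_j l_ij x_j`.
#' @export
forward_project <- function(img, M) {
  .check_img(img, M)
  vec_to_nontof_sino(as.numeric(M$L %*% as.vector(img$values)), M$geometry)
}

#' Back projection (adjoint operators)
#'
#' Applies the exact transpose of the corresponding forward operator:
#' `sum_i l_ij s_i` for a non-TOF sinogram, `sum_{i,TOF} c_ij^TOF s_{i,TOF}`
#' for a TOF sinogram.
#'
#' @param s A [tof_sinogram()] or [nontof_sinogram()].
#' @param M A [build_system_matrix()] result.
#' @return A matrix `nx` x `ny` of back-projected values.
#' @export
back_project <- function(s, M) {
  v <- sino_vec(s)
  op <- if (inherits(s, "tof_sinogram")) M$Mt else M$Lt
  matrix(as.numeric(op %*% v), M$grid$nx, M$grid$ny)
}

#' Sum a TOF sinogram over TOF bins
#'
#' @param s A [tof_sinogram()].
#' @return A [nontof_sinogram()] with `y_i = sum_TOF y_{i,TOF}`.
#' @export
sum_tof <- function(s) {
  nontof_sinogram(rowSums(s$values, dims = 2), s$geometry)
}
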