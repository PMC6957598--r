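#' Reconstruction configuration
#'
#' Controls the interleaved MLAA loop: `n_mlem_iters` TOF-MLEM activity
#' updates with one attenuation gradient-ascent update every
#' `mu_update_interval` MLEM iterations (default 1000 and 3, i.e. about 333
#' attenuation updates), relaxation `alpha_p / D` with `alpha_p = 2` and
#' ring diameter `D = 903` mm.  Modes:
#'
#' * `"standard"` — plain MLAA, no bias correction (subject to the
#'   additive-constant degeneracy of the attenuation sinogram);
#' * `"ref_corrected"` — after every attenuation update, the whole map is
#'   shifted by `K = mu_ref - mean(mu[roi_mask])` so the reference-object
#'   ROI attains its known attenuation;
#' * `"ref_corrected_fixed_air"` — additionally pins air pixels (outside
#'   body, table and reference) to zero throughout.
#'
#' Pixels in `fixed_mask` (the patient table template, plus air in
#' fixed-air mode) are never updated and never shifted.
#'
#' @param n_mlem_iters Total MLEM iterations.
#' @param mu_update_interval MLEM iterations per attenuation update (>= 1).
#' @param alpha_p Relaxation coefficient (> 0).
#' @param D Scanner ring diameter in mm (> 0).
#' @param mode Reconstruction mode, see above.
#' @param mu_ref Known mean attenuation of the reference object (1/mm);
#'   required in the reference-corrected modes.
#' @param roi_mask Logical matrix: the ROI inside the reference object used
#'   for the bias correction (typically the reference mask eroded by one
#'   pixel, see [erode_mask()]).
#' @param fixed_mask Logical matrix of never-updated pixels; must not
#'   intersect `roi_mask`.
#' @param air_mask Logical matrix of air pixels (outside body, table and
#'   reference object); required in fixed-air mode, where these pixels are
#'   set to zero attenuation and never updated.
#' @param eps Positive floor used to guard zero denominators.
#' @param trace_every Record the convergence trace every this many MLEM
#'   iterations (0 to disable).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_mlem_iters = 1000L, mu_update_interval = 3L,
                         alpha_p = 2, D = 903,
                         mode = c("standard", "ref_corrected",
                                  "ref_corrected_fixed_air"),
                         mu_ref = NULL, roi_mask = NULL, fixed_mask = NULL,
                         air_mask = NULL, eps = 1e-12, trace_every = 10L) {
  mode <- match.arg(mode)
  stopifnot(alpha_p > 0, D > 0, mu_update_interval >= 1, n_mlem_iters >= 1,
            eps > 0)
  if (mode == "ref_corrected_fixed_air" && is.null(air_mask)) {
    stop("fixed-air mode requires air_mask")
  }
  if (mode != "standard") {
    if (is.null(mu_ref) || is.null(roi_mask)) {
      stop("reference-corrected modes require mu_ref and roi_mask")
    }
    if (!any(roi_mask)) stop("roi_mask is empty")
    if (!is.null(fixed_mask) && any(roi_mask & fixed_mask)) {
      stop("roi_mask and fixed_mask must be disjoint")
    }
  }
  structure(
    list(n_mlem_iters = as.integer(n_mlem_iters),
         mu_update_interval = as.integer(mu_update_interval),
         alpha_p = alpha_p, D = D, mode = mode, mu_ref = mu_ref,
         roi_mask = roi_mask, fixed_mask = fixed_mask, air_mask = air_mask,
         eps = eps, trace_every = as.integer(trace_every)),
    class = "recon_config"
  )
}

# ---- elementary updates -----------------------------------------------------

# guarded ratio y/b: 0/0 -> 0, y>0 & b==0 -> y/eps
.safe_ratio <- function(y, b, eps) {
  r <- numeric(length(y))
  pos <- b > 0
  r[pos] <- y[pos] / b[pos]
  bad <- !pos & y > 0
  if (any(bad)) r[bad] <- y[bad] / eps
  r
}

#' One TOF-MLEM activity update
#'
#' Multiplicative update
#' `lambda_j <- lambda_j * [sum_{i,TOF} c_ij^TOF y_{i,TOF} / b_{i,TOF}] /
#' [sum_{i,TOF} c_ij^TOF a_i]` with `b = forward(lambda)`.  Non-negativity
#' is preserved; pixels with zero sensitivity (zero denominator) are left
#' unchanged.  Empty model bins with observed counts are guarded by `eps`.
#'
#' @param lambda Numeric vector of current activity (pixel-major).
#' @param yv Measured TOF sinogram as a flat vector (system-matrix order).
#' @param den Sensitivity denominator `sum_{i,TOF} c_ij^TOF a_i` per pixel
#'   (see [mlem_denominator()]).
#' @param M A [build_system_matrix()] result.
#' @param eps Ratio guard.
#' @return Updated activity vector.
#' @export
mlem_update <- function(lambda, yv, den, M, eps = 1e-12) {
  b <- as.numeric(M$Mtof %*% lambda)
  num <- as.numeric(M$Mt %*% .safe_ratio(yv, b, eps))
  ok <- den > 0
  lambda[ok] <- lambda[ok] * num[ok] / den[ok]
  lambda
}

#' MLEM sensitivity denominator
#'
#' `sum_{i,TOF} c_ij^TOF a_i` per pixel, for attenuation factors `a_i`
#' (vector in LOR order, or 1 for non-attenuation-corrected MLEM).
#'
#' @param a_vec Attenuation factors per LOR (flat vector) or a scalar.
#' @param M A [build_system_matrix()] result.
#' @return Numeric vector, one entry per pixel.
#' @export
mlem_denominator <- function(a_vec, M) {
  n_tof <- M$geometry$n_tof
  if (length(a_vec) == 1L) a_vec <- rep(a_vec, n_lors(M$geometry))
  as.numeric(M$Mt %*% rep(a_vec, each = n_tof))
}

#' One attenuation gradient-ascent update
#'
#' `mu_j <- mu_j + (alpha_p / D) * (1 - [sum_i l_ij y_i] /
#' [sum_i l_ij a_i b_i])`, where `y_i` and `b_i` are the TOF-summed
#' measured and estimated emission sinograms and `a_i` the current
#' attenuation sinogram: no TOF information enters this step, and the
#' per-pixel step size is bounded by `alpha_p / D` in absolute value.
#' Pixels with a zero denominator are left unchanged (their count is
#' returned), as are pixels in `fixed_mask`.
#'
#' @param mu Numeric vector of current attenuation (pixel-major).
#' @param y_i Measured counts summed over TOF, per LOR (flat vector).
#' @param ab_i Current model `a_i * b_i` summed over TOF, per LOR.
#' @param M A [build_system_matrix()] result.
#' @param alpha_p,D Relaxation coefficient and ring diameter (mm).
#' @param fixed Logical vector of pixels to leave untouched (or `NULL`).
#' @return List with updated `mu` and `n_zero_den`, the number of live
#'   pixels skipped for a zero denominator.
#' @export
attenuation_update <- function(mu, y_i, ab_i, M, alpha_p = 2, D = 903,
                               fixed = NULL) {
  num <- as.numeric(M$Lt %*% y_i)
  den <- as.numeric(M$Lt %*% ab_i)
  upd <- den > 0
  if (!is.null(fixed)) upd <- upd & !fixed
  mu[upd] <- mu[upd] + (alpha_p / D) * (1 - num[upd] / den[upd])
  list(mu = mu, n_zero_den = sum(den <= 0 & if (is.null(fixed)) TRUE else !fixed))
}

#' Reference-object bias correction
#'
#' Shifts the whole attenuation map by the additive constant
#' `K = mu_ref - mean(mu[roi_mask])`, so that the mean attenuation inside
#' the reference-object ROI equals its known value.  Pixels in `fixed`
#' are not shifted.
#'
#' @param mu Numeric vector or matrix of attenuation values.
#' @param roi_mask Logical mask of the ROI inside the reference object
#'   (non-empty).
#' @param mu_ref Known reference attenuation (1/mm).
#' @param fixed Optional logical mask of pixels to leave untouched.
#' @return List with corrected `mu` and the applied constant `K`.
#' @export
bias_correction <- function(mu, roi_mask, mu_ref, fixed = NULL) {
  if (!any(roi_mask)) stop("roi_mask is empty")
  K <- mu_ref - mean(mu[roi_mask])
  if (is.null(fixed)) mu <- mu + K else mu[!fixed] <- mu[!fixed] + K
  list(mu = mu, K = K)
}

#' Erode a logical mask by one pixel (4-neighbourhood)
#'
#' @param mask Logical matrix.
#' @return Logical matrix: pixels whose 4-neighbours are all in the mask.
#' @export
erode_mask <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  out[c(1, n), ] <- FALSE; out[, c(1, m)] <- FALSE
  inner <- out
  inner[2:(n - 1), ] <- inner[2:(n - 1), ] & mask[1:(n - 2), ] & mask[3:n, ]
  inner[, 2:(m - 1)] <- inner[, 2:(m - 1)] & mask[, 1:(m - 2)] & mask[, 3:m]
  inner
}

# ---- standard MLEM ----------------------------------------------------------

#' Standard TOF-MLEM with known attenuation
#'
#' Plain MLEM reconstruction of the activity image given the measured TOF
#' sinogram and a fixed attenuation sinogram (`a = NULL` runs the
#' non-attenuation-corrected variant with `a = 1`).  The activity starts
#' uniform and positive.
#'
#' @param y Measured [tof_sinogram()].
#' @param M A [build_system_matrix()] result.
#' @param a Known attenuation [nontof_sinogram()], or `NULL`.
#' @param n_iters Number of MLEM iterations.
#' @param lambda0 Optional starting activity [pet_image()].
#' @param eps Ratio guard.
#' @return List with `lambda` (activity [pet_image()]) and `n_iters`.
#' @export
run_mlem <- function(y, M, a = NULL, n_iters = 100L, lambda0 = NULL,
                     eps = 1e-12) {
  yv <- sino_vec(y)
  a_vec <- if (is.null(a)) 1 else sino_vec(a)
  den <- mlem_denominator(a_vec, M)
  lambda <- if (is.null(lambda0)) rep(1, M$grid$nx * M$grid$ny)
            else as.vector(lambda0$values)
  for (n in seq_len(n_iters)) lambda <- mlem_update(lambda, yv, den, M, eps)
  list(lambda = activity_image(matrix(lambda, M$grid$nx, M$grid$ny), M$grid),
       n_iters = n_iters)
}

# ---- initialization ---------------------------------------------------------

#' Gaussian smoothing of an image matrix
#'
#' Separable convolution with a truncated Gaussian kernel, edge-renormalised
#' so flat regions stay flat at the borders.
#'
#' @param mat Numeric matrix.
#' @param sigma Kernel sigma in pixels.
#' @return Smoothed matrix of the same dimension.
#' @export
gaussian_smooth <- function(mat, sigma = 2) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (d in seq(-r, r)) {
      w <- k[d + r + 1]
      src <- pmin(pmax(seq_len(n) + d, 1L), n)  # replicate edges
      out <- out + w * m[src, , drop = FALSE]
      wsum <- wsum + w
    }
    out / wsum
  }
  t(smooth1(t(smooth1(mat))))
}

# connected components of a logical mask by label propagation (4-neighbour)
.label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lab
    nb[-1, ] <- pmax(nb[-1, ], lab[-nrow(lab), ])
    nb[-nrow(lab), ] <- pmax(nb[-nrow(lab), ], lab[-1, ])
    nb[, -1] <- pmax(nb[, -1], lab[, -ncol(lab)])
    nb[, -ncol(lab)] <- pmax(nb[, -ncol(lab)], lab[, -1])
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  lab
}

# fill holes: any non-mask region not connected to the border becomes mask
.fill_holes <- function(mask) {
  outside <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[c(1, nrow(mask)), ] <- outside[c(1, nrow(mask)), ]
  reach[, c(1, ncol(mask))] <- reach[, c(1, ncol(mask))] | outside[, c(1, ncol(mask))]
  repeat {
    nb <- reach
    nb[-1, ] <- nb[-1, ] | reach[-nrow(mask), ]
    nb[-nrow(mask), ] <- nb[-nrow(mask), ] | reach[-1, ]
    nb[, -1] <- nb[, -1] | reach[, -ncol(mask)]
    nb[, -ncol(mask)] <- nb[, -ncol(mask)] | reach[, -1]
    nb <- nb & outside
    if (identical(nb, reach)) break
    reach <- nb
  }
  mask | (outside & !reach)
}

#' Marker-based watershed segmentation of the body contour
#'
#' Segments the patient body from a (smoothed) non-attenuation-corrected
#' reconstruction.  Markers are the image border (background) and pixels
#' above `fg_frac` of the maximum (foreground); Meyer-style flooding on the
#' gradient magnitude, implemented with a quantised-priority bucket queue,
#' grows both markers until they meet at the gradient ridge of the body
#' edge.  The body is the largest connected foreground component with
#' interior holes filled.  The default marker fraction of 0.5 suits graded,
#' body-like objects; high-contrast uniform objects (e.g. the calibration
#' cylinder) segment better at ~0.65 because non-attenuation-corrected
#' reconstructions put an outward halo around hot objects that would
#' otherwise inflate the contour.
#'
#' @param img_smooth Smoothed image matrix.
#' @param fg_frac Foreground marker threshold as a fraction of the maximum
#'   (default 0.5).
#' @param n_levels Number of priority quantisation levels (default 256).
#' @return Logical body mask.
#' @export
watershed_body_mask <- function(img_smooth, fg_frac = 0.5, n_levels = 256L) {
  n <- nrow(img_smooth); m <- ncol(img_smooth)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  gx[2:(n - 1), ] <- (img_smooth[3:n, ] - img_smooth[1:(n - 2), ]) / 2
  gy[, 2:(m - 1)] <- (img_smooth[, 3:m] - img_smooth[, 1:(m - 2)]) / 2
  g <- sqrt(gx^2 + gy^2)
  br <- unique(stats::quantile(g, probs = seq(0, 1, length.out = n_levels + 1L)))
  if (length(br) < 2L) {
    prio <- matrix(1L, n, m)
  } else {
    prio <- matrix(as.integer(cut(g, breaks = br, include.lowest = TRUE,
                                  labels = FALSE)), n, m)
  }
  n_levels <- max(prio)

  lab <- matrix(0L, n, m)
  lab[img_smooth >= fg_frac * max(img_smooth)] <- 2L
  lab[c(1, n), ] <- 1L; lab[, c(1, m)] <- 1L

  # bucket queue of frontier pixels keyed by quantised gradient
  idx <- function(i, j) i + (j - 1L) * n
  buckets <- vector("list", n_levels)
  in_queue <- matrix(FALSE, n, m)
  push <- function(ii) {
    ii <- ii[!in_queue[ii] & lab[ii] == 0L]
    if (length(ii)) {
      in_queue[ii] <<- TRUE
      for (lv in unique(prio[ii])) {
        buckets[[lv]] <<- c(buckets[[lv]], ii[prio[ii] == lv])
      }
    }
  }
  neighbours <- function(ii) {
    i <- ((ii - 1L) %% n) + 1L; j <- ((ii - 1L) %/% n) + 1L
    c(idx(pmax(i - 1L, 1L), j), idx(pmin(i + 1L, n), j),
      idx(i, pmax(j - 1L, 1L)), idx(i, pmin(j + 1L, m)))
  }
  labelled <- which(lab > 0L)
  push(unique(neighbours(labelled)))
  lv <- 1L
  while (lv <= n_levels) {
    if (length(buckets[[lv]]) == 0L) { lv <- lv + 1L; next }
    p <- buckets[[lv]][1L]
    buckets[[lv]] <- buckets[[lv]][-1L]
    if (lab[p] == 0L) {
      nb <- neighbours(p)
      nl <- lab[nb]
      if (any(nl > 0L)) {
        lab[p] <- nl[nl > 0L][1L]
        push(nb)
        # a newly labelled pixel may enable lower-priority neighbours
        open_nb <- nb[lab[nb] == 0L]
        if (length(open_nb)) lv <- min(lv, prio[open_nb])
      }
    }
  }
  body <- lab == 2L
  comp <- .label_components(body)
  if (!any(body)) return(body)
  sizes <- tabulate(comp[comp > 0L])
  body <- comp == which.max(sizes)
  .fill_holes(body)
}

#' Initialize the MLAA state
#'
#' Runs `n0` non-attenuation-corrected MLEM iterations from a uniform
#' activity, smooths the result with a Gaussian filter, segments the body
#' contour with a marker-based watershed, and builds the initial
#' attenuation map: water inside the body, zero outside, overwritten by the
#' known patient-table and reference-object templates.  The non-AC
#' reconstruction serves only to find the contour; the returned starting
#' activity is uniform (the joint loop rebuilds the activity itself).
#'
#' @param y Measured [tof_sinogram()].
#' @param M A [build_system_matrix()] result.
#' @param table_template Attenuation [pet_image()] holding the true table
#'   values (zero elsewhere), or `NULL`.
#' @param table_mask Logical matrix marking the table pixels (or `NULL`).
#' @param ref_template,ref_mask Same for the reference object.
#' @param n0 Non-AC MLEM iterations (default 20).
#' @param smooth_sigma Gaussian filter sigma in pixels (default 2).
#' @param fg_frac Watershed foreground-marker fraction (default 0.5, see
#'   [watershed_body_mask()]; use ~0.65 for high-contrast uniform objects).
#' @param mu_water Water attenuation used inside the body (default 9.6e-3).
#' @return List with `lambda` ([pet_image()]), `mu` ([pet_image()]) and the
#'   segmented `body_mask`.
#' @export
initialize_mlaa <- function(y, M, table_template = NULL, table_mask = NULL,
                            ref_template = NULL, ref_mask = NULL,
                            n0 = 20L, smooth_sigma = 2, fg_frac = 0.5,
                            mu_water = 9.6e-3) {
  rec <- run_mlem(y, M, a = NULL, n_iters = n0)
  sm <- gaussian_smooth(rec$lambda$values, smooth_sigma)
  body <- watershed_body_mask(sm, fg_frac = fg_frac)
  if (!any(body)) stop("body segmentation produced an empty mask")
  mu <- matrix(0, M$grid$nx, M$grid$ny)
  mu[body] <- mu_water
  if (!is.null(table_template) && !is.null(table_mask)) {
    mu[table_mask] <- table_template$values[table_mask]
  }
  if (!is.null(ref_template) && !is.null(ref_mask)) {
    mu[ref_mask] <- ref_template$values[ref_mask]
  }
  list(lambda = activity_image(matrix(1, M$grid$nx, M$grid$ny), M$grid),
       mu = attenuation_image(mu, M$grid),
       body_mask = body,
       lambda_nonac = rec$lambda)
}

# ---- the full MLAA loop -----------------------------------------------------

#' Run the interleaved MLAA reconstruction
#'
#' Alternates TOF-MLEM activity updates with gradient-ascent attenuation
#' updates: every `mu_update_interval` MLEM iterations one attenuation
#' update is applied, followed — in the reference-corrected modes — by the
#' additive bias correction that pins the reference-object ROI mean to its
#' known attenuation.  The attenuation sinogram and the MLEM sensitivity
#' are recomputed after every attenuation change.  Pixels in
#' `cfg$fixed_mask` keep their initial values throughout.
#'
#' @param y Measured [tof_sinogram()].
#' @param M A [build_system_matrix()] result.
#' @param cfg A [recon_config()].
#' @param init Initial state from [initialize_mlaa()], or a list with
#'   `lambda` and `mu` [pet_image()]s.
#' @param truth Optional list with true `activity` [pet_image()] and
#'   `tissue_masks` (as from [make_thorax_phantom()]); when given, the
#'   per-tissue mean percentage difference is traced every
#'   `cfg$trace_every` iterations.
#' @return An object of class `mlaa_fit`: `lambda`, `mu` ([pet_image()]s),
#'   `K_history` (applied bias-correction constants), `trace` (tibble of
#'   per-tissue mean percentage differences vs iteration, if traced),
#'   `config`, `diagnostics`.
#' @export
run_mlaa <- function(y, M, cfg, init, truth = NULL) {
  stopifnot(inherits(cfg, "recon_config"))
  yv <- sino_vec(y)
  n_tof <- M$geometry$n_tof
  nlor <- n_lors(M$geometry)
  y_i <- as.numeric(rowsum(yv, rep(seq_len(nlor), each = n_tof)))

  lambda <- as.vector(init$lambda$values)
  mu <- as.vector(init$mu$values)
  fixed <- if (!is.null(cfg$fixed_mask)) as.vector(cfg$fixed_mask) else NULL
  if (cfg$mode == "ref_corrected_fixed_air") {
    air <- as.vector(cfg$air_mask)
    mu[air] <- 0  # air pinned to zero attenuation throughout
    fixed <- if (is.null(fixed)) air else fixed | air
  }
  roi <- if (!is.null(cfg$roi_mask)) as.vector(cfg$roi_mask) else NULL
  ref_modes <- cfg$mode %in% c("ref_corrected", "ref_corrected_fixed_air")

  a_vec <- exp(-as.numeric(M$L %*% mu))
  den <- mlem_denominator(a_vec, M)

  K_history <- numeric(0)
  n_zero_den <- 0L
  trace_rows <- list()
  record_trace <- !is.null(truth) && cfg$trace_every > 0L
  tissue_idx <- NULL
  if (record_trace) {
    tissue_idx <- lapply(truth$tissue_masks, function(m) {
      w <- which(as.vector(m) & as.vector(truth$activity$values) > 0)
      list(idx = w, truth = as.vector(truth$activity$values)[w])
    })
  }

  for (n in seq_len(cfg$n_mlem_iters)) {
    lambda <- mlem_update(lambda, yv, den, M, cfg$eps)
    if (!all(is.finite(lambda))) {
      stop("non-finite activity at MLEM iteration ", n)
    }
    if (n %% cfg$mu_update_interval == 0L) {
      b_tof <- as.numeric(M$Mtof %*% lambda)
      b_i <- as.numeric(rowsum(b_tof, rep(seq_len(nlor), each = n_tof)))
      st <- attenuation_update(mu, y_i, a_vec * b_i, M,
                               alpha_p = cfg$alpha_p, D = cfg$D, fixed = fixed)
      mu <- st$mu
      n_zero_den <- n_zero_den + st$n_zero_den
      if (ref_modes) {
        bc <- bias_correction(mu, roi, cfg$mu_ref, fixed = fixed)
        mu <- bc$mu
        K_history <- c(K_history, bc$K)
      }
      if (!all(is.finite(mu))) {
        stop("non-finite attenuation at MLEM iteration ", n)
      }
      a_vec <- exp(-as.numeric(M$L %*% mu))
      den <- mlem_denominator(a_vec, M)
    }
    if (record_trace && (n %% cfg$trace_every == 0L || n == cfg$n_mlem_iters)) {
      trace_rows[[length(trace_rows) + 1L]] <- tibble::tibble(
        iteration = n,
        tissue = names(tissue_idx),
        delta = vapply(tissue_idx, function(t) {
          mean((lambda[t$idx] - t$truth) / t$truth) * 100
        }, numeric(1))
      )
    }
  }

  structure(
    list(
      lambda = activity_image(matrix(lambda, M$grid$nx, M$grid$ny), M$grid),
      mu = attenuation_image(matrix(mu, M$grid$nx, M$grid$ny), M$grid),
      K_history = K_history,
      trace = if (length(trace_rows)) dplyr::bind_rows(trace_rows) else NULL,
      config = cfg,
      diagnostics = list(n_zero_den_skipped = n_zero_den)
    ),
    class = "mlaa_fit"
  )
}

#' @export
print.mlaa_fit <- function(x, ...) {
  cat(sprintf("<mlaa_fit> mode = %s, %d MLEM iterations, %d attenuation updates\n",
              x$config$mode, x$config$n_mlem_iters, length(x$K_history)))
  if (length(x$K_history)) {
    cat(sprintf("  final bias-correction constant K = %.3e 1/mm\n",
                x$K_history[length(x$K_history)]))
  }
  invisible(x)
}

#' Clamp an attenuation map to non-negative values
#'
#' Intermediate MLAA attenuation maps may contain negative values (the
#' additive correction must be free to shift the map); this applies the
#' optional final clamp for reporting.
#'
#' @param att An attenuation [pet_image()].
#' @return The clamped image.
#' @export
clamp_attenuation <- function(att) {
  attenuation_image(pmax(att$values, 0), att$grid)
}
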