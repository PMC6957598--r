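#' Noise configuration
#'
#' @param n_events Total number of coincidences to sample (e.g. 1e5, 1e6,
#'   1e7).
#' @param seed Integer RNG seed; sampling is reproducible given the seed.
#' @param method `"rejection"` for the literal acceptance-rejection Monte
#'   Carlo loop, `"multinomial"` for the equivalent (and much faster) direct
#'   multinomial draw.  Both define the same law: a fixed total count
#'   distributed over sinogram entries proportionally to the noise-free
#'   sinogram.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(n_events, seed = 1L,
                         method = c("multinomial", "rejection")) {
  if (n_events <= 0) stop("n_events must be positive")
  if (n_events >= 2^31) stop("n_events must be below 2^31")
  structure(list(n_events = as.integer(round(n_events)),
                 seed = as.integer(seed),
                 method = match.arg(method)),
            class = "noise_config")
}

#' Sample a noisy sinogram with a fixed total count
#'
#' Draws exactly `n_events` coincidences distributed over sinogram entries
#' proportionally to the noise-free sinogram.  The reference method is the
#' acceptance-rejection Monte Carlo loop: pick a uniformly random entry
#' `(i, TOF)` and a uniform random number in `[0, max(y)]`, and accept the
#' event when the random number falls below the noise-free value at that
#' entry, repeating until `n_events` events are accepted.  The default
#' method draws the same multinomial law directly.
#'
#' @param y_clean A [tof_sinogram()] with at least one positive entry.
#' @param cfg A [noise_config()].
#' @return A [tof_sinogram()] of integer counts with
#'   `sum(values) == n_events`.
#' @export
#' @examples
#' g <- sinogram_geometry(n_angles = 4, n_radial = 8, crt_ps = 300, n_tof = 3)
#' y <- tof_sinogram(array(runif(4 * 8 * 3), c(4, 8, 3)), g)
#' n <- sample_sinogram(y, noise_config(1000, seed = 7))
#' sum(n$values)  # exactly 1000
sample_sinogram <- function(y_clean, cfg) {
  stopifnot(inherits(y_clean, "tof_sinogram"), inherits(cfg, "noise_config"))
  yv <- as.vector(y_clean$values)
  if (all(yv <= 0)) stop("noise-free sinogram is all zero; cannot sample")
  counts <- withr::with_seed(cfg$seed, {
    if (cfg$method == "multinomial") {
      as.vector(stats::rmultinom(1L, cfg$n_events, prob = yv))
    } else {
      .sample_rejection(yv, cfg$n_events)
    }
  })
  tof_sinogram(array(as.numeric(counts), dim = dim(y_clean$values)),
               y_clean$geometry)
}

# literal acceptance-rejection loop, vectorised in chunks
.sample_rejection <- function(yv, n_events, chunk = 2e6L) {
  ymax <- max(yv)
  counts <- integer(length(yv))
  got <- 0L
  while (got < n_events) {
    idx <- sample.int(length(yv), chunk, replace = TRUE)
    acc <- idx[stats::runif(chunk) * ymax < yv[idx]]
    need <- n_events - got
    if (length(acc) > need) acc <- acc[seq_len(need)]
    counts <- counts + tabulate(acc, nbins = length(yv))
    got <- got + length(acc)
  }
  counts
}

#' Calibrate the simulated count level against a target noise
#'
#' Reproduces the count-level calibration study: for each candidate count,
#' simulate a uniform water cylinder (20 cm diameter by default), sample
#' that many events, reconstruct with standard MLEM using the known
#' attenuation sinogram, and measure the percent standard deviation
#' (100 * SD / mean) in a centred circular ROI.  Returns the candidate
#' whose SD is closest to the target.
#'
#' @param geometry A [sinogram_geometry()].
#' @param grid An [image_grid()].
#' @param candidate_counts Increasing vector of candidate event counts.
#' @param target_sd_pct Target percent SD (default 5).
#' @param diameter Cylinder diameter in mm (default 200).
#' @param mu Cylinder attenuation (default water, 9.6e-3 1/mm).
#' @param n_iters MLEM iterations (default 100).
#' @param roi_radius Central ROI radius in mm (default 50).
#' @param seed Base RNG seed; one stream per candidate.
#' @param M Optional prebuilt system matrix.
#' @return A list with `selected` (the chosen count) and `table`, a tibble
#'   of `(n_events, sd_pct)`.
#' @export
calibrate_counts <- function(geometry, grid, candidate_counts,
                             target_sd_pct = 5, diameter = 200, mu = 9.6e-3,
                             n_iters = 100L, roi_radius = 50, seed = 1L,
                             M = NULL) {
  stopifnot(length(candidate_counts) >= 1, all(diff(candidate_counts) > 0))
  if (is.null(M)) M <- build_system_matrix(geometry, grid)
  ph <- make_cylinder_phantom(diameter, mu = mu, activity = 1, grid = grid)
  y_clean <- attenuate(forward_project_tof(ph$activity, M),
                       attenuation_sinogram(ph$attenuation, M))
  roi <- rasterize_shape(shape_circle(c(0, 0), roi_radius), grid)
  sd_pct <- vapply(seq_along(candidate_counts), function(k) {
    yn <- sample_sinogram(y_clean, noise_config(candidate_counts[k],
                                                seed = seed + k - 1L))
    rec <- run_mlem(yn, M, a = attenuation_sinogram(ph$attenuation, M),
                    n_iters = n_iters)
    roi_sd_pct(rec$lambda, roi)
  }, numeric(1))
  tab <- tibble::tibble(n_events = candidate_counts, sd_pct = sd_pct)
  list(selected = candidate_counts[which.min(abs(sd_pct - target_sd_pct))],
       table = tab)
}

#' Percent standard deviation in a region of interest
#'
#' @param img A [pet_image()].
#' @param roi_mask Logical matrix.
#' @return `100 * sd / mean` of the image values inside the ROI.
#' @export
roi_sd_pct <- function(img, roi_mask) {
  v <- img$values[roi_mask]
  100 * stats::sd(v) / mean(v)
}
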