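#' Derive a per-stage seed from a master seed
#'
#' Deterministic, documented derivation: `(master + 10007 * stage + 101 *
#' replicate) mod (2^31 - 1)`, with stages numbered `noise = 1`,
#' `recon = 2`, `calibration = 3`.  Keeps every derived seed a valid 32-bit
#' integer.
#'
#' @param master Master integer seed.
#' @param stage Stage name or number.
#' @param replicate Replicate index (default 1).
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage = 1L, replicate = 1L) {
  if (is.character(stage)) {
    stage <- match(stage, c("noise", "recon", "calibration"))
    if (is.na(stage)) stop("unknown stage name")
  }
  as.integer((as.numeric(master) + 10007 * stage + 101 * replicate) %%
               (2^31 - 1))
}

#' Specify an end-to-end experiment
#'
#' Bundles a phantom, a sinogram geometry, a noise level and a
#' reconstruction configuration into one reproducible unit.  Replicate
#' seeds are derived from `master_seed` via [derive_seed()].
#'
#' @param name Label used in reports.
#' @param phantom A [thorax_phantom_spec()] (or any `phantom_spec`).
#' @param geometry A [sinogram_geometry()].
#' @param n_events Total coincidences to sample; `NULL` for noise-free.
#' @param recon A [recon_config()]; its `roi_mask`/`fixed_mask` are filled
#'   in from the phantom at run time when left `NULL`.
#' @param replicates Number of noise replicates (default 1).
#' @param master_seed Master seed for all stochastic stages.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, phantom, geometry = sinogram_geometry(),
                            n_events = 1e7, recon = recon_config(),
                            replicates = 1L, master_seed = 1L) {
  structure(
    list(name = name, phantom = phantom, geometry = geometry,
         n_events = n_events, recon = recon,
         replicates = as.integer(replicates),
         master_seed = as.integer(master_seed)),
    class = "experiment_spec"
  )
}

#' Named experiment presets
#'
#' Ready-made configurations of the simulation studies:
#'
#' * `"reference"` — proposed MLAA with one 4-cm water reference cylinder
#'   at A0 activity, CRT 300 ps, 1e7 coincidences;
#' * `"standard-mlaa"` — the same data reconstructed without any reference
#'   object (standard MLAA);
#' * `"reference-fixed-air"` — the reference configuration with air pixels
#'   pinned to zero attenuation.
#'
#' Any preset accepts overrides for the reference-object activity
#' multiplier, material, cylinder count, CRT and count level, which covers
#' the activity / material / geometry / CRT / count sweeps.
#'
#' @param name Preset name.
#' @param activity_multiplier Reference activity as a multiple of A0.
#' @param material Reference material ([tissue_params()]).
#' @param n_cylinders 1, 2 or 4 reference cylinders.
#' @param crt_ps Coincidence resolving time (ps).
#' @param n_events Total coincidences.
#' @param n_mlem_iters MLEM iterations (default 1000).
#' @param master_seed Master seed.
#' @param grid An [image_grid()].
#' @return An [experiment_spec()].
#' @export
experiment_preset <- function(name = c("reference", "standard-mlaa",
                                       "reference-fixed-air"),
                              activity_multiplier = 1,
                              material = tissue_params("water"),
                              n_cylinders = 1L, crt_ps = 300, n_events = 1e7,
                              n_mlem_iters = 1000L, master_seed = 1L,
                              grid = image_grid()) {
  name <- match.arg(name)
  ref <- reference_object_spec(n_cylinders = n_cylinders,
                               material = material,
                               activity_multiplier = activity_multiplier)
  phantom <- thorax_phantom_spec(grid = grid, reference = ref)
  mode <- switch(name, "reference" = "ref_corrected",
                 "standard-mlaa" = "standard",
                 "reference-fixed-air" = "ref_corrected_fixed_air")
  experiment_spec(
    name = sprintf("%s_A%g_%s_n%d_crt%g_N%g", name, activity_multiplier,
                   material$name, n_cylinders, crt_ps, n_events),
    phantom = phantom,
    geometry = sinogram_geometry(crt_ps = crt_ps),
    n_events = n_events,
    recon = recon_config(n_mlem_iters = n_mlem_iters, mode = mode,
                         mu_ref = if (mode == "standard") NULL else material$mu,
                         roi_mask = if (mode == "standard") NULL else TRUE),
    master_seed = master_seed
  )
}

#' Run an experiment end to end
#'
#' Phantom construction, forward projection, attenuation, noise sampling,
#' initialization, MLAA reconstruction and per-tissue metrics.  The sampled
#' sinogram is rescaled by `sum(y_clean) / n_events` so the reconstruction
#' stays in the units of the true activity (MLEM is scale-equivariant, so
#' this is pure bookkeeping).  When `output_dir` is given, every
#' intermediate is persisted along with the configuration and seeds.
#'
#' @param spec An [experiment_spec()].
#' @param M Optional prebuilt [build_system_matrix()] result.
#' @param output_dir Optional directory for artifacts.
#' @param verbose Print stage progress.
#' @return A list with the phantom truth, the noisy data, one `mlaa_fit`
#'   per replicate (`fits`), and `metrics`, a tibble of per-tissue results
#'   with the experiment name and replicate attached.
#' @export
run_experiment <- function(spec, M = NULL, output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  say <- function(...) if (verbose) message(...)
  say("phantom: ", spec$name)
  ph <- make_thorax_phantom(spec$phantom)
  if (is.null(M)) {
    say("system matrix ...")
    M <- build_system_matrix(spec$geometry, spec$phantom$grid)
  }
  b <- forward_project_tof(ph$activity, M)
  a <- attenuation_sinogram(ph$attenuation, M)
  y_clean <- attenuate(b, a)

  cfg <- spec$recon
  ref_mode <- cfg$mode != "standard"
  if (ref_mode && (isTRUE(cfg$roi_mask) || is.null(cfg$roi_mask))) {
    if (!any(ph$ref_mask)) stop("reference-corrected mode but phantom has no reference object")
    roi <- erode_mask(ph$ref_mask)
    if (!any(roi)) roi <- ph$ref_mask
    cfg$roi_mask <- roi
  }
  if (is.null(cfg$fixed_mask)) cfg$fixed_mask <- ph$table_mask
  if (cfg$mode == "ref_corrected_fixed_air" && is.null(cfg$air_mask)) {
    cfg$air_mask <- !(ph$body_mask | ph$table_mask | ph$ref_mask)
  }

  table_template <- attenuation_image(
    ifelse(ph$table_mask, ph$attenuation$values, 0), spec$phantom$grid)
  ref_template <- attenuation_image(
    ifelse(ph$ref_mask, ph$attenuation$values, 0), spec$phantom$grid)

  truth <- list(activity = ph$activity, tissue_masks = ph$tissue_masks)
  fits <- vector("list", spec$replicates)
  metrics <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    if (is.null(spec$n_events)) {
      y <- y_clean
    } else {
      say("sampling ", spec$n_events, " events (replicate ", r, ") ...")
      yn <- sample_sinogram(y_clean, noise_config(
        spec$n_events, seed = derive_seed(spec$master_seed, "noise", r)))
      y <- tof_sinogram(yn$values * (sum(y_clean$values) / spec$n_events),
                        spec$geometry)
    }
    say("initializing ...")
    init <- initialize_mlaa(y, M,
                            table_template = table_template,
                            table_mask = ph$table_mask,
                            ref_template = ref_template,
                            ref_mask = ph$ref_mask)
    say("running MLAA (", cfg$n_mlem_iters, " iterations) ...")
    fit <- run_mlaa(y, M, cfg, init, truth = truth)
    fits[[r]] <- fit
    metrics[[r]] <- dplyr::mutate(
      metrics_report(fit$lambda, ph$activity, ph$tissue_masks),
      experiment = spec$name, replicate = r, .before = 1L)
    if (!is.null(output_dir)) {
      d <- file.path(output_dir, spec$name)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_image(ph$activity, file.path(d, "true_activity.tsv"))
      write_image(ph$attenuation, file.path(d, "true_attenuation.tsv"))
      write_sinogram(y, file.path(d, sprintf("sinogram_rep%d.tsv", r)))
      write_image(fit$lambda, file.path(d, sprintf("lambda_rep%d.tsv", r)))
      write_image(fit$mu, file.path(d, sprintf("mu_rep%d.tsv", r)))
      utils::write.csv(metrics[[r]],
                       file.path(d, sprintf("metrics_rep%d.csv", r)),
                       row.names = FALSE)
      jsonlite::write_json(
        list(name = spec$name, master_seed = spec$master_seed,
             n_events = spec$n_events, mode = cfg$mode,
             n_mlem_iters = cfg$n_mlem_iters,
             K_history = fit$K_history),
        file.path(d, sprintf("run_rep%d.json", r)), auto_unbox = TRUE,
        digits = NA)
    }
  }
  list(phantom = ph, y_clean = y_clean, fits = fits,
       metrics = dplyr::bind_rows(metrics), spec = spec)
}

#' Combine experiment metrics into a sweep table
#'
#' One row per configuration and tissue, mirroring a published results
#' table.
#'
#' @param results A list of [run_experiment()] results (or of their
#'   `metrics` tibbles).
#' @return A tibble with columns `experiment`, `replicate`, `tissue`,
#'   `delta`, `sd`, `n`.
#' @export
sweep_table <- function(results) {
  dplyr::bind_rows(lapply(results, function(r) {
    if (is.data.frame(r)) r else r$metrics
  }))
}
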