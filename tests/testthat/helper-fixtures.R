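# Shared scaled-down worlds for fast tests.  build_system_matrix() memoises
# per configuration in the package cache, so repeated calls are free.

tiny_grid <- function() image_grid(32, 32, 5)                       # 160 mm FOV
tiny_geometry <- function(n_tof = 5L) {
  sinogram_geometry(n_angles = 16, n_radial = 32, radial_bin = 5,
                    crt_ps = 300, n_tof = n_tof, scanner_diameter = 260)
}

small_grid <- function() image_grid(64, 64, 5)                      # 320 mm FOV
small_geometry <- function() {
  sinogram_geometry(n_angles = 40, n_radial = 64, radial_bin = 5,
                    crt_ps = 300, n_tof = 13, scanner_diameter = 500)
}

small_thorax <- function(reference = reference_object_spec()) {
  make_thorax_phantom(thorax_phantom_spec(small_grid(), reference = reference))
}

# noise-free attenuated TOF data for a phantom
consistent_data <- function(ph, M) {
  b <- forward_project_tof(ph$activity, M)
  a <- attenuation_sinogram(ph$attenuation, M)
  list(b = b, a = a, y = attenuate(b, a))
}

# templates for initialize_mlaa from a thorax phantom
phantom_templates <- function(ph) {
  g <- ph$activity$grid
  list(
    table_template = attenuation_image(
      ifelse(ph$table_mask, ph$attenuation$values, 0), g),
    ref_template = attenuation_image(
      ifelse(ph$ref_mask, ph$attenuation$values, 0), g)
  )
}

# full-scale world shared by the acceptance tests (built once per session)
full_grid <- function() image_grid()
full_geometry <- function() sinogram_geometry()
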