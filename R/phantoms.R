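#' Tissue parameters
#'
#' Linear attenuation coefficients at 511 keV (1/mm) and relative emission
#' activity (arbitrary units) for the materials used in the synthetic
#' phantoms.  Lung and bone use the standard values 2.76e-3 and 12.01e-3
#' 1/mm; soft tissue / water is fixed at 9.6e-3, adipose at 9.0e-3, air at
#' 0, and the patient table at a low-density 3.0e-3.  Emission contrasts
#' emulate a thoracic FDG pattern where lung and adipose take up much less
#' tracer than soft tissue and bone.
#'
#' @param name One of `"lung"`, `"soft"`, `"adipose"`, `"bone"`, `"water"`,
#'   `"air"`, `"table"`.
#' @param mu Attenuation coefficient override (1/mm).
#' @param activity Activity override (a.u.).
#' @return A list with `name`, `mu`, `activity` of class `tissue_params`.
#' @export
#' @examples
#' tissue_params("bone")$mu  # 0.01201
tissue_params <- function(name, mu = NULL, activity = NULL) {
  defaults <- list(
    lung    = list(mu = 2.76e-3,  activity = 0.25),
    soft    = list(mu = 9.6e-3,   activity = 1.0),
    adipose = list(mu = 9.0e-3,   activity = 0.3),
    bone    = list(mu = 12.01e-3, activity = 0.8),
    water   = list(mu = 9.6e-3,   activity = 0),
    air     = list(mu = 0,        activity = 0),
    table   = list(mu = 3.0e-3,   activity = 0)
  )
  if (!name %in% names(defaults)) {
    stop("unknown tissue: ", name, " (expected one of ",
         paste(names(defaults), collapse = ", "), ")")
  }
  out <- defaults[[name]]
  if (!is.null(mu)) out$mu <- mu
  if (!is.null(activity)) out$activity <- activity
  if (out$mu < 0) stop("attenuation coefficient must be >= 0")
  structure(c(list(name = name), out), class = "tissue_params")
}

# ---- shape primitives -------------------------------------------------------

#' Shape primitives for phantom construction
#'
#' Shapes are rasterised with a centre-in-shape rule: a pixel belongs to the
#' shape iff its centre lies inside (no partial-volume weighting).  All
#' coordinates and lengths in mm, origin at the grid centre.
#'
#' @param center Numeric length-2, shape centre (mm).
#' @param semi_axes Numeric length-2, ellipse semi-axes along x and y (mm).
#' @param radius Circle radius (mm).
#' @param half_size Numeric length-2, rectangle half-widths along x and y (mm).
#' @return A shape description list.
#' @name shapes
NULL

#' @rdname shapes
#' @export
shape_ellipse <- function(center, semi_axes) {
  stopifnot(length(center) == 2, length(semi_axes) == 2, all(semi_axes > 0))
  list(type = "ellipse", center = center, semi_axes = semi_axes)
}

#' @rdname shapes
#' @export
shape_circle <- function(center, radius) {
  stopifnot(radius > 0)
  shape_ellipse(center, c(radius, radius))
}

#' @rdname shapes
#' @export
shape_rectangle <- function(center, half_size) {
  stopifnot(length(center) == 2, length(half_size) == 2, all(half_size > 0))
  list(type = "rectangle", center = center, half_size = half_size)
}

#' Rasterise a shape on a grid
#'
#' @param shape A shape from [shape_ellipse()], [shape_circle()] or
#'   [shape_rectangle()].
#' @param grid An [image_grid()].
#' @return Logical `nx` x `ny` matrix: pixel centre inside the shape.
#' @export
rasterize_shape <- function(shape, grid) {
  cc <- grid_coords(grid)
  dx <- outer(cc$x - shape$center[1], rep(1, grid$ny))
  dy <- outer(rep(1, grid$nx), cc$y - shape$center[2])
  switch(shape$type,
    ellipse = (dx / shape$semi_axes[1])^2 + (dy / shape$semi_axes[2])^2 < 1,
    rectangle = abs(dx) < shape$half_size[1] & abs(dy) < shape$half_size[2],
    stop("unknown shape type: ", shape$type)
  )
}

.shape_in_fov <- function(shape, grid) {
  half <- c(grid$nx, grid$ny) * grid$pixel_size / 2
  ext <- switch(shape$type, ellipse = shape$semi_axes, rectangle = shape$half_size)
  all(abs(shape$center) + ext <= half + 1e-9)
}

# ---- cylinder phantom -------------------------------------------------------

#' Uniform cylinder phantom
#'
#' A disk of given diameter centred in the grid, with uniform attenuation
#' and activity; used for count-level calibration (the 20-cm water cylinder)
#' and for parameter-recovery checks.
#'
#' @param diameter Disk diameter (mm); must fit in the field of view.
#' @param mu Attenuation coefficient inside the disk (1/mm).
#' @param activity Activity inside the disk (a.u.).
#' @param grid An [image_grid()].
#' @param center Disk centre (mm), default the origin.
#' @return List with `activity` and `attenuation` ([pet_image()]s) and the
#'   logical `mask` of disk pixels.
#' @export
#' @examples
#' ph <- make_cylinder_phantom(200, mu = 9.6e-3, activity = 1, image_grid())
#' sum(ph$mask) * 25  # disk area in mm^2, close to pi * 100^2
make_cylinder_phantom <- function(diameter, mu = 9.6e-3, activity = 1,
                                  grid = image_grid(), center = c(0, 0)) {
  if (diameter <= 0) stop("diameter must be positive")
  shape <- shape_circle(center, diameter / 2)
  if (!.shape_in_fov(shape, grid)) {
    stop("cylinder of diameter ", diameter, " mm does not fit in the ",
         grid_fov(grid), " mm field of view")
  }
  mask <- rasterize_shape(shape, grid)
  act <- matrix(0, grid$nx, grid$ny); act[mask] <- activity
  att <- matrix(0, grid$nx, grid$ny); att[mask] <- mu
  list(activity = activity_image(act, grid),
       attenuation = attenuation_image(att, grid),
       mask = mask)
}

# ---- reference object -------------------------------------------------------

#' Specify the external reference object
#'
#' One, two or four cylinders of known attenuation placed outside the
#' patient's convex hull.  The single cylinder sits inside the patient
#' table; with two, one more is placed above the patient; with four, two
#' more flank the patient laterally.  The total activity is conserved
#' across `n_cylinders`: each cylinder carries
#' `A0 * activity_multiplier / n_cylinders`.
#'
#' @param n_cylinders 1, 2 or 4.
#' @param diameter Cylinder diameter (mm), default 40.
#' @param material A [tissue_params()]; its `mu` is the known reference
#'   attenuation, default water.
#' @param activity_multiplier Total reference activity as a multiple of the
#'   patient mean activity A0 (>= 0); default 1.
#' @param placements Optional list of centre coordinates (mm), one per
#'   cylinder; defaults depend on the thorax layout and are filled in by
#'   [thorax_phantom_spec()].
#' @return An object of class `reference_object_spec`.
#' @export
reference_object_spec <- function(n_cylinders = 1L, diameter = 40,
                                  material = tissue_params("water"),
                                  activity_multiplier = 1,
                                  placements = NULL) {
  if (!n_cylinders %in% c(1L, 2L, 4L)) stop("n_cylinders must be 1, 2 or 4")
  if (diameter <= 0) stop("diameter must be positive")
  if (activity_multiplier < 0) stop("activity_multiplier must be >= 0")
  if (!is.null(placements) && length(placements) != n_cylinders) {
    stop("need one placement per cylinder")
  }
  structure(
    list(n_cylinders = as.integer(n_cylinders), diameter = diameter,
         material = material, activity_multiplier = activity_multiplier,
         placements = placements),
    class = "reference_object_spec"
  )
}

#' Insert the reference object into a phantom
#'
#' Sets reference pixels to the known material attenuation and to an
#' activity of `A0 * activity_multiplier / n_cylinders` per cylinder, so the
#' total reference activity is conserved across cylinder counts.
#'
#' @param act,att Activity and attenuation [pet_image()]s (modified copies
#'   are returned).
#' @param ref A [reference_object_spec()] with `placements` set.
#' @param A0 Mean activity concentration within the patient body (a.u.).
#' @param body_mask Optional logical matrix; placements overlapping it are
#'   rejected.
#' @return List with updated `activity`, `attenuation` and the logical
#'   `ref_mask`.
#' @export
add_reference_object <- function(act, att, ref, A0, body_mask = NULL) {
  stopifnot(inherits(ref, "reference_object_spec"))
  if (is.null(ref$placements)) stop("reference placements not set")
  grid <- act$grid
  per_cyl <- A0 * ref$activity_multiplier / ref$n_cylinders
  a <- act$values; m <- att$values
  ref_mask <- matrix(FALSE, grid$nx, grid$ny)
  for (ctr in ref$placements) {
    shp <- shape_circle(ctr, ref$diameter / 2)
    if (!.shape_in_fov(shp, grid)) {
      stop("reference cylinder at (", ctr[1], ", ", ctr[2],
           ") extends outside the field of view")
    }
    msk <- rasterize_shape(shp, grid)
    if (!is.null(body_mask) && any(msk & body_mask)) {
      stop("reference cylinder at (", ctr[1], ", ", ctr[2],
           ") overlaps the patient body")
    }
    a[msk] <- per_cyl
    m[msk] <- ref$material$mu
    ref_mask <- ref_mask | msk
  }
  list(activity = activity_image(a, grid),
       attenuation = attenuation_image(m, grid),
       ref_mask = ref_mask)
}

# ---- thorax phantom ---------------------------------------------------------

#' Thorax phantom specification
#'
#' A synthetic stand-in for a thoracic emission/attenuation slice: an
#' elliptical body with a peripheral adipose ring, two elliptical lungs, a
#' circular spine (bone), a rectangular patient table below the body, and a
#' configurable external reference object.  Region sizes scale with the
#' field of view so the same layout works on small test grids.  Activities
#' are rescaled so that the mean over the body equals `A0`.
#'
#' @param grid An [image_grid()].
#' @param A0 Target mean activity concentration in the body (a.u.).
#' @param reference A [reference_object_spec()] or `NULL` for no reference
#'   object.
#' @param tissues Named list of [tissue_params()] for `soft`, `adipose`,
#'   `lung`, `bone`, `table`.
#' @param scale Spatial scale factor applied to the default 640-mm layout;
#'   defaults to `grid_fov(grid) / 640` so the phantom fills any grid.
#' @return An object of class `phantom_spec`.
#' @export
thorax_phantom_spec <- function(grid = image_grid(), A0 = 1,
                                reference = reference_object_spec(),
                                tissues = list(
                                  soft    = tissue_params("soft"),
                                  adipose = tissue_params("adipose"),
                                  lung    = tissue_params("lung"),
                                  bone    = tissue_params("bone"),
                                  table   = tissue_params("table")
                                ),
                                scale = grid_fov(grid) / 640) {
  s <- scale
  regions <- list(
    adipose = shape_ellipse(c(0, 0) * s, c(180, 120) * s),   # full body outline
    soft    = shape_ellipse(c(0, 0) * s, c(165, 105) * s),   # inner body
    lung_l  = shape_ellipse(c(-85, 20) * s, c(50, 65) * s),
    lung_r  = shape_ellipse(c(85, 20) * s, c(50, 65) * s),
    bone    = shape_circle(c(0, -75) * s, 22 * s)
  )
  table_shape <- shape_rectangle(c(0, -160) * s, c(200, 25) * s)
  if (!is.null(reference) && is.null(reference$placements)) {
    # default layout: scale the cylinder with the layout so small test
    # grids keep the same relative geometry
    reference$diameter <- reference$diameter * s
    default_placements <- list(c(0, -160) * s,    # in the table
                               c(0, 160) * s,     # above the patient
                               c(-215, 0) * s,    # lateral
                               c(215, 0) * s)
    reference$placements <- default_placements[seq_len(reference$n_cylinders)]
  }
  structure(
    list(grid = grid, A0 = A0, regions = regions, table_shape = table_shape,
         reference = reference, tissues = tissues, scale = s),
    class = "phantom_spec"
  )
}

#' Build the thorax phantom images
#'
#' Rasterises a [thorax_phantom_spec()] into true activity and attenuation
#' images plus the masks needed downstream.  Later regions overwrite earlier
#' ones (body outline, then inner soft tissue, lungs, spine); the table and
#' reference object lie outside the body.  Activities inside the body are
#' rescaled so `mean(activity[body_mask]) == A0` exactly.
#'
#' @param spec A [thorax_phantom_spec()].
#' @return A list with `activity`, `attenuation` ([pet_image()]s),
#'   `body_mask`, `table_mask`, `ref_mask`, the per-tissue list
#'   `tissue_masks` (`lung`, `soft`, `adipose`, `bone`; a partition of
#'   `body_mask`), `A0` and the input `phantom_spec`.
#' @export
#' @examples
#' ph <- make_thorax_phantom(thorax_phantom_spec())
#' mean(ph$activity$values[ph$body_mask])  # == 1 (A0)
make_thorax_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  act <- matrix(0, grid$nx, grid$ny)
  att <- matrix(0, grid$nx, grid$ny)
  label <- matrix("air", grid$nx, grid$ny)

  paint <- function(shape, tissue) {
    msk <- rasterize_shape(shape, grid)
    act[msk] <<- tissue$activity
    att[msk] <<- tissue$mu
    label[msk] <<- tissue$name
    msk
  }
  paint(spec$regions$adipose, spec$tissues$adipose)
  paint(spec$regions$soft, spec$tissues$soft)
  paint(spec$regions$lung_l, spec$tissues$lung)
  paint(spec$regions$lung_r, spec$tissues$lung)
  paint(spec$regions$bone, spec$tissues$bone)
  body_mask <- label != "air"

  table_mask <- rasterize_shape(spec$table_shape, grid) & !body_mask
  att[table_mask] <- spec$tissues$table$mu
  act[table_mask] <- spec$tissues$table$activity
  label[table_mask] <- "table"

  # normalise body activity so its mean is exactly A0
  mb <- mean(act[body_mask])
  if (mb <= 0) stop("body has no activity; cannot normalise to A0")
  act[body_mask] <- act[body_mask] * (spec$A0 / mb)

  ref_mask <- matrix(FALSE, grid$nx, grid$ny)
  act_img <- activity_image(act, grid)
  att_img <- attenuation_image(att, grid)
  if (!is.null(spec$reference)) {
    res <- add_reference_object(act_img, att_img, spec$reference, spec$A0,
                                body_mask = body_mask)
    act_img <- res$activity; att_img <- res$attenuation; ref_mask <- res$ref_mask
    if (any(ref_mask & table_mask)) table_mask <- table_mask & !ref_mask
  }

  tissue_masks <- list(
    lung    = label == "lung",
    soft    = label == "soft",
    adipose = label == "adipose",
    bone    = label == "bone"
  )
  list(activity = act_img, attenuation = att_img,
       body_mask = body_mask, table_mask = table_mask, ref_mask = ref_mask,
       tissue_masks = tissue_masks, A0 = spec$A0, spec = spec)
}
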