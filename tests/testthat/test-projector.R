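test_that("siddon_trace is exact on axis-aligned and diagonal rays", {
  g <- small_grid()  # offsets fall on pixel-centre rows for 5 mm radial bins

  # vertical LOR through a pixel column centre: every pixel contributes 5 mm
  tr <- siddon_trace(0, 2.5, g, scanner_diameter = 500)
  expect_equal(length(tr$length), 64)
  expect_equal(tr$length, rep(5, 64), tolerance = 1e-12)

  # 45-degree LOR through the centre of a 5x5 grid: each diagonal pixel
  # contributes sqrt(2) * 5 mm
  g5 <- image_grid(5, 5, 5)
  tr45 <- siddon_trace(pi / 4, 0, g5, scanner_diameter = 200)
  expect_equal(sort(tr45$length), rep(sqrt(2) * 5, 5), tolerance = 1e-9)
})

test_that("traced lengths sum to the analytic chord length through the image", {
  g <- small_grid()
  geo <- small_geometry()
  lc <- lor_coordinates(geo)
  # dense sub-sampling oracle: fraction of 1e5 ray points inside the square
  dense_chord <- function(theta, r, R, half, n = 1e5) {
    h <- sqrt(R^2 - r^2)
    tt <- seq(-h, h, length.out = n)
    x <- r * cos(theta) - tt * sin(theta)
    y <- r * sin(theta) + tt * cos(theta)
    mean(abs(x) < half & abs(y) < half) * 2 * h
  }
  set.seed(7)
  for (k in seq_len(8)) {
    ia <- sample(geo$n_angles, 1); ir <- sample(geo$n_radial, 1)
    tr <- siddon_trace(lc$theta[ia], lc$offset[ir], g, geo$scanner_diameter)
    got <- if (is.null(tr)) 0 else sum(tr$length)
    expect_equal(got, dense_chord(lc$theta[ia], lc$offset[ir],
                                  geo$scanner_diameter / 2, 160),
                 tolerance = 2e-3)
  }
  # and exactly (<= 1e-6 mm) against the closed-form box clip
  clip_chord <- function(theta, r, R, half) {
    h <- sqrt(R^2 - r^2); u <- c(-sin(theta), cos(theta)); p0 <- r * c(cos(theta), sin(theta))
    tmin <- -h; tmax <- h
    for (ax in 1:2) {
      if (abs(u[ax]) > 1e-12) {
        tt <- sort(c((-half - p0[ax]) / u[ax], (half - p0[ax]) / u[ax]))
        tmin <- max(tmin, tt[1]); tmax <- min(tmax, tt[2])
      } else if (abs(p0[ax]) >= half) return(0)
    }
    max(tmax - tmin, 0)
  }
  for (ia in c(1, 11, 27)) {
    for (ir in c(5, 33, 60)) {
      tr <- siddon_trace(lc$theta[ia], lc$offset[ir], g, geo$scanner_diameter)
      got <- if (is.null(tr)) 0 else sum(tr$length)
      expect_equal(got, clip_chord(lc$theta[ia], lc$offset[ir],
                                   geo$scanner_diameter / 2, 160),
                   tolerance = 1e-6)
    }
  }
})

test_that("TOF bin weights follow the Gaussian timing kernel", {
  sigma <- tof_sigma_mm(300)
  expect_equal(sigma, 0.2998 * 300 / 2 / (2 * sqrt(2 * log(2))))

  edges <- tof_bin_edges(sinogram_geometry(n_tof = 9, crt_ps = 300),
                         image_grid(64, 64, 5))
  w <- tof_bin_weights(0, sigma, edges)[1, ]

  # midpoint pixel: symmetric weights about the central bin
  expect_equal(w, rev(w), tolerance = 1e-12)
  # central-bin weight equals the closed-form Gaussian integral
  delta <- diff(edges)[1]
  expect_equal(w[5], 2 * stats::pnorm(delta / 2 / sigma) - 1, tolerance = 1e-12)
  # weights sum to at most 1, and to 1 up to the 4-sigma truncation
  expect_lte(sum(w), 1)
  expect_equal(sum(w), 1, tolerance = 1e-3)

  # flat-Gaussian limit: sigma >> FOV makes the weights uniform
  wflat <- tof_bin_weights(0, 1e6, edges, trunc = 4)[1, ]
  expect_equal(wflat / wflat[1], rep(1, 9), tolerance = 1e-6)

  expect_error(tof_sigma_mm(0), "positive")
})

test_that("TOF coefficients sum to the intersection lengths", {
  M <- build_system_matrix(small_geometry(), small_grid())
  # sum over TOF bins of c^TOF reduces to l for pixels whose TOF window is
  # inside the FOV; compare through a centred cylinder so every traversed
  # pixel is well inside
  ph <- make_cylinder_phantom(120, mu = 9.6e-3, activity = 1,
                              grid = small_grid())
  bl <- forward_project(ph$activity, M)$values
  bt <- sum_tof(forward_project_tof(ph$activity, M))$values
  expect_lt(max(abs(bt - bl) / pmax(bl, 1e-9)), 1e-3)
})

test_that("forward operators are linear and consistent", {
  M <- build_system_matrix(small_geometry(), small_grid())
  g <- small_grid()
  ph <- make_cylinder_phantom(150, mu = 9.0e-3, activity = 1.7, grid = g)

  # zero in, zero out; scaling by k scales the sinogram by k
  z <- forward_project_tof(activity_image(matrix(0, 64, 64), g), M)
  expect_true(all(z$values == 0))
  b1 <- forward_project_tof(ph$activity, M)
  b3 <- forward_project_tof(activity_image(3 * ph$activity$values, g), M)
  expect_equal(b3$values, 3 * b1$values, tolerance = 1e-12)

  # grid mismatch rejected
  expect_error(forward_project_tof(
    activity_image(matrix(1, 32, 32), tiny_grid()), M), "grid")
})

test_that("attenuation sinogram obeys the exponential line-integral model", {
  g <- small_grid()
  M <- build_system_matrix(small_geometry(), g)

  # mu == 0 -> a == 1
  a0 <- attenuation_sinogram(attenuation_image(matrix(0, 64, 64), g), M)
  expect_true(all(a0$values == 1))

  ph <- make_cylinder_phantom(200, mu = 9.6e-3, activity = 1, grid = g)
  a <- attenuation_sinogram(ph$attenuation, M)
  expect_true(all(a$values > 0 & a$values <= 1))

  # central LOR: a = exp(-mu * traced chord through the disk)
  lc <- lor_coordinates(small_geometry())
  ir <- which.min(abs(lc$offset - 2.5))
  tr <- siddon_trace(lc$theta[1], lc$offset[ir], g, 500)
  inside <- ph$mask[tr$j]
  expect_equal(a$values[1, ir], exp(-9.6e-3 * sum(tr$length[inside])),
               tolerance = 1e-12)

  # exp additivity: a(mu1 + mu2) = a(mu1) * a(mu2)
  mu2 <- make_cylinder_phantom(100, mu = 3e-3, activity = 1, grid = g)
  asum <- attenuation_sinogram(
    attenuation_image(ph$attenuation$values + mu2$attenuation$values, g), M)
  expect_equal(asum$values,
               a$values * attenuation_sinogram(mu2$attenuation, M)$values,
               tolerance = 1e-12)

  # adding a constant inside a mask multiplies a by exp(-c * chord in mask)
  cadd <- 2e-3
  mu_shift <- ph$attenuation$values
  mu_shift[mu2$mask] <- mu_shift[mu2$mask] + cadd
  chord <- forward_project(pet_image(mu2$mask * 1, g, "activity"), M)$values
  expect_equal(attenuation_sinogram(attenuation_image(mu_shift, g), M)$values,
               a$values * exp(-cadd * chord), tolerance = 1e-10)
})

test_that("attenuate applies the survival factors elementwise", {
  g <- small_grid(); M <- build_system_matrix(small_geometry(), g)
  ph <- make_cylinder_phantom(150, mu = 9.6e-3, activity = 1, grid = g)
  b <- forward_project_tof(ph$activity, M)
  geo <- small_geometry()

  a1 <- nontof_sinogram(matrix(1, geo$n_angles, geo$n_radial), geo)
  expect_equal(attenuate(b, a1)$values, b$values)

  ah <- nontof_sinogram(matrix(0.5, geo$n_angles, geo$n_radial), geo)
  expect_equal(sum(attenuate(b, ah)$values), 0.5 * sum(b$values))

  a <- attenuation_sinogram(ph$attenuation, M)
  y <- attenuate(b, a)
  pos <- b$values > 0
  ratio <- y$values[pos] / b$values[pos]
  afull <- array(rep(a$values, geo$n_tof), dim = dim(b$values))
  expect_equal(ratio, afull[pos], tolerance = 1e-12)
})

test_that("back projection is the exact adjoint of forward projection", {
  M <- build_system_matrix(small_geometry(), small_grid())
  geo <- small_geometry(); g <- small_grid()
  set.seed(11)
  x <- activity_image(matrix(runif(64 * 64), 64, 64), g)
  s_tof <- tof_sinogram(array(runif(40 * 64 * 13), c(40, 64, 13)), geo)
  s_flat <- nontof_sinogram(matrix(runif(40 * 64), 40, 64), geo)

  lhs <- sum(forward_project_tof(x, M)$values * s_tof$values)
  rhs <- sum(x$values * back_project(s_tof, M))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)

  lhs2 <- sum(forward_project(x, M)$values * s_flat$values)
  rhs2 <- sum(x$values * back_project(s_flat, M))
  expect_lt(abs(lhs2 - rhs2) / abs(lhs2), 1e-10)

  # zero sinogram -> zero image; a single-LOR unit sinogram returns that
  # LOR's coefficient row
  z <- nontof_sinogram(matrix(0, 40, 64), geo)
  expect_true(all(back_project(z, M) == 0))
  one <- matrix(0, 40, 64); one[13, 31] <- 1
  row_img <- back_project(nontof_sinogram(one, geo), M)
  lc <- lor_coordinates(geo)
  tr <- siddon_trace(lc$theta[13], lc$offset[31], g, geo$scanner_diameter)
  expect_equal(row_img[tr$j], tr$length, tolerance = 1e-12)
  expect_equal(sum(row_img > 0), length(tr$j))
})

test_that("system matrix is deterministic and mirror-symmetric", {
  geo <- tiny_geometry(); g <- tiny_grid()
  M1 <- build_system_matrix(geo, g)
  # force a rebuild past the in-session memo
  rm(list = ls(envir = tofmlaa:::.matrix_cache), envir = tofmlaa:::.matrix_cache)
  M2 <- build_system_matrix(geo, g)
  expect_identical(M1$L, M2$L)
  expect_identical(M1$Mtof, M2$Mtof)

  # x-mirrored image projects onto the mirrored angle index
  set.seed(3)
  img <- activity_image(matrix(runif(32 * 32), 32, 32), g)
  mir <- activity_image(img$values[32:1, ], g)
  p <- forward_project(img, M1)$values
  pm <- forward_project(mir, M1)$values
  for (ia in c(2, 5, 9)) {
    expect_equal(p[ia, ], pm[geo$n_angles - ia + 2, ], tolerance = 1e-9)
  }
})

test_that("a corrupt on-disk cache entry triggers a clean rebuild", {
  geo <- tiny_geometry(); g <- tiny_grid()
  cache <- withr::local_tempdir()
  rm(list = ls(envir = tofmlaa:::.matrix_cache), envir = tofmlaa:::.matrix_cache)
  M1 <- build_system_matrix(geo, g, cache_dir = cache)
  f <- list.files(cache, full.names = TRUE)
  expect_length(f, 1)
  writeLines("garbage", f)
  rm(list = ls(envir = tofmlaa:::.matrix_cache), envir = tofmlaa:::.matrix_cache)
  M2 <- build_system_matrix(geo, g, cache_dir = cache)
  expect_identical(M1$Mtof, M2$Mtof)
})
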