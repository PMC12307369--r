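brute_force_sphere <- function(center, diameter, grid) {
  # full-grid enumeration, independent of sphere_mask's bounding-box logic
  dm <- dim(grid$data)[1:3]
  idx <- as.matrix(expand.grid(0:(dm[1] - 1), 0:(dm[2] - 1), 0:(dm[3] - 1)))
  w <- voxel_to_world(grid, idx)
  d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 + (w[, 3] - center[3])^2
  m <- array(FALSE, dm)
  m[idx[d2 <= (diameter / 2)^2 + 1e-12, , drop = FALSE] + 1] <- TRUE
  m
}

test_that("a 5-mm sphere on a 1-mm grid centred on a voxel holds 81 voxels", {
  grid <- volume(array(0, dim = c(21, 21, 21)), voxel_size_mm = 1)
  m <- sphere_mask(c(10, 10, 10), 5, grid)
  expect_identical(sum(m$data), 81L)
  expect_identical(m$data, brute_force_sphere(c(10, 10, 10), 5, grid))
})

test_that("sphere masks equal brute-force lattice enumeration", {
  set.seed(30)
  grid <- volume(array(0, dim = c(16, 14, 12)), voxel_size_mm = 1.3)
  for (i in 1:8) {
    ctr <- c(runif(1, 4, 14), runif(1, 4, 12), runif(1, 4, 10))
    dia <- runif(1, 2, 7)
    m <- try(sphere_mask(ctr, dia, grid), silent = TRUE)
    bf <- brute_force_sphere(ctr, dia, grid)
    if (inherits(m, "try-error")) {
      expect_identical(sum(bf), 0L)
    } else {
      expect_identical(m$data, bf)
    }
  }
})

test_that("voxel-centred spheres are symmetric under axis reflection", {
  grid <- volume(array(0, dim = c(15, 15, 15)), voxel_size_mm = 1)
  m <- sphere_mask(c(7, 7, 7), 5, grid)$data
  expect_identical(m, m[15:1, , ])
  expect_identical(m, m[, 15:1, ])
  expect_identical(m, m[, , 15:1])
})

test_that("ROI projection handles identity, shifts and off-grid transforms", {
  grid <- volume(array(0, dim = c(20, 20, 20)), voxel_size_mm = 1)
  m <- sphere_mask(c(10, 10, 10), 5, grid)

  id <- project_roi(m, diag(4), grid)
  expect_identical(id$data, m$data)

  tr <- diag(4); tr[1, 4] <- 1    # one-voxel world translation along x
  sh <- project_roi(m, tr, grid)
  expect_identical(sh$data[2:20, , ], m$data[1:19, , ])

  far <- diag(4); far[1:3, 4] <- c(500, 0, 0)
  expect_error(project_roi(m, far, grid), "empty|outside")
})

test_that("ALPS is exactly 1 on isotropic fields and scale invariant", {
  spec <- tiny_spec()
  grid <- make_template_atlas(spec)$vol
  rois <- alps_rois(tiny_roi_spec(), grid)
  iso <- constant_tensor_field(grid, 0.8e-3, 0.8e-3, 0.8e-3)
  r <- compute_alps(iso, rois)
  expect_identical(r$alps_left, 1)
  expect_identical(r$alps_right, 1)
  expect_identical(r$alps_mean, 1)

  aniso <- constant_tensor_field(grid, 1.6e-3, 1.0e-3, 1.0e-3)
  r1 <- compute_alps(aniso, rois)
  expect_equal(r1$alps_mean, 1.6, tolerance = 1e-12)
  for (cc in c(0.5, 3, 42)) {
    sc <- constant_tensor_field(grid, 1.6e-3 * cc, 1.0e-3 * cc, 1.0e-3 * cc)
    expect_equal(compute_alps(sc, rois)$alps_mean, r1$alps_mean,
                 tolerance = 1e-12)
  }
})

test_that("raising Dxx in one hemisphere's ROIs raises only that index", {
  spec <- tiny_spec()
  grid <- make_template_atlas(spec)$vol
  rois <- alps_rois(tiny_roi_spec(), grid)
  tf <- constant_tensor_field(grid, 1.2e-3, 0.9e-3, 0.9e-3)
  base <- compute_alps(tf, rois)
  bump <- tf
  sel <- rois$proj_left$data
  bump$dxx[sel] <- bump$dxx[sel] * 1.5
  up <- compute_alps(bump, rois)
  expect_gt(up$alps_left, base$alps_left)
  expect_equal(up$alps_right, base$alps_right, tolerance = 1e-12)
})

test_that("swapping hemisphere ROI sets swaps the indices, mean unchanged", {
  spec <- tiny_spec()
  grid <- make_template_atlas(spec)$vol
  rois <- alps_rois(tiny_roi_spec(), grid)
  tf <- constant_tensor_field(grid, 1.3e-3, 0.8e-3, 0.7e-3)
  tf$dxx[rois$proj_left$data] <- 1.9e-3   # make the sides differ
  a <- compute_alps(tf, rois)
  swapped <- list(proj_left = rois$proj_right, proj_right = rois$proj_left,
                  assoc_left = rois$assoc_right, assoc_right = rois$assoc_left)
  b <- compute_alps(tf, swapped)
  expect_equal(a$alps_left, b$alps_right, tolerance = 1e-12)
  expect_equal(a$alps_right, b$alps_left, tolerance = 1e-12)
  expect_equal(a$alps_mean, b$alps_mean, tolerance = 1e-12)
})

test_that("the radiological laterality flag swaps the hemisphere labels", {
  p <- alps_roi_spec()
  r <- alps_roi_spec(laterality = "radiological")
  expect_equal(r$proj_left_mm, p$proj_right_mm)
  expect_equal(r$assoc_right_mm, p$assoc_left_mm)
})

test_that("invalid voxels are excluded from ROI means", {
  spec <- tiny_spec()
  grid <- make_template_atlas(spec)$vol
  rois <- alps_rois(tiny_roi_spec(), grid)
  tf <- constant_tensor_field(grid, 1.6e-3, 1.0e-3, 1.0e-3)
  sel <- which(rois$proj_left$data)
  # poison half the ROI with absurd values but flag them invalid
  half <- sel[seq_len(length(sel) %/% 2)]
  tf$dxx[half] <- 99
  tf$valid[half] <- FALSE
  r <- compute_alps(tf, rois)
  expect_equal(r$alps_left, 1.6, tolerance = 1e-12)
  # a fully invalid ROI is an error
  tf$valid[sel] <- FALSE
  expect_error(compute_alps(tf, rois), "no valid")
})
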