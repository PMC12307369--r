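# Small phantom fixtures: a reduced grid with proportionally reduced region
# boxes and ROI coordinates, cheap enough for per-test rendering.

tiny_box <- function(xlo, xhi, ylo, yhi, zlo, zhi)
  matrix(c(xlo, xhi, ylo, yhi, zlo, zhi), nrow = 2,
         dimnames = list(c("min", "max"), c("x", "y", "z")))

tiny_region_boxes <- function() {
  list(brain      = tiny_box(-21, 21, -33, 9, 9, 39),
       bg         = tiny_box(-15, 15, -30, 0, 10, 14.5),
       cso        = tiny_box(-15, 15, -30, 6, 33, 39),
       midbrain   = tiny_box(16.5, 21, -30, -22, 10, 14.5),
       proj_slab  = tiny_box(-12, 12, -20, -4, 16, 32),
       assoc_slab = tiny_box(-21, 21, -20, -4, 16, 32))
}

tiny_roi_spec <- function(...) {
  alps_roi_spec(proj_left_mm = c(9, -12, 24), proj_right_mm = c(-9, -12, 24),
                assoc_left_mm = c(16, -12, 24), assoc_right_mm = c(-16, -12, 24),
                ...)
}

tiny_spec <- function(snr = Inf, ...) {
  phantom_spec(grid_shape = c(32L, 32L, 24L), voxel_size_mm = 1.5,
               region_boxes = tiny_region_boxes(), snr = snr,
               roi_spec = tiny_roi_spec(), ...)
}

tiny_group <- function(name = "G", n = 2, alps_mean = 1.5, alps_sd = 0,
                       count_median = 4, count_sigma = 0.3,
                       vol_median = 15, vol_sigma = 0.3, ...) {
  group_config(name = name, n_subjects = n,
               alps_mean = alps_mean, alps_between_sd = alps_sd,
               lesion_count_log_median = log(count_median),
               lesion_count_log_sigma = count_sigma,
               lesion_vol_log_median_mm3 = log(vol_median),
               lesion_vol_log_sigma = vol_sigma, ...)
}

# independent forward DWI simulator used as an oracle: full tensor allowed,
# written without reference to the package's synthesis code
simulate_signals <- function(D, bvals, bvecs, s0 = 1000, dims = c(3, 3, 3)) {
  nvol <- length(bvals)
  sig <- array(0, c(dims, nvol))
  for (v in seq_len(nvol)) {
    g <- bvecs[v, ]
    att <- exp(-bvals[v] * drop(t(g) %*% D %*% g))
    sig[, , , v] <- s0 * att
  }
  sig
}

std_gradients <- function(n_dirs = 12) {
  # deterministic directions spread on the sphere plus two b0 volumes
  i <- seq_len(n_dirs) - 0.5
  z <- 1 - 2 * i / n_dirs
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dimnames(dirs) <- NULL
  list(bvals = c(0, 0, rep(1000, n_dirs)),
       bvecs = rbind(c(0, 0, 0), c(0, 0, 0), dirs))
}

# tensor_field with constant diagonal tensors on a given grid (for ALPS
# formula tests without a fit)
constant_tensor_field <- function(grid, dxx, dyy, dzz) {
  dm <- dim(grid$data)[1:3]
  mk <- function(v) array(v, dm)
  structure(list(dxx = mk(dxx), dyy = mk(dyy), dzz = mk(dzz),
                 dxy = mk(0), dxz = mk(0), dyz = mk(0),
                 fa = mk(0), md = mk((dxx + dyy + dzz) / 3),
                 s0 = mk(1000), valid = array(TRUE, dm),
                 affine = grid$affine, mask = array(TRUE, dm)),
            class = "tensor_field")
}

brute_force_seg_counts <- function(a, b) {
  # independent voxel-set comparison
  ia <- which(a != 0); ib <- which(b != 0)
  c(tp = length(intersect(ia, ib)),
    fp = length(setdiff(ia, ib)),
    fn = length(setdiff(ib, ia)))
}
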