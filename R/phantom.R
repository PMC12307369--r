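#' Phantom geometry and acquisition specification
#'
#' Defines the synthetic-subject grid, its world frame, the anatomical
#' region boxes, and the DWI acquisition parameters. The default 64 x 64 x
#' 40 grid at 1.5 mm isotropic spacing has its world origin placed so that
#' the template ALPS ROI centres (x = 24/-28 mm projection, 36/-40 mm
#' association; y = -12; z = 24) fall inside the projection- and
#' association-fiber slabs — the phantom's world frame is an MNI-like frame
#' shifted so the printed coordinates are usable directly.
#'
#' Region boxes are axis-aligned world-mm extents (2 x 3 matrices, rows
#' min/max): `brain`, `bg` (basal ganglia), `cso` (centrum semiovale),
#' `midbrain`, `proj_slab`, `assoc_slab`. BG, CSO and midbrain must be
#' pairwise disjoint and inside the brain; where the fiber slabs overlap,
#' the projection slab takes precedence when tensors are assigned.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size_mm Isotropic spacing in mm (> 0).
#' @param origin_mm World position of voxel (0,0,0); default centres x/y and
#'   shifts z so the ROI plane z = 24 mm is interior.
#' @param region_boxes Named list of 2 x 3 world-extent matrices; defaults
#'   scale with the grid only in the sense that the defaults fit the default
#'   grid.
#' @param s0 Baseline (b = 0) signal amplitude.
#' @param snr Signal-to-noise ratio of the DWI (Rician, sigma = s0/snr);
#'   `Inf` disables noise.
#' @param noise_model `"rician"` (standard for magnitude MRI) or
#'   `"gaussian"` fallback.
#' @param bval Diffusion weighting in s/mm^2 for the non-zero shell.
#' @param n_dirs Number of diffusion directions (near-uniform deterministic
#'   set), plus one b = 0 volume.
#' @param d_perp,d_axial,d_iso Tensor diffusivities in mm^2/s: perpendicular
#'   and axial diffusivity of the fiber slabs, and the isotropic diffusivity
#'   of non-slab brain tissue.
#' @param lesion_radius_mm Tube radius of planted EPVS lesions in mm; kept
#'   at or below 1.5 mm so lesion diameters respect the < 3 mm convention.
#' @param roi_spec An [alps_roi_spec()] the slabs must accommodate, or
#'   `NULL` to skip that check (small test phantoms).
#' @param seed Default seed used when single subjects are generated without
#'   an explicit one.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 40L),
                         voxel_size_mm = 1.5,
                         origin_mm = NULL,
                         region_boxes = NULL,
                         s0 = 1000, snr = 30,
                         noise_model = c("rician", "gaussian"),
                         bval = 1000, n_dirs = 24L,
                         d_perp = 0.4e-3, d_axial = 1.4e-3, d_iso = 0.8e-3,
                         lesion_radius_mm = 1.2,
                         roi_spec = alps_roi_spec(),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be > 0")
  if (snr <= 0) stop("snr must be > 0")
  grid_shape <- as.integer(grid_shape)
  if (is.null(origin_mm))
    origin_mm <- c(-(grid_shape[1] - 1) / 2 * voxel_size_mm,
                   -(grid_shape[2] - 1) / 2 * voxel_size_mm - 12,
                   -(grid_shape[3] - 1) / 2 * voxel_size_mm + 24)
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- origin_mm
  if (is.null(region_boxes)) region_boxes <- default_region_boxes()
  spec <- structure(list(grid_shape = grid_shape,
                         voxel_size_mm = voxel_size_mm,
                         affine = affine, region_boxes = region_boxes,
                         s0 = s0, snr = snr, noise_model = noise_model,
                         bval = bval, n_dirs = as.integer(n_dirs),
                         d_perp = d_perp, d_axial = d_axial, d_iso = d_iso,
                         lesion_radius_mm = lesion_radius_mm,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec, roi_spec)
  spec
}

default_region_boxes <- function() {
  box <- function(xlo, xhi, ylo, yhi, zlo, zhi)
    matrix(c(xlo, xhi, ylo, yhi, zlo, zhi), nrow = 2,
           dimnames = list(c("min", "max"), c("x", "y", "z")))
  list(brain      = box(-45, 45, -57, 33, -3, 51),
       bg         = box(-28.5, 28.5, -34, 4, 1.5, 13.5),
       cso        = box(-30, 30, -40, 10, 36, 51),
       midbrain   = box(-12, 12, -24, -6, -3, 0),
       proj_slab  = box(-33, 29, -22, -2, 14, 34),
       assoc_slab = box(-45, 41, -22, -2, 14, 34))
}

grid_extent_mm <- function(spec) {
  # world extents of voxel centres
  lo <- spec$affine[1:3, 4]
  hi <- lo + (spec$grid_shape - 1) * spec$voxel_size_mm
  rbind(min = lo, max = hi)
}

box_contains_sphere <- function(box, centre, radius) {
  all(centre - radius >= box["min", ] - 1e-9) &&
    all(centre + radius <= box["max", ] + 1e-9)
}

boxes_overlap <- function(a, b) {
  all(a["min", ] <= b["max", ]) && all(b["min", ] <= a["max", ])
}

validate_phantom_spec <- function(spec, roi_spec = NULL) {
  ext <- grid_extent_mm(spec)
  for (nm in names(spec$region_boxes)) {
    bx <- spec$region_boxes[[nm]]
    if (any(bx["min", ] < ext["min", ] - 1e-9) ||
        any(bx["max", ] > ext["max", ] + 1e-9))
      stop("region box '", nm, "' lies outside the phantom grid")
  }
  excl <- c("bg", "cso", "midbrain")
  for (i in seq_along(excl)) for (j in seq_len(i - 1)) {
    if (boxes_overlap(spec$region_boxes[[excl[i]]], spec$region_boxes[[excl[j]]]))
      stop("region boxes '", excl[j], "' and '", excl[i], "' overlap")
  }
  if (!is.null(roi_spec)) {
    r <- roi_spec$diameter_mm / 2
    for (cc in list(roi_spec$proj_left_mm, roi_spec$proj_right_mm))
      if (!box_contains_sphere(spec$region_boxes$proj_slab, cc, r))
        stop("projection slab does not contain the ROI sphere at (",
             paste(cc, collapse = ", "), ")")
    for (cc in list(roi_spec$assoc_left_mm, roi_spec$assoc_right_mm))
      if (!box_contains_sphere(spec$region_boxes$assoc_slab, cc, r))
        stop("association slab does not contain the ROI sphere at (",
             paste(cc, collapse = ", "), ")")
  }
  invisible(spec)
}

# logical mask of voxels whose centres lie inside a world-mm box
box_mask <- function(spec, box) {
  n <- spec$grid_shape
  o <- spec$affine[1:3, 4]
  vs <- spec$voxel_size_mm
  inside1 <- function(ax, k) {
    x <- o[ax] + (0:(n[ax] - 1)) * vs
    x >= box["min", ax] - 1e-9 & x <= box["max", ax] + 1e-9
  }
  outer(outer(inside1(1), inside1(2), "&"), inside1(3), "&")
}

#' Build the phantom's template region atlas
#'
#' Labels: 0 background, 1 brain (interior tissue), 2 basal ganglia, 3
#' centrum semiovale, 4 midbrain. BG, CSO and midbrain are carved out of the
#' brain label and are pairwise disjoint by construction.
#'
#' @param spec A [phantom_spec()].
#' @return A `region_atlas`: a `glymph_volume` of integer labels plus a
#'   `labels` lookup table.
#' @export
make_template_atlas <- function(spec) {
  validate_phantom_spec(spec, NULL)
  lab <- array(0L, dim = spec$grid_shape)
  lab[box_mask(spec, spec$region_boxes$brain)] <- 1L
  lab[box_mask(spec, spec$region_boxes$bg)] <- 2L
  lab[box_mask(spec, spec$region_boxes$cso)] <- 3L
  lab[box_mask(spec, spec$region_boxes$midbrain)] <- 4L
  structure(list(vol = volume(lab, affine = spec$affine),
                 labels = c(background = 0L, brain = 1L, bg = 2L,
                            cso = 3L, midbrain = 4L)),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  tab <- table(factor(x$vol$data, levels = x$labels,
                      labels = names(x$labels)))
  cat("<region_atlas>\n"); print(tab); invisible(x)
}

# Deterministic near-uniform directions on the unit sphere (spherical
# Fibonacci lattice).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(r * cos(phi), r * sin(phi), z)
  dimnames(d) <- NULL
  d
}

#' Gradient table of the phantom acquisition
#'
#' One b = 0 volume followed by `spec$n_dirs` directions at `spec$bval`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `bvals` and `bvecs` (n x 3).
#' @export
phantom_gradients <- function(spec) {
  dirs <- fibonacci_directions(spec$n_dirs)
  list(bvals = c(0, rep(spec$bval, spec$n_dirs)),
       bvecs = rbind(c(0, 0, 0), dirs))
}
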