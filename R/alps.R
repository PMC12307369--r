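#' ALPS ROI specification
#'
#' Centres (template world mm) and diameter of the four spherical ROIs used
#' for the DTI-ALPS index: one projection-fiber and one association-fiber
#' ROI per hemisphere at the level of the lateral-ventricle body. Defaults
#' follow the printed template coordinates: projection (24, -12, 24) left /
#' (-28, -12, 24) right; association (36, -12, 24) left / (-40, -12, 24)
#' right; 5-mm diameter. Note the "left" label carries positive x; set
#' `laterality = "radiological"` to swap the hemisphere labels if your
#' template uses the opposite convention.
#'
#' @param proj_left_mm,proj_right_mm,assoc_left_mm,assoc_right_mm Length-3
#'   world coordinates (mm) of the ROI centres.
#' @param diameter_mm Sphere diameter in mm (> 0), default 5.
#' @param laterality `"printed"` (default) keeps the labels as given;
#'   `"radiological"` swaps left and right labels.
#' @return An `alps_roi_spec` object.
#' @export
alps_roi_spec <- function(proj_left_mm = c(24, -12, 24),
                          proj_right_mm = c(-28, -12, 24),
                          assoc_left_mm = c(36, -12, 24),
                          assoc_right_mm = c(-40, -12, 24),
                          diameter_mm = 5,
                          laterality = c("printed", "radiological")) {
  laterality <- match.arg(laterality)
  if (diameter_mm <= 0) stop("diameter_mm must be > 0")
  s <- list(proj_left_mm = proj_left_mm, proj_right_mm = proj_right_mm,
            assoc_left_mm = assoc_left_mm, assoc_right_mm = assoc_right_mm,
            diameter_mm = diameter_mm, laterality = laterality)
  if (laterality == "radiological") {
    s[c("proj_left_mm", "proj_right_mm")] <- s[c("proj_right_mm", "proj_left_mm")]
    s[c("assoc_left_mm", "assoc_right_mm")] <- s[c("assoc_right_mm", "assoc_left_mm")]
  }
  structure(s, class = "alps_roi_spec")
}

#' Rasterize a spherical ROI onto a volume grid
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its world
#' centre to `center_mm` is `<= diameter_mm / 2` (boundary inclusive).
#'
#' @param center_mm Length-3 world coordinate of the sphere centre.
#' @param diameter_mm Sphere diameter in mm.
#' @param grid A `glymph_volume` supplying the grid and affine.
#' @return Logical `glymph_volume` mask.
#' @export
sphere_mask <- function(center_mm, diameter_mm, grid) {
  if (!is_volume(grid)) stop("`grid` must be a glymph_volume")
  r <- diameter_mm / 2
  dm <- grid_shape(grid)
  # bounding box of the sphere in voxel space
  corners <- as.matrix(expand.grid(center_mm[1] + c(-r, r),
                                   center_mm[2] + c(-r, r),
                                   center_mm[3] + c(-r, r)))
  vc <- world_to_voxel(grid, corners)
  lo <- pmax(floor(apply(vc, 2, min)) - 1, 0)
  hi <- pmin(ceiling(apply(vc, 2, max)) + 1, dm - 1)
  mask <- array(FALSE, dim = dm)
  if (any(hi < lo)) stop("sphere at (", paste(center_mm, collapse = ", "),
                         ") does not intersect the grid")
  idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  w <- voxel_to_world(grid, idx)
  inside <- (w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
            (w[, 3] - center_mm[3])^2 <= r^2 + 1e-12
  if (!any(inside)) stop("empty sphere mask at centre (",
                         paste(center_mm, collapse = ", "), ")")
  mask[idx[inside, , drop = FALSE] + 1] <- TRUE
  volume(mask, affine = grid$affine)
}

#' Project a template-space ROI mask into subject space
#'
#' Nearest-neighbour resampling of a template-space mask through a given
#' template-to-subject affine onto the subject grid (the inverse-transform
#' step of the ALPS procedure; registration estimation itself is an input,
#' not performed here). A warning is raised if the projected voxel count
#' differs from the template count by more than a factor of 2 (adjusted for
#' voxel-volume ratio), mirroring the manual ROI-placement sanity check.
#'
#' @param roi_mask_template Logical `glymph_volume` in template space.
#' @param affine_template_to_subject 4x4 world-to-world affine mapping
#'   template world coordinates to subject world coordinates.
#' @param subject_grid `glymph_volume` supplying the subject grid.
#' @return Logical `glymph_volume` mask on the subject grid.
#' @export
project_roi <- function(roi_mask_template, affine_template_to_subject,
                        subject_grid) {
  Tm <- as.matrix(affine_template_to_subject)
  if (abs(det(Tm)) < .Machine$double.eps) stop("transform must be invertible")
  dm <- grid_shape(subject_grid)
  idx <- as.matrix(expand.grid(0:(dm[1] - 1), 0:(dm[2] - 1), 0:(dm[3] - 1)))
  w_subj <- t(subject_grid$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  w_tmpl <- t(solve(Tm) %*% rbind(t(w_subj), 1))[, 1:3, drop = FALSE]
  src <- world_to_voxel(roi_mask_template, w_tmpl)
  vals <- sample_at_voxel(roi_mask_template$data + 0, src,
                          method = "nearest", outside = 0)
  out <- array(vals > 0.5, dim = dm)
  n_out <- sum(out)
  if (n_out == 0)
    stop("projected ROI is empty: transform maps the ROI outside the grid")
  n_tmpl <- sum(roi_mask_template$data != 0)
  vratio <- prod(voxel_size(roi_mask_template)) / prod(voxel_size(subject_grid))
  expected <- n_tmpl * vratio
  if (n_out > 2 * expected || n_out < expected / 2)
    warning("projected ROI voxel count ", n_out,
            " differs from expected ~", round(expected), " by more than 2x")
  volume(out, affine = subject_grid$affine)
}

#' Build the four ALPS ROI masks on a subject grid
#'
#' Rasterizes the four spheres on the template grid and projects each
#' through the supplied template-to-subject transform.
#'
#' @param roi_spec An [alps_roi_spec()].
#' @param template_grid `glymph_volume` defining the template grid.
#' @param affine_template_to_subject 4x4 world affine (identity for
#'   template-space subjects).
#' @param subject_grid `glymph_volume` defining the subject grid (defaults
#'   to the template grid).
#' @return Named list of logical masks: `proj_left`, `proj_right`,
#'   `assoc_left`, `assoc_right`.
#' @export
alps_rois <- function(roi_spec, template_grid,
                      affine_template_to_subject = diag(4),
                      subject_grid = template_grid) {
  centres <- list(proj_left = roi_spec$proj_left_mm,
                  proj_right = roi_spec$proj_right_mm,
                  assoc_left = roi_spec$assoc_left_mm,
                  assoc_right = roi_spec$assoc_right_mm)
  lapply(centres, function(cc) {
    m <- sphere_mask(cc, roi_spec$diameter_mm, template_grid)
    project_roi(m, affine_template_to_subject, subject_grid)
  })
}

roi_mean <- function(map, valid, mask) {
  sel <- mask & valid
  n <- sum(sel)
  if (n == 0) stop("ROI contains no valid tensor voxels")
  mean(map[sel])
}

#' Compute the DTI-ALPS index from a fitted tensor field
#'
#' Per hemisphere, extracts ROI-mean diffusivities from the tensor diagonal
#' in image coordinates (x left-right, y anterior-posterior, z
#' superior-inferior, as in an axial acquisition): Dxx and Dyy over the
#' projection-fiber ROI, Dxx and Dzz over the association-fiber ROI, and
#' forms
#' \deqn{ALPS = (Dx_{proj} + Dx_{assoc}) / (Dy_{proj} + Dz_{assoc})}
#' The left and right indices are averaged into `alps_mean`, the
#' individual-level measure.
#'
#' @param tf A `tensor_field` from [fit_tensor()].
#' @param rois Named list of four logical masks as returned by
#'   [alps_rois()]: `proj_left`, `proj_right`, `assoc_left`, `assoc_right`.
#' @return An `alps_result`: per-side ROI-mean diffusivities, voxel counts,
#'   `alps_left`, `alps_right`, `alps_mean`.
#' @export
compute_alps <- function(tf, rois) {
  if (!inherits(tf, "tensor_field")) stop("`tf` must be a tensor_field")
  need <- c("proj_left", "proj_right", "assoc_left", "assoc_right")
  if (!all(need %in% names(rois))) stop("rois must contain: ",
                                        paste(need, collapse = ", "))
  msk <- lapply(rois[need], function(r) if (is_volume(r)) r$data != 0 else r != 0)
  side <- function(proj, assoc) {
    dx_proj <- roi_mean(tf$dxx, tf$valid, proj)
    dy_proj <- roi_mean(tf$dyy, tf$valid, proj)
    dx_assoc <- roi_mean(tf$dxx, tf$valid, assoc)
    dz_assoc <- roi_mean(tf$dzz, tf$valid, assoc)
    den <- dy_proj + dz_assoc
    if (!(den > 0)) stop("non-positive ALPS denominator")
    list(dx_proj = dx_proj, dy_proj = dy_proj, dx_assoc = dx_assoc,
         dz_assoc = dz_assoc, alps = (dx_proj + dx_assoc) / den)
  }
  L <- side(msk$proj_left, msk$assoc_left)
  R <- side(msk$proj_right, msk$assoc_right)
  structure(list(
    left = L[c("dx_proj", "dy_proj", "dx_assoc", "dz_assoc")],
    right = R[c("dx_proj", "dy_proj", "dx_assoc", "dz_assoc")],
    roi_voxel_counts = vapply(msk, sum, integer(1)),
    alps_left = L$alps, alps_right = R$alps,
    alps_mean = (L$alps + R$alps) / 2), class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("ALPS index  left %.4f  right %.4f  mean %.4f\n",
              x$alps_left, x$alps_right, x$alps_mean))
  invisible(x)
}
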