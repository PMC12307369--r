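#' Image volumes with a voxel-to-world affine
#'
#' A `glymph_volume` is a 3D (or 4D) numeric array together with a 4x4
#' voxel-to-world affine. Voxel indices are 0-based in the affine convention:
#' the world position of voxel `(i, j, k)` is `affine %*% c(i, j, k, 1)`.
#' This convention is used everywhere in the package.
#'
#' @param data A 3D or 4D numeric/logical array.
#' @param affine 4x4 voxel-to-world matrix. If `NULL`, a diagonal affine is
#'   built from `voxel_size_mm` with the world origin at voxel (0,0,0).
#' @param voxel_size_mm Isotropic or per-axis spacing in mm, used only when
#'   `affine` is `NULL`. Default 1.
#' @return A `glymph_volume` object (list with `data` and `affine`).
#' @export
volume <- function(data, affine = NULL, voxel_size_mm = 1) {
  if (!(is.array(data) && length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array")
  if (is.null(affine)) {
    vs <- rep_len(voxel_size_mm, 3L)
    if (any(vs <= 0)) stop("voxel_size_mm must be strictly positive")
    affine <- diag(c(vs, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be a 4x4 matrix")
  d <- abs(det(affine[1:3, 1:3]))
  if (!is.finite(d) || d < .Machine$double.eps)
    stop("`affine` must be invertible")
  structure(list(data = data, affine = affine), class = "glymph_volume")
}

#' @export
print.glymph_volume <- function(x, ...) {
  cat("<glymph_volume> ", paste(dim(x$data), collapse = " x "),
      " @ ", paste(signif(voxel_size(x), 4), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

is_volume <- function(x) inherits(x, "glymph_volume")

#' Voxel spacing of a volume
#'
#' Per-axis spacing in mm, computed as the column norms of the affine's
#' rotational part.
#'
#' @param v A `glymph_volume`.
#' @return Numeric length-3 vector of spacings.
#' @export
voxel_size <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

grid_shape <- function(v) dim(v$data)[1:3]

#' Map 0-based voxel indices to world coordinates
#'
#' @param v A `glymph_volume` (its affine is used).
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- matrix(idx, ncol = 3L)
  t(v$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' Map world coordinates to 0-based (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world coordinates in mm.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  t(solve(v$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file; the sform, when set, is authoritative for the
#' voxel-to-world affine, otherwise the qform is used.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `glymph_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(array(as.numeric(img), dim = dim(img)), affine = aff)
}

#' Write a volume to NIfTI-1
#'
#' Both qform and sform are written (identically) from the volume's affine.
#'
#' @param v A `glymph_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Trilinear (or nearest-neighbour) sampling of a 3D array at fractional
# 0-based voxel coordinates. Coordinates outside the grid are edge-clamped;
# if `outside` is non-NULL, coordinates more than half a voxel outside the
# grid get that value instead (used for mask projection, where off-grid
# means "not in the mask").
sample_at_voxel <- function(a, coords, method = c("linear", "nearest"),
                            outside = NULL) {
  method <- match.arg(method)
  dm <- dim(a)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  oob <- x < -0.5 | x > dm[1] - 0.5 |
         y < -0.5 | y > dm[2] - 0.5 |
         z < -0.5 | z > dm[3] - 0.5
  cx <- pmin(pmax(x, 0), dm[1] - 1)
  cy <- pmin(pmax(y, 0), dm[2] - 1)
  cz <- pmin(pmax(z, 0), dm[3] - 1)
  if (method == "nearest") {
    out <- a[cbind(round(cx) + 1, round(cy) + 1, round(cz) + 1)]
  } else {
    x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
    x1 <- pmin(x0 + 1, dm[1] - 1); y1 <- pmin(y0 + 1, dm[2] - 1)
    z1 <- pmin(z0 + 1, dm[3] - 1)
    fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
    g <- function(i, j, k) a[cbind(i + 1, j + 1, k + 1)]
    out <-
      g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
      g(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
      g(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
      g(x1, y1, z0) * fx       * fy       * (1 - fz) +
      g(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
      g(x1, y0, z1) * fx       * (1 - fy) * fz +
      g(x0, y1, z1) * (1 - fx) * fy       * fz +
      g(x1, y1, z1) * fx       * fy       * fz
  }
  if (!is.null(outside)) out[oob] <- outside
  out
}

#' Resample a volume to isotropic spacing
#'
#' The output grid covers the input field of view at the requested isotropic
#' spacing, keeping the input's axis orientation and the world position of
#' the first voxel. Continuous images are interpolated trilinearly; label or
#' mask images must use nearest-neighbour interpolation so that no new label
#' values are invented.
#'
#' @param v A `glymph_volume` (3D).
#' @param target_mm Target isotropic spacing in mm (> 0).
#' @param method `"linear"` for intensity images (default) or `"nearest"`
#'   for labels and masks.
#' @return A resampled `glymph_volume`.
#' @export
resample_iso <- function(v, target_mm, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (!is_volume(v)) stop("`v` must be a glymph_volume")
  if (length(target_mm) != 1L || target_mm <= 0) stop("target_mm must be > 0")
  vs <- voxel_size(v)
  dm <- grid_shape(v)
  new_dim <- pmax(1L, as.integer(ceiling(dm * vs / target_mm - 1e-9)))
  dirs <- sweep(v$affine[1:3, 1:3], 2, vs, "/")   # unit column directions
  new_aff <- diag(4)
  new_aff[1:3, 1:3] <- dirs * target_mm
  new_aff[1:3, 4] <- v$affine[1:3, 4]
  idx <- as.matrix(expand.grid(i = 0:(new_dim[1] - 1), j = 0:(new_dim[2] - 1),
                               k = 0:(new_dim[3] - 1)))
  world <- t(new_aff %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  src <- world_to_voxel(v, world)
  vals <- sample_at_voxel(v$data, src, method = method)
  volume(array(vals, dim = new_dim), affine = new_aff)
}

#' Min-max intensity normalization to [-1, 1]
#'
#' Affine map `x -> 2 (x - min) / (max - min) - 1`, sending the minimum to
#' -1 and the maximum to +1.
#'
#' @param v A `glymph_volume` with more than one distinct value.
#' @return Normalized `glymph_volume`.
#' @export
normalize_intensity <- function(v) {
  if (!is_volume(v)) stop("`v` must be a glymph_volume")
  rng <- range(v$data, na.rm = TRUE)
  if (!(rng[2] > rng[1]))
    stop("cannot normalize a constant volume (undefined scaling)")
  out <- v
  out$data <- 2 * (v$data - rng[1]) / (rng[2] - rng[1]) - 1
  out
}

#' Read an FSL-style gradient table
#'
#' `bvals` holds one whitespace-separated row of b-values in s/mm^2;
#' `bvecs` holds three rows (x, y, z components), one column per volume,
#' unit-norm for b > 0 volumes.
#'
#' @param bvals_path,bvecs_path Paths to the two text files.
#' @return List with `bvals` (numeric vector) and `bvecs` (n x 3 matrix).
#' @export
read_gradients <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  m <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(m) != 3L) stop("bvecs file must have exactly 3 rows")
  if (ncol(m) != length(bvals))
    stop("bvals and bvecs describe different numbers of volumes")
  list(bvals = bvals, bvecs = t(unname(m)))
}

#' Write an FSL-style gradient table
#'
#' @param bvals Numeric vector of b-values.
#' @param bvecs n x 3 matrix of gradient directions.
#' @param bvals_path,bvecs_path Output paths.
#' @return Invisibly, `c(bvals_path, bvecs_path)`.
#' @export
write_gradients <- function(bvals, bvecs, bvals_path, bvecs_path) {
  stopifnot(nrow(bvecs) == length(bvals), ncol(bvecs) == 3L)
  writeLines(paste(format(bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bvals_path)
  write.table(t(bvecs), bvecs_path, row.names = FALSE, col.names = FALSE)
  invisible(c(bvals_path, bvecs_path))
}
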