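#' Rule-based EPVS candidate segmentation
#'
#' A transparent intensity-rule segmenter for CSF-isointense perivascular
#' spaces: a voxel is a candidate iff its normalized T1 intensity is below
#' `t1_max` AND its normalized T2 intensity is above `t2_min` AND it lies
#' inside the brain label. Optionally, connected components whose maximum
#' cross-sectional extent exceeds `max_diameter_mm` are removed (the < 3 mm
#' diameter convention for perivascular spaces). Inputs must be
#' co-registered on one grid and normalized to \[-1, 1\]
#' (see [normalize_intensity()]).
#'
#' This is a deliberately simple, fully specified stand-in for learned
#' segmentation models; its thresholds default to the phantom's
#' construction contrasts and are user configuration on real data.
#'
#' @param t1_like,t2_like Normalized `glymph_volume`s on a common grid.
#' @param atlas A `region_atlas` on the same grid.
#' @param t1_max Upper T1 threshold (normalized units), default -0.3.
#' @param t2_min Lower T2 threshold (normalized units), default 0.3.
#' @param max_diameter_mm If non-`NULL`, remove components wider than this
#'   across their principal axis.
#' @return Logical `glymph_volume` mask of EPVS candidates.
#' @export
segment_epvs <- function(t1_like, t2_like, atlas, t1_max = -0.3,
                         t2_min = 0.3, max_diameter_mm = NULL) {
  if (!all(grid_shape(t1_like) == grid_shape(t2_like)) ||
      !all(grid_shape(t1_like) == grid_shape(atlas$vol)))
    stop("t1, t2 and atlas grids do not match")
  brain <- atlas$vol$data > 0L
  cand <- t1_like$data < t1_max & t2_like$data > t2_min & brain
  out <- volume(cand, affine = t1_like$affine)
  if (!is.null(max_diameter_mm)) {
    ls <- label_lesions(out, atlas)
    keep <- vapply(ls$lesions, function(l) l$width_mm <= max_diameter_mm,
                   logical(1))
    cand2 <- array(FALSE, grid_shape(out))
    for (l in ls$lesions[keep]) cand2[l$voxels] <- TRUE
    out <- volume(cand2, affine = t1_like$affine)
  }
  out
}

# 26-connected components of a sparse 3D logical array, BFS over the voxel
# set (no installed R package labels 3D components).
connected_components_26 <- function(mask_arr) {
  dm <- dim(mask_arr)
  lin <- which(mask_arr)
  if (length(lin) == 0) return(list())
  coords <- arrayInd(lin, dm)
  key <- function(ijk) (ijk[, 3] - 1) * dm[1] * dm[2] + (ijk[, 2] - 1) * dm[1] + ijk[, 1]
  inmask <- new.env(hash = TRUE, size = length(lin))
  for (i in seq_along(lin)) assign(as.character(lin[i]), i, envir = inmask)
  visited <- logical(length(lin))
  comps <- list()
  for (s in seq_along(lin)) {
    if (visited[s]) next
    queue <- s; visited[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      members <- c(members, cur)
      nb <- sweep(neighbors26, 2, coords[cur, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
            nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nk <- key(nb[ok, , drop = FALSE])
      for (k in nk) {
        j <- inmask[[as.character(k)]]
        if (!is.null(j) && !visited[j]) {
          visited[j] <- TRUE; queue <- c(queue, j)
        }
      }
    }
    comps[[length(comps) + 1]] <- coords[members, , drop = FALSE]
  }
  comps
}

# principal-axis spread of world-space voxel centres: (max - min) of the
# projection on the first principal component
principal_spread <- function(w) {
  if (nrow(w) == 1) return(c(len = 0, width = 0))
  wc <- sweep(w, 2, colMeans(w))
  e <- eigen(crossprod(wc) / nrow(wc), symmetric = TRUE)
  p1 <- wc %*% e$vectors[, 1]
  p2 <- wc %*% e$vectors[, 2]
  c(len = max(p1) - min(p1), width = max(p2) - min(p2))
}

#' Label connected EPVS lesions and measure them
#'
#' Maximal 26-connected components of a binary mask. Per lesion: voxel
#' list, volume (voxel count x voxel volume), length, width, and region
#' assignment by majority vote of member voxels over the atlas (BG, CSO,
#' midbrain, otherwise "other").
#'
#' Lesion length is defined as the spread of voxel centres projected on the
#' lesion's first principal axis plus one voxel edge — stable for tubes and
#' equal to the end-to-end extent for straight lesions. Width is the same
#' measure on the second principal axis.
#'
#' @param mask Binary `glymph_volume`.
#' @param atlas Optional `region_atlas` on the same grid for region labels.
#' @return A `lesion_set`: list of per-lesion records, plus the grid affine
#'   and spacing.
#' @export
label_lesions <- function(mask, atlas = NULL) {
  arr <- if (is_volume(mask)) mask$data != 0 else mask != 0
  aff <- if (is_volume(mask)) mask$affine else diag(4)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  voxvol <- prod(vs)
  edge <- mean(vs)
  comps <- connected_components_26(arr)
  region_names <- c("2" = "bg", "3" = "cso", "4" = "midbrain")
  lesions <- lapply(comps, function(ijk) {
    w <- t(aff %*% rbind(t(ijk - 1), 1))[, 1:3, drop = FALSE]
    sp <- principal_spread(w)
    region <- "other"
    if (!is.null(atlas)) {
      labs <- atlas$vol$data[ijk]
      labs <- labs[labs %in% c(2L, 3L, 4L)]
      if (length(labs))
        region <- region_names[[names(which.max(table(labs)))]]
    }
    list(voxels = ijk, n_voxels = nrow(ijk),
         volume_mm3 = nrow(ijk) * voxvol,
         length_mm = unname(sp["len"]) + edge,
         width_mm = unname(sp["width"]) + edge,
         region = region)
  })
  structure(list(lesions = lesions, affine = aff, voxel_size_mm = vs),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat("<lesion_set> ", length(x$lesions), " lesions, total volume ",
      round(sum(vapply(x$lesions, `[[`, numeric(1), "volume_mm3")), 1),
      " mm^3\n", sep = "")
  invisible(x)
}

#' Convert a lesion set to a per-lesion table
#'
#' @param ls A `lesion_set`.
#' @return Data frame with `lesion_id`, `region`, `n_voxels`, `volume_mm3`,
#'   `length_mm`.
#' @export
lesion_table <- function(ls) {
  data.frame(
    lesion_id = seq_along(ls$lesions),
    region = vapply(ls$lesions, `[[`, character(1), "region"),
    n_voxels = vapply(ls$lesions, `[[`, integer(1), "n_voxels"),
    volume_mm3 = vapply(ls$lesions, `[[`, numeric(1), "volume_mm3"),
    length_mm = vapply(ls$lesions, `[[`, numeric(1), "length_mm"))
}

#' Exclude lesions shorter than a minimum length
#'
#' Retains exactly the lesions with `length_mm >= min_length_mm` (boundary
#' inclusive: structures shorter than the threshold are excluded, a 2.0 mm
#' lesion is retained at the default threshold). Order and identity of the
#' survivors are preserved; the operation is idempotent.
#'
#' @param ls A `lesion_set`.
#' @param min_length_mm Minimum length in mm (>= 0), default 2.
#' @return Filtered `lesion_set`.
#' @export
filter_by_length <- function(ls, min_length_mm = 2) {
  if (min_length_mm < 0) stop("min_length_mm must be >= 0")
  keep <- vapply(ls$lesions, function(l) l$length_mm >= min_length_mm,
                 logical(1))
  out <- ls
  out$lesions <- ls$lesions[keep]
  out
}

#' EPVS summary metrics
#'
#' Total lesion volume and count, and regional volume fractions: the summed
#' volume of lesions assigned to BG (resp. CSO) divided by the whole-brain
#' volume, times `fraction_scale`. The default scale of 1000 reports
#' per-mille fractions, matching the magnitude convention of regional EPVS
#' volume-fraction tables.
#'
#' @param ls A `lesion_set` (after any length filtering).
#' @param atlas A `region_atlas`; its non-background labels define the
#'   whole-brain volume.
#' @param fraction_scale Multiplier applied to the raw volume ratio.
#' @return List: `total_volume_mm3`, `total_number`, `bg_fraction`,
#'   `cso_fraction`, `whole_brain_volume_mm3`.
#' @export
lesion_metrics <- function(ls, atlas, fraction_scale = 1000) {
  voxvol <- prod(voxel_size(atlas$vol))
  wb <- sum(atlas$vol$data > 0L) * voxvol
  if (wb <= 0) stop("whole-brain volume is zero")
  vols <- vapply(ls$lesions, `[[`, numeric(1), "volume_mm3")
  regs <- vapply(ls$lesions, `[[`, character(1), "region")
  list(total_volume_mm3 = sum(vols),
       total_number = length(ls$lesions),
       bg_fraction = sum(vols[regs == "bg"]) / wb * fraction_scale,
       cso_fraction = sum(vols[regs == "cso"]) / wb * fraction_scale,
       whole_brain_volume_mm3 = wb)
}

#' Voxelwise segmentation agreement: Dice, recall, precision
#'
#' Counts true positives, false positives and false negatives of `pred`
#' against a reference mask and reports
#' `DSC = 2 TP / (2 TP + FP + FN)`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`. The reference is a single rater mask
#' (`mode = "single"`), or the voxelwise union or intersection of two rater
#' masks. Conventions for degenerate inputs: if prediction and reference
#' are both empty all three metrics are 1 (perfect agreement); if exactly
#' one is empty all three are 0.
#'
#' @param pred Binary `glymph_volume` or logical array (the evaluated mask).
#' @param refs A single reference mask, or a list of one or two masks.
#' @param mode `"single"`, `"union"` or `"intersection"`; the latter two
#'   require two references.
#' @return A `seg_eval` list: `tp`, `fp`, `fn`, `dsc`, `recall`,
#'   `precision`.
#' @export
seg_eval <- function(pred, refs, mode = c("single", "union", "intersection")) {
  mode <- match.arg(mode)
  as_arr <- function(x) if (is_volume(x)) x$data != 0 else x != 0
  p <- as_arr(pred)
  if (!is.list(refs) || is_volume(refs)) refs <- list(refs)
  refs <- lapply(refs, as_arr)
  for (r in refs) if (!all(dim(r) == dim(p))) stop("mask grids do not match")
  if (mode == "single") {
    if (length(refs) != 1) stop("mode 'single' takes exactly one reference")
    ref <- refs[[1]]
  } else {
    if (length(refs) != 2)
      stop("mode '", mode, "' requires exactly two reference masks")
    ref <- if (mode == "union") refs[[1]] | refs[[2]] else refs[[1]] & refs[[2]]
  }
  tp <- sum(p & ref); fp <- sum(p & !ref); fn <- sum(!p & ref)
  if (tp + fp + fn == 0) {
    d <- r <- pr <- 1
  } else if (tp == 0 && (fp == 0 || fn == 0)) {
    d <- r <- pr <- 0
  } else {
    d <- 2 * tp / (2 * tp + fp + fn)
    r <- tp / (tp + fn)
    pr <- tp / (tp + fp)
  }
  structure(list(tp = tp, fp = fp, fn = fn, dsc = d, recall = r,
                 precision = pr), class = "seg_eval")
}
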