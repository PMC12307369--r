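# Structural rendering intensities (arbitrary units, pre-normalization).
# Lesions are CSF-isointense: dark on T1-like, bright on T2-like.
T1_LEVELS <- c(background = 0.00, brain = 0.80, bg = 0.72, cso = 0.80,
               midbrain = 0.72, lesion = 0.08)
T2_LEVELS <- c(background = 0.00, brain = 0.38, bg = 0.42, cso = 0.38,
               midbrain = 0.42, lesion = 0.95)

shift_logical <- function(a, d) {
  # shift logical array by integer offset d (length 3), zero padded
  dm <- dim(a)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      if (d[ax] >= dm[ax]) return(out)
      dst[[ax]] <- (1 + d[ax]):dm[ax]; src[[ax]] <- 1:(dm[ax] - d[ax])
    } else {
      if (-d[ax] >= dm[ax]) return(out)
      dst[[ax]] <- 1:(dm[ax] + d[ax]); src[[ax]] <- (1 - d[ax]):dm[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbors26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
neighbors26 <- neighbors26[rowSums(abs(neighbors26)) > 0, ]
neighbors6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

# Rasterize one tubular lesion of n_target voxels into a region box,
# keeping a one-voxel (26-connectivity) separation from `occupied`.
# Returns an n x 3 matrix of 1-based voxel indices, or NULL if this
# placement attempt failed.
try_place_tube <- function(spec, region_idx, region_mask, occupied, n_target) {
  dm <- spec$grid_shape
  vs <- spec$voxel_size_mm
  r <- spec$lesion_radius_mm
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  cvox <- region_idx[sample.int(nrow(region_idx), 1), ]
  # generous half-length so enough candidate voxels exist along the tube
  half_len <- max(n_target * vs^3 / (pi * r^2), vs) * 0.75 + 2 * vs
  reach <- ceiling((half_len + r) / vs)
  lo <- pmax(cvox - reach, 1); hi <- pmin(cvox + reach, dm)
  sub <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  inreg <- region_mask[sub]
  sub <- sub[inreg, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  rel <- sweep(sub, 2, cvox) * vs
  tt <- rel %*% u
  d2 <- rowSums(rel^2) - tt^2
  member <- d2 <= r^2 + 1e-9 & abs(tt) <= half_len
  if (sum(member) < n_target) return(NULL)
  sub <- sub[member, , drop = FALSE]
  ord <- order(abs(tt[member]), d2[member])
  sel <- sub[ord[seq_len(n_target)], , drop = FALSE]
  # one-voxel separation: reject if any 26-neighbour (or the voxel itself)
  # is already occupied
  for (k in seq_len(nrow(neighbors26) + 1)) {
    d <- if (k > nrow(neighbors26)) c(0L, 0L, 0L) else neighbors26[k, ]
    shifted <- sweep(sel, 2, -d)
    ok <- shifted[, 1] >= 1 & shifted[, 1] <= dm[1] &
          shifted[, 2] >= 1 & shifted[, 2] <= dm[2] &
          shifted[, 3] >= 1 & shifted[, 3] <= dm[3]
    if (any(occupied[shifted[ok, , drop = FALSE]])) return(NULL)
  }
  sel
}

plant_lesions <- function(spec, atlas, truth, max_tries = 250L,
                          max_voxels = 50L) {
  lab <- atlas$vol$data
  voxvol <- spec$voxel_size_mm^3
  masks <- list(bg = lab == 2L, cso = lab == 3L)
  idxs <- lapply(masks, function(m) which(m, arr.ind = TRUE))
  occupied <- array(FALSE, spec$grid_shape)
  n <- truth$n_lesions
  voxels <- vector("list", n)
  # place large lesions first: greatly improves packing under separation
  for (i in order(-truth$lesion_vols_mm3)) {
    region <- if (truth$in_bg[i]) "bg" else "cso"
    # cap at the largest tube the regions can accommodate; the truth record
    # reflects the voxelized (possibly capped) volume
    n_target <- min(max_voxels,
                    max(2L, as.integer(round(truth$lesion_vols_mm3[i] / voxvol))))
    placed <- NULL
    for (try in seq_len(max_tries)) {
      placed <- try_place_tube(spec, idxs[[region]], masks[[region]],
                               occupied, n_target)
      if (!is.null(placed)) break
      # under extreme crowding, progressively concede volume rather than
      # fail the whole subject; the planted (recorded) volume stays honest
      if (try %% 50L == 0L && n_target > 2L)
        n_target <- max(2L, n_target - 2L)
    }
    if (is.null(placed))
      stop("unable to place lesion ", i, " of ", n,
           " without overlap; region too crowded")
    occupied[placed] <- TRUE
    voxels[[i]] <- placed
  }
  list(mask = occupied, voxels = voxels,
       voxel_counts = vapply(voxels, nrow, integer(1)))
}

add_gaussian_noise <- function(a, sd) {
  if (sd <= 0) return(a)
  a + stats::rnorm(length(a), 0, sd)
}

#' Synthesize one ground-truthed phantom subject
#'
#' Builds a full single-subject bundle: a diffusion acquisition whose
#' tensor field encodes a known ALPS index, T1-like and T2-like structural
#' volumes with planted tubular EPVS lesions, the region atlas, and the
#' ground-truth record.
#'
#' The tensor construction inverts the ALPS formula: in the
#' projection-fiber slab tensors are `diag(g*d_perp, d_perp, d_axial)`
#' (principal axis z) and in the association-fiber slab
#' `diag(g*d_perp, d_axial, d_perp)` (principal axis y), where `g` is the
#' subject's true ALPS index drawn from the group's normal distribution.
#' All four ROI-mean diffusivities then give
#' `(Dx_proj + Dx_assoc) / (Dy_proj + Dz_assoc) = g` exactly. Remaining
#' brain tissue is isotropic at `d_iso`. DWI magnitudes are
#' `S = s0 * exp(-b g' D g)` with Rician noise at `spec$snr`
#' (`snr = Inf` disables noise; `noise_model = "gaussian"` is available as
#' a fallback).
#'
#' Lesions are tubes of radius `spec$lesion_radius_mm` with random
#' orientation, planted in BG or CSO according to the group's `bg_share`,
#' voxel counts matching the drawn per-lesion volumes, mutually separated
#' by at least one voxel so connected-component labeling recovers the
#' planted count exactly. Any lesion of >= 2 voxels has length >= 2 mm at
#' the default spacing, so every planted lesion survives the minimum-length
#' filter.
#'
#' @param spec A [phantom_spec()].
#' @param group A [group_config()].
#' @param subject_seed Integer seed; the bundle is a deterministic function
#'   of `(spec, group, subject_seed)`.
#' @param with_dwi If `FALSE`, skip DWI synthesis (structural-only studies
#'   of lesion morphometry); all other draws — lesion geometry, structural
#'   noise — are unaffected by this flag.
#' @return A `subject_bundle`: `t1_like`, `t2_like` (`glymph_volume`),
#'   `dwi` (`diffusion_acquisition`, or `NULL`), `gt_epvs_mask`, `atlas`,
#'   `affine_template_to_subject` (identity: phantom subjects live in
#'   template space), and `truth` (scalars plus voxelized lesion stats).
#' @export
synth_subject <- function(spec, group, subject_seed, with_dwi = TRUE) {
  set.seed(as.integer(subject_seed))
  truth <- draw_subject_truth(group)
  atlas <- make_template_atlas(spec)
  lab <- atlas$vol$data
  brain <- lab > 0L
  dm <- spec$grid_shape

  les <- plant_lesions(spec, atlas, truth)
  t1 <- array(T1_LEVELS[["background"]], dm)
  t2 <- array(T2_LEVELS[["background"]], dm)
  for (nm in c("brain", "bg", "cso", "midbrain")) {
    m <- lab == atlas$labels[[nm]]
    t1[m] <- T1_LEVELS[[nm]]; t2[m] <- T2_LEVELS[[nm]]
  }
  t1[les$mask] <- T1_LEVELS[["lesion"]]
  t2[les$mask] <- T2_LEVELS[["lesion"]]
  if (is.finite(spec$snr)) {
    t1 <- add_gaussian_noise(t1, T1_LEVELS[["brain"]] / spec$snr)
    t2 <- add_gaussian_noise(t2, T2_LEVELS[["lesion"]] / spec$snr)
  }

  # DWI synthesis last, so skipping it leaves every other draw untouched
  dwi <- NULL
  if (with_dwi) {
    proj <- box_mask(spec, spec$region_boxes$proj_slab) & brain
    assoc <- box_mask(spec, spec$region_boxes$assoc_slab) & brain & !proj
    g <- truth$alps
    dxx <- array(0, dm); dyy <- array(0, dm); dzz <- array(0, dm)
    dxx[brain] <- spec$d_iso; dyy[brain] <- spec$d_iso
    dzz[brain] <- spec$d_iso
    dxx[proj] <- g * spec$d_perp; dyy[proj] <- spec$d_perp
    dzz[proj] <- spec$d_axial
    dxx[assoc] <- g * spec$d_perp; dyy[assoc] <- spec$d_axial
    dzz[assoc] <- spec$d_perp

    grad <- phantom_gradients(spec)
    nvol <- length(grad$bvals)
    sig <- array(0, c(dm, nvol))
    for (v in seq_len(nvol)) {
      b <- grad$bvals[v]; gv <- grad$bvecs[v, ]
      q <- b * (gv[1]^2 * dxx + gv[2]^2 * dyy + gv[3]^2 * dzz)
      sig[, , , v] <- spec$s0 * exp(-q) * brain
    }
    if (is.finite(spec$snr)) {
      sd_n <- spec$s0 / spec$snr
      if (spec$noise_model == "rician") {
        e1 <- stats::rnorm(length(sig), 0, sd_n)
        e2 <- stats::rnorm(length(sig), 0, sd_n)
        sig <- sqrt((sig + e1)^2 + e2^2)
      } else {
        sig <- sig + stats::rnorm(length(sig), 0, sd_n)
      }
    }
    dwi <- diffusion_acquisition(sig, grad$bvals, grad$bvecs,
                                 affine = spec$affine, mask = brain)
  }

  voxvol <- spec$voxel_size_mm^3
  truth$lesion_voxel_counts <- les$voxel_counts
  truth$epvs_volume_voxelized_mm3 <- sum(les$voxel_counts) * voxvol
  truth$epvs_bg_volume_mm3 <- sum(les$voxel_counts[truth$in_bg]) * voxvol
  truth$epvs_cso_volume_mm3 <- sum(les$voxel_counts[!truth$in_bg]) * voxvol

  structure(list(
    t1_like = volume(t1, affine = spec$affine),
    t2_like = volume(t2, affine = spec$affine),
    dwi = dwi,
    gt_epvs_mask = volume(les$mask, affine = spec$affine),
    atlas = atlas,
    affine_template_to_subject = diag(4),
    truth = truth, spec = spec),
    class = "subject_bundle")
}

#' Synthesize a multi-group phantom cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the cohort is reproducible and each subject can be re-rendered in
#' isolation. The scalar truths agree with [synth_cohort_table()] called
#' with the same groups and seed.
#'
#' @param spec A [phantom_spec()].
#' @param groups List of [group_config()]s with distinct names.
#' @param seed Master seed.
#' @return List with `bundles` (list of `subject_bundle`) and `truth`
#'   (data frame, one row per subject, including `subject_seed`).
#' @export
synth_cohort <- function(spec, groups, seed) {
  nms <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate group names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  if (length(groups) < 1) stop("need at least one group")
  ntot <- sum(vapply(groups, function(g) g$n_subjects, numeric(1)))
  seeds <- derive_subject_seeds(seed, ntot)
  bundles <- vector("list", ntot)
  rows <- vector("list", ntot)
  k <- 0L
  for (g in groups) for (i in seq_len(g$n_subjects)) {
    k <- k + 1L
    bundles[[k]] <- synth_subject(spec, g, seeds[k])
    rows[[k]] <- cbind(truth_row(bundles[[k]]$truth),
                       subject_seed = seeds[k])
  }
  truth <- do.call(rbind, rows)
  truth <- cbind(subject_id = sprintf("S%03d", seq_len(ntot)), truth)
  rownames(truth) <- NULL
  list(bundles = bundles, truth = truth)
}

#' Simulate a rater's correction of a segmentation mask
#'
#' Emulates expert review of an automated EPVS segmentation by perturbing
#' mask boundaries. `add_only` appends outside voxels that touch the mask
#' (6-connectivity), each with probability `rate`, never outside the brain
#' label — the output is a superset of the input, so the input evaluated
#' against the output has zero false positives and precision exactly 1.
#' `delete_only` removes boundary voxels of the mask with probability
#' `rate` (output is a subset). `mixed` applies both.
#'
#' @param mask Binary `glymph_volume` (or logical array).
#' @param mode One of `"add_only"`, `"delete_only"`, `"mixed"`.
#' @param rate Per-boundary-voxel perturbation probability in \[0, 1\].
#' @param seed Integer seed.
#' @param brain Optional logical array / volume restricting additions.
#' @return Perturbed mask of the same type as the input.
#' @export
simulate_rater <- function(mask, mode = c("add_only", "delete_only", "mixed"),
                           rate, seed, brain = NULL) {
  mode <- match.arg(mode)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  vol_in <- is_volume(mask)
  m <- if (vol_in) mask$data != 0 else mask != 0
  if (!is.null(brain)) brain <- if (is_volume(brain)) brain$data != 0 else brain != 0
  set.seed(as.integer(seed))
  out <- m
  if (rate > 0 && any(m)) {
    dil <- m
    ero <- m
    for (k in seq_len(nrow(neighbors6))) {
      s <- shift_logical(m, neighbors6[k, ])
      dil <- dil | s
      ero <- ero & s
    }
    outer_bd <- dil & !m
    if (!is.null(brain)) outer_bd <- outer_bd & brain
    inner_bd <- m & !ero
    if (mode %in% c("add_only", "mixed")) {
      cand <- which(outer_bd)
      keep <- cand[stats::runif(length(cand)) < rate]
      out[keep] <- TRUE
    }
    if (mode %in% c("delete_only", "mixed")) {
      cand <- which(inner_bd)
      drop <- cand[stats::runif(length(cand)) < rate]
      out[drop] <- FALSE
    }
  }
  if (vol_in) volume(out, affine = mask$affine) else out
}
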