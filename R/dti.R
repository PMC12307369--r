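#' Diffusion-weighted acquisition container
#'
#' Bundles a 4D signal array with its gradient table, affine and brain mask.
#' At least one b = 0 volume and at least six distinct, non-collinear b > 0
#' directions are required for the tensor model to be estimable; gradient
#' directions for b > 0 volumes must be unit norm (tolerance 1e-3).
#'
#' @param signals 4D array (x, y, z, volume) of DWI magnitudes.
#' @param bvals Per-volume b-value in s/mm^2.
#' @param bvecs n x 3 matrix of per-volume gradient directions.
#' @param affine 4x4 voxel-to-world matrix.
#' @param mask Logical 3D array restricting the fit (default: all voxels).
#' @return A `diffusion_acquisition` object.
#' @export
diffusion_acquisition <- function(signals, bvals, bvecs, affine = diag(4),
                                  mask = NULL) {
  if (length(dim(signals)) != 4L) stop("`signals` must be a 4D array")
  nvol <- dim(signals)[4]
  bvecs <- matrix(bvecs, ncol = 3L)
  if (length(bvals) != nvol || nrow(bvecs) != nvol)
    stop("bvals/bvecs length must match the number of volumes")
  if (!any(bvals == 0)) stop("at least one b = 0 volume is required")
  dw <- which(bvals > 0)
  if (length(dw) > 0) {
    nrms <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrms - 1) > 1e-3))
      stop("b > 0 gradient directions must be unit norm (tolerance 1e-3)")
  }
  # distinct directions up to sign, and estimability of the 6 tensor terms
  dirs <- bvecs[dw, , drop = FALSE]
  if (nrow(dirs) > 0) {
    canon <- dirs * ifelse(dirs[, 1] < 0 | (dirs[, 1] == 0 & dirs[, 2] < 0) |
                           (dirs[, 1] == 0 & dirs[, 2] == 0 & dirs[, 3] < 0),
                           -1, 1)
    ndistinct <- nrow(unique(round(canon, 6)))
  } else ndistinct <- 0L
  if (ndistinct < 6L)
    stop("need at least 6 distinct non-collinear diffusion directions, got ",
         ndistinct)
  G <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  if (qr(G)$rank < 6L)
    stop("diffusion directions do not span the 6 tensor components")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(signals)[1:3])
  if (!all(dim(mask) == dim(signals)[1:3])) stop("mask grid mismatch")
  structure(list(signals = signals, bvals = as.numeric(bvals), bvecs = bvecs,
                 affine = as.matrix(affine), mask = mask != 0),
            class = "glymph_dwi")
}

# Design matrix of the log-linear tensor model:
# ln S = ln S0 - b g' D g, columns (lnS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
dti_design <- function(bvals, bvecs) {
  gx <- bvecs[, 1]; gy <- bvecs[, 2]; gz <- bvecs[, 3]
  cbind(1, -bvals * gx^2, -bvals * gy^2, -bvals * gz^2,
        -2 * bvals * gx * gy, -2 * bvals * gx * gz, -2 * bvals * gy * gz)
}

# Analytic eigenvalues of many symmetric 3x3 matrices (rows of a 6-column
# matrix dxx,dyy,dzz,dxy,dxz,dyz), descending. Trigonometric closed form.
sym3_eigenvalues <- function(m) {
  a11 <- m[, 1]; a22 <- m[, 2]; a33 <- m[, 3]
  a12 <- m[, 4]; a13 <- m[, 5]; a23 <- m[, 6]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- which(p > 0)   # which() drops NA rows (invalid voxels)
  if (length(nz)) {
    pn <- p[nz]
    b11 <- (a11[nz] - q[nz]) / pn; b22 <- (a22[nz] - q[nz]) / pn
    b33 <- (a33[nz] - q[nz]) / pn
    b12 <- a12[nz] / pn; b13 <- a13[nz] / pn; b23 <- a23[nz] / pn
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
            b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * pn * cos(phi)
    e3 <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
    l1[nz] <- e1
    l3[nz] <- e3
    l2[nz] <- 3 * q[nz] - e1 - e3
  }
  cbind(l1, l2, l3)
}

#' Fractional anisotropy from eigenvalues
#'
#' Standard closed form
#' `FA = sqrt(3/2) * sqrt(sum((lambda - MD)^2)) / sqrt(sum(lambda^2))`,
#' defined as 0 where all eigenvalues are 0.
#'
#' @param ev n x 3 matrix of eigenvalues.
#' @return Numeric vector of FA values in \[0, 1\].
#' @export
fa_from_eigenvalues <- function(ev) {
  ev <- matrix(ev, ncol = 3L)
  md <- rowMeans(ev)
  num <- sqrt(rowSums((ev - md)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, sqrt(3 / 2) * num / den, 0)
  pmin(pmax(fa, 0), 1)
}

#' Fit the diffusion tensor model voxel-wise
#'
#' Unweighted log-linear least squares of `ln S = ln S0 - b g' D g` over all
#' volumes, per masked voxel. Non-positive signal samples are dropped from
#' that voxel's fit; if fewer than 7 samples remain the voxel is flagged
#' invalid and excluded from downstream ROI means. Eigenvalues are clamped
#' below at `eig_floor` (default 1e-6 mm^2/s) and the tensor is
#' reconstructed from the clamped spectrum where clamping was needed, so
#' diffusivities (and ALPS denominators) stay positive.
#'
#' @param acq A `diffusion_acquisition`.
#' @param eig_floor Eigenvalue floor in mm^2/s.
#' @param weighted If `TRUE`, one reweighted pass with weights S^2
#'   (Gauss-Newton step for the exponential model); default `FALSE`.
#' @return A `tensor_field`: arrays `dxx, dyy, dzz, dxy, dxz, dyz`, scalar
#'   maps `fa`, `md`, baseline `s0`, logical `valid`, plus `affine`, `mask`.
#' @export
fit_tensor <- function(acq, eig_floor = 1e-6, weighted = FALSE) {
  if (!inherits(acq, "glymph_dwi")) stop("`acq` must be a diffusion_acquisition")
  dm <- dim(acq$signals)[1:3]
  nvol <- dim(acq$signals)[4]
  X <- dti_design(acq$bvals, acq$bvecs)
  vox <- which(acq$mask)
  nv <- length(vox)
  S <- matrix(acq$signals, ncol = nvol)[vox, , drop = FALSE]

  beta <- matrix(NA_real_, nrow = nv, ncol = 7L)
  allpos <- rowSums(S <= 0) == 0L
  if (any(allpos)) {
    P <- solve(crossprod(X), t(X))            # 7 x nvol
    beta[allpos, ] <- log(S[allpos, , drop = FALSE]) %*% t(P)
  }
  bad <- which(!allpos)
  for (i in bad) {
    keep <- S[i, ] > 0
    if (sum(keep) < 7L) next                  # stays NA -> invalid
    Xi <- X[keep, , drop = FALSE]
    if (qr(Xi)$rank < 7L) next
    beta[i, ] <- qr.coef(qr(Xi), log(S[i, keep]))
  }
  if (weighted) {
    ok <- which(!is.na(beta[, 1]))
    for (i in ok) {
      keep <- S[i, ] > 0
      Xi <- X[keep, , drop = FALSE]
      w <- exp(Xi %*% beta[i, ])[, 1]^2       # predicted-signal^2 weights
      beta[i, ] <- qr.coef(qr(Xi * sqrt(w)), sqrt(w) * log(S[i, keep]))
    }
  }

  valid_v <- !is.na(beta[, 1])
  D <- beta[, 2:7, drop = FALSE]
  ev <- sym3_eigenvalues(D)
  clamped <- valid_v & (ev[, 3] < eig_floor)
  if (any(clamped)) {
    for (i in which(clamped)) {
      M <- matrix(c(D[i, 1], D[i, 4], D[i, 5],
                    D[i, 4], D[i, 2], D[i, 6],
                    D[i, 5], D[i, 6], D[i, 3]), 3, 3)
      e <- eigen(M, symmetric = TRUE)
      lam <- pmax(e$values, eig_floor)
      M2 <- e$vectors %*% diag(lam) %*% t(e$vectors)
      D[i, ] <- c(M2[1, 1], M2[2, 2], M2[3, 3], M2[1, 2], M2[1, 3], M2[2, 3])
      ev[i, ] <- lam
    }
  }
  ev <- pmax(ev, eig_floor)
  fa <- fa_from_eigenvalues(ev)
  md <- rowMeans(ev)

  blank <- function() array(NA_real_, dim = dm)
  out <- list(dxx = blank(), dyy = blank(), dzz = blank(),
              dxy = blank(), dxz = blank(), dyz = blank(),
              fa = blank(), md = blank(), s0 = blank(),
              valid = array(FALSE, dim = dm),
              affine = acq$affine, mask = acq$mask)
  cols <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  for (j in seq_along(cols)) out[[cols[j]]][vox] <- ifelse(valid_v, D[, j], NA)
  out$fa[vox] <- ifelse(valid_v, fa, NA)
  out$md[vox] <- ifelse(valid_v, md, NA)
  out$s0[vox] <- ifelse(valid_v, exp(beta[, 1]), NA)
  out$valid[vox] <- valid_v
  structure(out, class = "tensor_field")
}

#' Extract FA and MD scalar maps from a fitted tensor field
#'
#' @param tf A `tensor_field` from [fit_tensor()].
#' @return List with `fa` and `md` as `glymph_volume`s (invalid voxels NA).
#' @export
scalar_maps <- function(tf) {
  if (!inherits(tf, "tensor_field")) stop("`tf` must be a tensor_field")
  list(fa = volume(tf$fa, affine = tf$affine),
       md = volume(tf$md, affine = tf$affine))
}
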