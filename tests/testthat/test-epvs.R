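mask_vol <- function(arr, vs = 1) volume(arr != 0, voxel_size_mm = vs)

test_that("seg_eval matches hand-computable cases", {
  a <- array(FALSE, c(5, 5, 2)); b <- a
  a[1:3, 1, 1] <- TRUE; b[1:3, 1, 1] <- TRUE
  same <- seg_eval(mask_vol(a), mask_vol(b))
  expect_equal(c(same$dsc, same$recall, same$precision), c(1, 1, 1))

  b2 <- array(FALSE, c(5, 5, 2)); b2[1:3, 5, 2] <- TRUE
  disj <- seg_eval(mask_vol(a), mask_vol(b2))
  expect_equal(c(disj$dsc, disj$recall, disj$precision), c(0, 0, 0))

  # constructed tp = 9, fp = 1, fn = 2
  p <- array(FALSE, c(4, 4, 2)); r <- p
  p[1:10] <- TRUE
  r[1:9] <- TRUE; r[11:12] <- TRUE
  ev <- seg_eval(mask_vol(p), mask_vol(r))
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(9L, 1L, 2L))
  expect_equal(ev$dsc, 18 / 21)
  expect_equal(ev$recall, 9 / 11)
  expect_equal(ev$precision, 0.9)

  # empty-mask conventions
  e <- array(FALSE, c(3, 3, 1))
  both <- seg_eval(mask_vol(e), mask_vol(e))
  expect_equal(c(both$dsc, both$recall, both$precision), c(1, 1, 1))
  one <- seg_eval(mask_vol(e), mask_vol(a[1:3, 1:3, 1, drop = FALSE]))
  expect_equal(c(one$dsc, one$recall, one$precision), c(0, 0, 0))
})

test_that("seg_eval equals brute-force voxel counting on random mask pairs", {
  set.seed(40)
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    dm <- c(6, 5, 4)
    a <- array(runif(prod(dm)) < 0.3, dm)
    b <- array(runif(prod(dm)) < 0.3, dm)
    cts <- brute_force_seg_counts(a, b)
    ev <- seg_eval(a, b)
    expect_identical(ev$tp, unname(cts["tp"]))
    expect_identical(ev$fp, unname(cts["fp"]))
    expect_identical(ev$fn, unname(cts["fn"]))
    tp <- cts["tp"]; fp <- cts["fp"]; fn <- cts["fn"]
    if (tp + fp + fn > 0 && !(tp == 0 && (fp == 0 || fn == 0))) {
      expect_equal(ev$dsc, unname(2 * tp / (2 * tp + fp + fn)))
      expect_equal(ev$recall, unname(tp / (tp + fn)))
      expect_equal(ev$precision, unname(tp / (tp + fp)))
    }
    # symmetry: recall(A|B) = precision(B|A); DSC symmetric and harmonic
    ev_ba <- seg_eval(b, a)
    expect_equal(ev$recall, ev_ba$precision)
    expect_equal(ev$dsc, ev_ba$dsc)
    if (ev$precision + ev$recall > 0)
      expect_equal(ev$dsc,
                   2 * ev$precision * ev$recall / (ev$precision + ev$recall))
  }
})

test_that("union and intersection references bound the single-rater metrics", {
  spec <- tiny_spec()
  g <- tiny_group(count_median = 6)
  b <- synth_subject(spec, g, 13)
  gt <- b$gt_epvs_mask
  brain <- b$atlas$vol$data > 0
  # precision has a fixed denominator |pred|, so it is monotone
  # nondecreasing in the reference set: intersection <= single <= union
  pred <- simulate_rater(gt, "mixed", 0.15, seed = 1, brain = brain)
  r1 <- simulate_rater(gt, "mixed", 0.2, seed = 2, brain = brain)
  r2 <- simulate_rater(gt, "mixed", 0.2, seed = 3, brain = brain)
  e1 <- seg_eval(pred, r1); e2 <- seg_eval(pred, r2)
  eu <- seg_eval(pred, list(r1, r2), "union")
  ei <- seg_eval(pred, list(r1, r2), "intersection")
  expect_gte(eu$precision, max(e1$precision, e2$precision) - 1e-12)
  expect_lte(ei$precision, min(e1$precision, e2$precision) + 1e-12)
  # with add-only raters the references are supersets of the prediction, so
  # recall against the union (the largest reference) is the smallest
  a1 <- simulate_rater(gt, "add_only", 0.3, seed = 4, brain = brain)
  a2 <- simulate_rater(gt, "add_only", 0.3, seed = 5, brain = brain)
  ra <- seg_eval(gt, a1); rb <- seg_eval(gt, a2)
  ru <- seg_eval(gt, list(a1, a2), "union")
  expect_lte(ru$recall, min(ra$recall, rb$recall) + 1e-12)
  expect_error(seg_eval(pred, list(r1), "union"), "two reference")
})

test_that("connected-component labeling separates and measures lesions", {
  arr <- array(FALSE, c(12, 8, 6))
  arr[2:6, 2, 2] <- TRUE          # straight 5-voxel tube along x
  arr[9:10, 6, 5] <- TRUE         # second lesion, well separated
  ls <- label_lesions(mask_vol(arr, vs = 1))
  expect_length(ls$lesions, 2)
  lens <- sort(vapply(ls$lesions, `[[`, numeric(1), "length_mm"))
  expect_equal(lens, c(2, 5))     # spread + one voxel edge
  vols <- sort(vapply(ls$lesions, `[[`, numeric(1), "volume_mm3"))
  expect_equal(vols, c(2, 5))

  # 10 voxels at 1 mm isotropic -> 10 mm^3
  arr2 <- array(FALSE, c(12, 8, 6)); arr2[2:11, 4, 3] <- TRUE
  ls2 <- label_lesions(mask_vol(arr2, vs = 1))
  expect_equal(ls2$lesions[[1]]$volume_mm3, 10)

  # diagonal touching counts as connected under 26-connectivity
  arr3 <- array(FALSE, c(6, 6, 6))
  arr3[2, 2, 2] <- TRUE; arr3[3, 3, 3] <- TRUE
  expect_length(label_lesions(mask_vol(arr3))$lesions, 1)
})

test_that("length filter keeps >= 2 mm, is idempotent, never grows", {
  mk_lesion <- function(len) list(voxels = matrix(1, 1, 3), n_voxels = 1L,
                                  volume_mm3 = 1, length_mm = len,
                                  width_mm = 1, region = "bg")
  ls <- structure(list(lesions = lapply(c(1.0, 1.9, 2.0, 6.3), mk_lesion),
                       affine = diag(4), voxel_size_mm = rep(1, 3)),
                  class = "lesion_set")
  f <- filter_by_length(ls, 2)
  expect_length(f$lesions, 2)
  expect_equal(vapply(f$lesions, `[[`, numeric(1), "length_mm"), c(2.0, 6.3))
  # boundary: exactly 2.0 retained, 1.5 excluded
  expect_length(filter_by_length(structure(list(
    lesions = list(mk_lesion(1.5)), affine = diag(4),
    voxel_size_mm = rep(1, 3)), class = "lesion_set"), 2)$lesions, 0)
  # idempotence and monotonicity
  ff <- filter_by_length(f, 2)
  expect_identical(ff$lesions, f$lesions)
  expect_lte(length(f$lesions), length(ls$lesions))
  expect_error(filter_by_length(ls, -1), ">= 0")
})

test_that("lesion metrics compute totals and regional fractions", {
  spec <- tiny_spec()
  atlas <- make_template_atlas(spec)
  ls0 <- structure(list(lesions = list(), affine = atlas$vol$affine,
                        voxel_size_mm = voxel_size(atlas$vol)),
                   class = "lesion_set")
  m0 <- lesion_metrics(ls0, atlas)
  expect_equal(c(m0$total_volume_mm3, m0$total_number,
                 m0$bg_fraction, m0$cso_fraction), c(0, 0, 0, 0))

  # single 10 mm^3 BG lesion, fractions against the known brain volume
  one <- structure(list(lesions = list(list(voxels = matrix(1, 1, 3),
                                            n_voxels = 3L, volume_mm3 = 10,
                                            length_mm = 3, width_mm = 1.5,
                                            region = "bg")),
                        affine = atlas$vol$affine,
                        voxel_size_mm = voxel_size(atlas$vol)),
                   class = "lesion_set")
  m1 <- lesion_metrics(one, atlas, fraction_scale = 1000)
  wb <- sum(atlas$vol$data > 0) * prod(voxel_size(atlas$vol))
  expect_equal(m1$bg_fraction, 10 / wb * 1000)
  expect_equal(m1$cso_fraction, 0)
})

test_that("planted ground truth is recovered exactly by the morphometry chain", {
  spec <- tiny_spec()
  g <- tiny_group(count_median = 5, vol_median = 20)
  for (s in c(3, 4)) {
    b <- synth_subject(spec, g, s)
    ls <- filter_by_length(label_lesions(b$gt_epvs_mask, b$atlas), 2)
    m <- lesion_metrics(ls, b$atlas)
    expect_identical(m$total_number, b$truth$n_lesions)
    expect_equal(m$total_volume_mm3, b$truth$epvs_volume_voxelized_mm3)
    expect_equal(sum(vapply(ls$lesions, function(l)
      if (l$region == "bg") l$volume_mm3 else 0, numeric(1))),
      b$truth$epvs_bg_volume_mm3)
  }
})

test_that("rule-based segmentation is exact without noise, good at SNR 20", {
  spec <- tiny_spec(snr = Inf)
  g <- tiny_group(count_median = 5)
  b <- synth_subject(spec, g, 21)
  pred <- segment_epvs(normalize_intensity(b$t1_like),
                       normalize_intensity(b$t2_like), b$atlas)
  expect_identical(pred$data, b$gt_epvs_mask$data)

  # empty brain stays empty
  g0 <- tiny_group(count_median = 1)
  b0 <- synth_subject(spec, g0, 22)
  empty_t1 <- b0$t1_like; empty_t1$data[b0$gt_epvs_mask$data] <- 0.8
  empty_t2 <- b0$t2_like; empty_t2$data[b0$gt_epvs_mask$data] <- 0.38
  pred0 <- segment_epvs(normalize_intensity(empty_t1),
                        normalize_intensity(empty_t2), b0$atlas)
  expect_identical(sum(pred0$data), 0L)

  specn <- tiny_spec(snr = 20)
  bn <- synth_subject(specn, g, 23)
  predn <- segment_epvs(normalize_intensity(bn$t1_like),
                        normalize_intensity(bn$t2_like), bn$atlas)
  expect_gt(seg_eval(predn, bn$gt_epvs_mask)$dsc, 0.8)

  bad <- volume(array(0, c(4, 4, 4)))
  expect_error(segment_epvs(bad, bad, b$atlas), "match")
})
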