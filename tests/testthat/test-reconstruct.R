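test_that("spline windows are symmetric, separable and centre-peaked", {
  w <- spline_window(c(8, 8))$w
  expect_equal(w, w[8:1, ]) # reflection symmetry
  expect_equal(w, w[, 8:1])
  one_d <- as.vector(spline_window(8)$w)
  expect_equal(w, outer(one_d, one_d), ignore_attr = TRUE) # separability
  # closed-form evaluation oracle for the taper
  s <- sin(pi * (seq_len(8) - 0.5) / 8)^2
  expect_equal(one_d, pmax(s / max(s), 1e-3))
  expect_gt(w[4, 4], w[1, 1])
  expect_true(all(w > 0))
})

test_that("merging is a weighted partition of unity", {
  # constant patches stay constant under any window
  g <- systematic_grid(c(64, 64), c(32, 32), 0.5, pad = "reflect")
  patches <- rep(list(matrix(0.37, 32, 32)), nrow(g$starts))
  expect_true(all(abs(merge_patches(patches, g, "flat") - 0.37) < 1e-12))
  expect_true(all(abs(merge_patches(patches, g, spline_window(c(32, 32))) - 0.37) < 1e-12))
})

test_that("cut-and-merge reproduces the source volume bit-exactly", {
  set.seed(2)
  v <- array(runif(12 * 48 * 48), c(12, 48, 48))
  for (ov in c(0, 0.5)) {
    g <- systematic_grid(dim(v), c(4, 16, 16), ov, pad = "reflect")
    expect_identical(merge_patches(extract_patches(v, g), g, "flat"), v)
  }
})

test_that("overlapping flat merge averages exactly (1D accumulation oracle)", {
  g <- structure(
    list(
      starts = matrix(c(0L, 2L), 2, 1), patch_shape = 4L,
      volume_shape = 6L, padded_shape = 6L, overlap = 0.5, pad = "shift"
    ),
    class = "patch_grid"
  )
  p1 <- array(c(1, 2, 3, 4), 4L)
  p2 <- array(c(10, 20, 30, 40), 4L)
  out <- merge_patches(list(p1, p2), g, "flat")
  # brute-force accumulation oracle
  num <- c(1, 2, 3 + 10, 4 + 20, 30, 40)
  den <- c(1, 1, 2, 2, 1, 1)
  expect_equal(as.vector(out), num / den)
})

test_that("uncovered voxels are an error", {
  g <- structure(
    list(
      starts = matrix(0L, 1, 1), patch_shape = 4L,
      volume_shape = 6L, padded_shape = 6L, overlap = 0, pad = "shift"
    ),
    class = "patch_grid"
  )
  expect_error(merge_patches(list(array(1, 4L)), g, "flat"), "uncovered")
})

test_that("TTA enumerates 8 (2D) and 16 (3D) distinct invertible variants", {
  set.seed(4)
  p2 <- matrix(runif(36), 6, 6)
  e2 <- tta_expand(p2)
  expect_length(e2$patches, 8L)
  expect_equal(length(unique(lapply(e2$patches, c))), 8L)
  expect_true(all(mapply(
    function(v, d) identical(emseg:::tta_invert(v, d), p2),
    e2$patches, e2$desc
  )))
  p3 <- array(runif(2 * 6 * 6), c(2, 6, 6))
  e3 <- tta_expand(p3)
  expect_length(e3$patches, 16L)
  expect_equal(length(unique(lapply(e3$patches, c))), 16L)
  expect_true(all(mapply(
    function(v, d) identical(emseg:::tta_invert(v, d), p3),
    e3$patches, e3$desc
  )))
  expect_error(tta_expand(matrix(0, 4, 6)), "square")
})

test_that("tta_collapse averages in probability space", {
  p <- matrix(runif(16), 4, 4)
  e <- tta_expand(p)
  # identical predictions under all transforms: mean of equals
  preds <- lapply(e$desc, function(d) emseg:::tta_apply(p, d))
  expect_equal(tta_collapse(preds, e$desc), p)
  # two hand-built 2x2 predictions with known inverses
  d2 <- list(list(rot = 0L, flip = FALSE), list(rot = 1L, flip = FALSE))
  pred_a <- matrix(c(1, 2, 3, 4), 2, 2)
  pred_b <- emseg:::tta_apply(matrix(c(5, 6, 7, 8), 2, 2), d2[[2]])
  out <- tta_collapse(list(pred_a, pred_b), d2)
  expect_equal(out, (matrix(c(1, 2, 3, 4), 2, 2) + matrix(c(5, 6, 7, 8), 2, 2)) / 2)
  expect_error(tta_collapse(list(pred_a), d2), "length")
})

test_that("predict_volume honours its policies", {
  v <- array(runif(4 * 32 * 32), c(4, 32, 32))
  pol <- recon_policy("overlap_50", patch_shape = c(4, 16, 16))
  # constant stub: constant volume under any policy
  expect_true(all(predict_volume(stub_constant(0.25), v, pol) == 0.25))
  # identity stub + flat overlap merge: original volume
  expect_equal(predict_volume(stub_identity, v, pol), v)
  # equivariant stub: TTA on and off agree
  pol_tta <- recon_policy("overlap_50", tta = TRUE, patch_shape = c(4, 16, 16))
  expect_equal(
    predict_volume(stub_identity, v, pol_tta),
    predict_volume(stub_identity, v, pol)
  )
  # full-image mode pads odd shapes to the model's divisibility and crops back
  m <- build_network(network_spec(2, c(3, 5)), seed = 1)
  img <- matrix(runif(30 * 34), 30, 34)
  out <- predict_volume(m, img, recon_policy("full_image"))
  expect_equal(dim(out), dim(img))
})

test_that("3D spline blending is refused unless forced", {
  v <- array(runif(8 * 16 * 16), c(8, 16, 16))
  pol <- recon_policy("overlap_50", blending = "spline", patch_shape = c(4, 8, 8))
  expect_error(predict_volume(stub_identity, v, pol), "force_blend_3d")
  pol$force_blend_3d <- TRUE
  expect_silent(predict_volume(stub_identity, v, pol))
  expect_error(recon_policy("full_image", blending = "spline"), "single tile")
})

test_that("spline blending beats mosaic on border-corrupting predictions", {
  set.seed(8)
  v <- matrix(runif(96 * 96), 96, 96)
  mosaic <- predict_volume(
    stub_border_corrupt, v,
    recon_policy("per_patch", patch_shape = c(32, 32))
  )
  blended <- predict_volume(
    stub_border_corrupt, v,
    recon_policy("overlap_50", blending = "spline", patch_shape = c(32, 32))
  )
  expect_lt(mean(abs(blended - v)), mean(abs(mosaic - v)))
})
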