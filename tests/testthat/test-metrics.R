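test_that("iou follows the confusion-count formulas", {
  a <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  b <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  r <- iou(a, b) # TP=1, FP=1, FN=0
  expect_equal(r$foreground, 1 / 2)
  expect_equal(r$background, 2 / 3)
  expect_equal(r$overall, 7 / 12)
  expect_equal(r$overall, (r$foreground + r$background) / 2)
  expect_equal(iou(a, a)$foreground, 1)
  expect_equal(iou(a, a)$overall, 1)
  disj <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(iou(a, disj)$foreground, 0)
  expect_error(iou(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("empty-union conventions hold", {
  z <- matrix(0, 3, 3)
  o <- matrix(1, 3, 3)
  expect_equal(iou(z, z)$foreground, 1) # both empty
  expect_equal(iou(o, z)$foreground, 0) # exactly one empty
  expect_equal(iou(o, o)$background, 1)
})

test_that("iou agrees with a brute-force per-voxel oracle", {
  set.seed(10)
  for (i in 1:10) {
    p <- array(rbinom(16^3, 1, runif(1, 0.1, 0.9)), c(16, 16, 16))
    t <- array(rbinom(16^3, 1, runif(1, 0.1, 0.9)), c(16, 16, 16))
    expect_equal(iou(p, t)$foreground, oracle_iou_fg(p, t))
    expect_equal(iou(p, t)$foreground, iou(t, p)$foreground) # symmetry
  }
})

test_that("flipping additional disagreeing voxels never raises foreground IoU", {
  set.seed(11)
  t <- array(rbinom(512, 1, 0.3), c(8, 8, 8))
  p <- t
  prev <- iou(p, t)$foreground
  idx <- sample(length(p))
  for (j in idx[1:40]) {
    p[j] <- 1 - p[j]
    cur <- iou(p, t)$foreground
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("perturbation tolerance matches hand morphology on a square", {
  sq <- array(0, c(1, 12, 12))
  sq[1, 5:8, 5:8] <- 1 # solid 4x4 square
  pt <- perturbation_tolerance(sq)
  expect_equal(pt$iou_eroded, 4 / 16) # 2x2 remains
  expect_equal(pt$iou_dilated, 16 / 36) # grows to 6x6
  # all-background: dilation changes nothing, empty-union convention gives 1
  blank <- array(0, c(1, 6, 6))
  expect_equal(perturbation_tolerance(blank)$iou_dilated, 1)
  # erosion to empty: warned, scored 0
  dot <- array(0, c(1, 6, 6))
  dot[1, 3, 3] <- 1
  expect_warning(pt2 <- perturbation_tolerance(dot), "all foreground")
  expect_equal(pt2$iou_eroded, 0)
})

test_that("in-plane morphology agrees with EBImage on 2D slices", {
  skip_if_not_installed("EBImage")
  set.seed(12)
  m <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  kern <- EBImage::makeBrush(3, "box")
  expect_equal(
    emseg:::binary_dilate(m, 1L),
    matrix(as.numeric(EBImage::dilate(m, kern)), 64, 64)
  )
  expect_equal(
    emseg:::binary_erode(m, 1L),
    matrix(as.numeric(EBImage::erode(m, kern)), 64, 64)
  )
})
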