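test_that("binarize applies the >= threshold rule", {
  expect_equal(binarize(array(0.5, c(2, 2))), array(1, c(2, 2)))
  lab <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
  expect_equal(binarize(lab), lab) # idempotent on 0/1 input
  probs <- matrix(c(0.2, 0.5, 0.8, 0.49), 2, 2)
  expect_equal(binarize(probs), (probs >= 0.5) * 1) # elementwise comparison
  expect_error(binarize(matrix(1.2, 2, 2)), "\\[0, 1\\]")
})

test_that("zfilter is a per-column majority vote with reflected edges", {
  const <- array(1, c(5, 4, 4))
  expect_equal(zfilter(const), const)
  v <- array(0, c(3, 1, 1))
  v[2, 1, 1] <- 1 # column pattern (0, 1, 0)
  f1 <- zfilter(v)
  expect_equal(f1[2, 1, 1], 0) # median of {0,1,0} removes the isolated slice
  expect_equal(zfilter(f1), f1) # stable on this example
  # unanimity: voxels whose whole window agrees never change
  set.seed(13)
  m <- array(rbinom(7 * 8 * 8, 1, 0.5), c(7, 8, 8))
  f <- zfilter(m)
  for (z in 2:6) {
    unan <- m[z - 1, , ] == m[z, , ] & m[z + 1, , ] == m[z, , ]
    expect_true(all(f[z, , ][unan] == m[z, , ][unan]))
  }
  expect_error(zfilter(m, 4), "odd")
  expect_error(zfilter(m, 15), "too large")
})

test_that("spurious_filter removes only sub-threshold components", {
  m <- array(0, c(1, 20, 20))
  m[1, 2:3, 2:3] <- 1 # 4-voxel blob (could also grow to 5)
  m[1, 2, 4] <- 1 # -> 5-voxel 8-connected component
  m[1, 8:17, 8:17] <- 1 # 100-voxel component
  out <- spurious_filter(m, min_area = 10)
  expect_equal(sum(out), 100)
  labs <- emseg:::.cc_label_cpp(as.vector(out > 0), dim(out), 26L)
  expect_equal(max(labs), 1L) # single surviving component
  expect_equal(spurious_filter(m, 0), m) # min_area 0 is the identity
  blank <- array(0, c(2, 5, 5))
  expect_equal(spurious_filter(blank, 10), blank)
  # never increases the component count
  set.seed(14)
  r <- array(rbinom(4 * 16 * 16, 1, 0.3), c(4, 16, 16))
  n0 <- max(emseg:::.cc_label_cpp(as.vector(r > 0), dim(r), 26L))
  out2 <- spurious_filter(r, 3)
  n1 <- max(emseg:::.cc_label_cpp(as.vector(out2 > 0), dim(out2), 26L))
  expect_lte(n1, n0)
})

test_that("connected components agree with EBImage labelling on 2D", {
  skip_if_not_installed("EBImage")
  set.seed(15)
  m <- matrix(rbinom(48 * 48, 1, 0.35), 48, 48)
  ours <- emseg:::.cc_label_cpp(as.vector(m > 0), c(1L, dim(m)), 4L)
  ref <- EBImage::bwlabel(m) # bwlabel uses 4-connectivity
  expect_equal(max(ours), max(ref))
  expect_equal(sort(tabulate(ours)), sort(tabulate(as.integer(ref))))
})

test_that("watershed refinement respects markers and improves noisy borders", {
  img <- matrix(0.8, 64, 64)
  disk <- ((row(img) - 32)^2 + (col(img) - 32)^2) <= 14^2
  img[disk] <- 0.2
  set.seed(16)
  img <- pmin(pmax(img + rnorm(length(img), 0, 0.03), 0), 1)
  truth <- disk * 1
  noisy <- emseg:::binary_dilate(truth, 2) # 2-pixel-dilated mask
  refined <- watershed_refine(img, noisy, erosion_radius = 2, dilation_radius = 5)
  markers <- emseg:::binary_erode(noisy, 2)
  expect_true(all(refined[markers > 0] == 1)) # refined mask contains markers
  envelope <- emseg:::binary_dilate(noisy, 5)
  expect_true(all(refined[envelope == 0] == 0)) # and stays inside the envelope
  expect_gt(iou(refined, truth)$foreground, iou(noisy, truth)$foreground)
  # empty mask: warning, empty output
  expect_warning(out <- watershed_refine(img, matrix(0, 64, 64)), "empty")
  expect_true(all(out == 0))
  # erosion annihilating the markers returns the input
  dot <- matrix(0, 64, 64)
  dot[30:31, 30:31] <- 1
  expect_warning(out2 <- watershed_refine(img, dot, erosion_radius = 3), "annihilated")
  expect_equal(out2, dot)
})

test_that("run_chain composes steps and logs them", {
  fx <- tiny_fixture()
  prob <- fx$labels # a perfect probability map
  only_bin <- run_chain(prob, fx$image, postproc_chain(list("binarize")))
  expect_equal(only_bin$mask, binarize(prob))
  # conservative parameters leave a clean mask untouched
  cons <- run_chain(prob, fx$image, postproc_chain(list(
    "binarize", list(step = "spurious", min_area = 10)
  )))
  expect_equal(cons$mask, fx$labels)
  expect_equal(cons$log$voxels_changed[2], 0L)
  expect_error(
    postproc_chain(list("spurious", "binarize")),
    "first step"
  )
  expect_error(postproc_chain(list("frobnicate")), "unknown step")
})

test_that("the full chain improves corrupted predictions over binarize-only", {
  fx <- tiny_fixture()
  pr <- corrupt_labels(fx$labels,
    flip_rate = 0.01, border_jitter = 0.2,
    spurious_blobs = 3, seed = 9
  )
  base <- iou(binarize(pr), fx$labels)$foreground
  chain <- postproc_chain(list(
    "binarize",
    list(step = "spurious", min_area = 20),
    list(step = "watershed", erosion_radius = 1, dilation_radius = 3),
    list(step = "zfilter", window = 3)
  ))
  res <- run_chain(pr, fx$image, chain, truth = fx$labels)
  expect_gte(tail(res$log$iou_foreground, 1), base)
})
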