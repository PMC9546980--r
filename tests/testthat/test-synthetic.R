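test_that("fixture generation is deterministic and well-formed", {
  sp <- fixture_spec(shape = c(8, 48, 48), n_organelles = 3, seed = 21)
  a <- make_volume(sp)
  b <- make_volume(sp)
  expect_identical(a, b)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$labels %in% c(0, 1)))
  none <- make_volume(fixture_spec(shape = c(8, 48, 48), n_organelles = 0, seed = 1))
  expect_equal(sum(none$labels), 0)
  expect_error(fixture_spec(shape = c(4, 16, 16)), "minimum")
})

test_that("foreground volume matches the analytic ellipsoid volume", {
  # degenerate semi-axis range -> every organelle has the same known size
  sp <- fixture_spec(
    shape = c(24, 160, 160), n_organelles = 10,
    semi_axes = c(8, 8), seed = 31
  )
  fx <- make_volume(sp)
  # in-plane semi-axes a = b = 8, axial = 8 (isotropic): V = 4/3 pi 8^3 each
  expected <- 10 * 4 / 3 * pi * 8^3 / prod(sp$shape)
  got <- mean(fx$labels)
  expect_gt(got, expected * 0.75) # voxelisation/overlap tolerance
  expect_lt(got, expected * 1.25)
})

test_that("overcrowding places fewer organelles with a warning", {
  sp <- fixture_spec(
    shape = c(8, 32, 32), n_organelles = 60,
    semi_axes = c(8, 10), seed = 41
  )
  expect_warning(fx <- make_volume(sp), "placed")
  expect_gt(sum(fx$labels), 0)
})

test_that("fixtures are separable by a plain intensity baseline", {
  fx <- tiny_fixture()
  base <- threshold_baseline(fx$image)
  expect_gt(iou(base, fx$labels)$foreground, 0.5)
})

test_that("corrupt_labels degrades gracefully and controllably", {
  fx <- make_volume(fixture_spec(shape = c(8, 48, 48), n_organelles = 4, seed = 51))
  clean <- corrupt_labels(fx$labels,
    flip_rate = 0, border_jitter = 0,
    spurious_blobs = 0, soften = 0, seed = 1
  )
  expect_equal(clean, fx$labels) # all rates zero: exact labels
  # flip count is Binomial(N, rate)
  rate <- 0.01
  p <- corrupt_labels(fx$labels,
    flip_rate = rate, border_jitter = 0,
    spurious_blobs = 0, soften = 0, seed = 7
  )
  n_flipped <- sum(abs(p - fx$labels) > 0.5)
  n <- length(p)
  expect_gt(n_flipped, rate * n - 4 * sqrt(n * rate * (1 - rate)))
  expect_lt(n_flipped, rate * n + 4 * sqrt(n * rate * (1 - rate)))
  # more flipping -> strictly worse IoU (Monte-Carlo over seeds)
  mean_iou <- function(r) {
    mean(vapply(1:20, function(s) {
      pp <- corrupt_labels(fx$labels,
        flip_rate = r, border_jitter = 0,
        spurious_blobs = 0, soften = 0, seed = s
      )
      iou(binarize(pp), fx$labels)$foreground
    }, 0))
  }
  m1 <- mean_iou(0.005)
  m2 <- mean_iou(0.02)
  m3 <- mean_iou(0.08)
  expect_gt(m1, m2)
  expect_gt(m2, m3)
})

test_that("fixture directories round-trip through TIFF stacks", {
  dir <- withr::local_tempdir()
  write_fixture_dir(
    dir,
    fixture_spec(shape = c(8, 32, 32), n_organelles = 2, seed = 61),
    fixture_spec(shape = c(8, 32, 32), n_organelles = 2, seed = 62)
  )
  vol <- read_volume(file.path(dir, "train/x/stack.tif"))
  expect_equal(dim(vol), c(8L, 32L, 32L))
  lab <- read_volume(file.path(dir, "train/y/stack.tif"))
  ref <- make_volume(fixture_spec(shape = c(8, 32, 32), n_organelles = 2, seed = 61))
  expect_equal(binarize(lab), ref$labels) # labels survive 8-bit exactly
  # probabilities survive 32-bit float to within single precision
  pv <- withr::local_tempfile(fileext = ".tif")
  write_volume(ref$image, pv, bits = 32L)
  expect_lt(max(abs(read_volume(pv) - ref$image)), 1e-6)
})
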