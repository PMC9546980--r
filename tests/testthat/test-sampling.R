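test_that("systematic grids enumerate the expected boxes", {
  expect_equal(nrow(systematic_grid(c(512, 512), c(256, 256), 0)$starts), 4L)
  # position-enumeration oracle: ceil((512-256)/128)+1 = 3 per axis
  n_pos <- function(L, P, s) length(seq.int(0L, L - P, by = s)) + as.integer((L - P) %% s != 0)
  expect_equal(
    nrow(systematic_grid(c(512, 512), c(256, 256), 0.5)$starts),
    n_pos(512, 256, 128)^2
  )
  g <- systematic_grid(c(300, 300), c(256, 256), 0)
  expect_equal(nrow(g$starts), 4L)
  expect_true(all(g$starts + rep(g$patch_shape, each = 4) <= rep(c(300, 300), each = 4)))
  expect_equal(max(g$starts[, 1L]) + 256L, 300L) # last box shifted to the border
  expect_error(systematic_grid(c(64, 64), c(32, 32), 1), "overlap")
  expect_error(systematic_grid(c(16, 16), c(32, 32), 0), "exceeds")
})

test_that("every voxel is covered and 50%-overlap interiors are covered 2^nd times", {
  v <- array(seq_len(64 * 64), c(64, 64))
  g <- systematic_grid(dim(v), c(32, 32), 0.5, pad = "reflect")
  cover <- array(0, g$padded_shape)
  for (i in seq_len(nrow(g$starts))) {
    s <- g$starts[i, ]
    cover[(s[1] + 1):(s[1] + 32), (s[2] + 1):(s[2] + 32)] <-
      cover[(s[1] + 1):(s[1] + 32), (s[2] + 1):(s[2] + 32)] + 1
  }
  expect_true(all(cover >= 1))
  expect_equal(cover[32, 32], 4) # interior voxel
})

test_that("probability map balances classes and degrades to uniform", {
  lab <- array(0, c(4, 4, 4))
  pm <- probability_map(lab)
  expect_true(all(abs(pm - 1 / 64) < 1e-15))
  lab[1, 1, 1] <- 1
  pm <- probability_map(lab)
  expect_equal(sum(pm), 1)
  # direct normalization oracle: w_f = n_bg / n_fg, weight = w_f / (w_f + n_bg)
  w <- 63 / 1
  expect_equal(pm[1, 1, 1], w / (w + 63))
  expect_true(min(pm[lab > 0]) >= max(pm[lab == 0]))
  expect_error(probability_map(numeric(0)), "empty")
})

test_that("probability map is permutation-equivariant", {
  set.seed(3)
  lab <- array(rbinom(64, 1, 0.2), c(4, 4, 4))
  pm <- probability_map(lab)
  perm <- sample(64)
  expect_equal(as.vector(probability_map(array(lab[perm], dim(lab)))), as.vector(pm)[perm])
})

test_that("random patch sampling is reproducible and foreground-seeking", {
  img <- matrix(runif(128 * 128), 128, 128)
  lab <- matrix(0, 128, 128)
  lab[49:80, 49:80] <- 1 # one 32x32 foreground square
  cfg <- sample_config(patches_per_image = 200L, seed = 11L)
  a <- random_patches(img, lab, c(16, 16), cfg)
  b <- random_patches(img, lab, c(16, 16), cfg)
  expect_identical(a, b)
  # centres should fall inside the square far more often than its area share
  centre_in <- vapply(a, function(s) {
    ctr <- s$start + 8L
    ctr[1] >= 48 && ctr[1] < 80 && ctr[2] >= 48 && ctr[2] < 80
  }, TRUE)
  area_share <- mean(lab)
  expect_gt(mean(centre_in), 3 * area_share)
})

test_that("foreground-fraction filter keeps only foreground-rich patches", {
  img <- matrix(0.5, 64, 64)
  lab <- matrix(0, 64, 64)
  lab[17:48, 17:48] <- 1
  cfg <- sample_config(patches_per_image = 10L, seed = 2L)
  cfg$foreground_min_fraction <- 1.0
  out <- random_patches(img, lab, c(8, 8), cfg)
  expect_true(all(vapply(out, function(s) all(s$labels == 1), TRUE)))
  # unattainable constraint falls back with a warning
  lab0 <- matrix(0, 64, 64)
  expect_warning(
    random_patches(img, lab0, c(8, 8), cfg),
    "unattainable"
  )
})

test_that("train/validation split follows the rounding and mode rules", {
  sp <- split_train_val(165, sample_config(val_mode = "consecutive"))
  expect_equal(length(sp$val), 17L) # round-half-up of 16.5
  expect_equal(sp$val, 149:165) # trailing block
  expect_equal(length(split_train_val(10, sample_config())$val), 1L)
  s1 <- split_train_val(50, sample_config(seed = 5))
  s2 <- split_train_val(50, sample_config(seed = 5))
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$val), 0)
})

test_that("augmentation transforms are involutive where they should be", {
  img <- matrix(runif(64), 8, 8)
  lab <- matrix(rbinom(64, 1, 0.4), 8, 8)
  f <- emseg:::flip_axis
  expect_identical(f(f(img, 1), 1), img)
  r <- emseg:::rot90_yx
  expect_identical(r(r(r(r(img)))), img)
  a <- augment(img, lab,
    rot90s = FALSE, flips = FALSE, elastic = TRUE,
    elastic_alpha = 0, seed = 1
  )
  expect_equal(a$image, img) # zero-amplitude elastic is the identity
  a2 <- augment(img, lab, elastic = TRUE, elastic_alpha = 4, seed = 9)
  expect_true(all(a2$labels %in% c(0, 1)))
  expect_identical(
    augment(img, lab, seed = 3),
    augment(img, lab, seed = 3)
  )
})
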