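test_that("presets encode the tuned configurations", {
  expect_equal(preset_spec("unet3d")$filters, c(28L, 36L, 48L, 64L))
  expect_equal(preset_spec("residual3d")$filters, c(28L, 36L, 48L, 64L, 80L))
  u2 <- preset_spec("unet2d")
  expect_equal(u2$filters, c(16L, 32L, 64L, 128L, 256L))
  expect_equal(u2$block_kind, "conv")
  expect_false(u2$attention_gates)
  expect_equal(u2$dropout, c(0.1, 0.1, 0.2, 0.2, 0.3))
  expect_equal(u2$activation, "ELU")
  expect_equal(preset_spec("se2d")$se_mode, "all_but_bottleneck")
  expect_true(all(!preset_spec("unet3d_aniso")$z_down))
  expect_error(preset_spec("nope"), "unet2d")
})

test_that("spec validation rejects malformed configurations", {
  expect_error(network_spec(2, c(4)), "at least 2")
  expect_error(network_spec(4, c(4, 8)), "ndim")
  expect_error(network_spec(2, c(4, 8), dropout = c(0.5, 1.0)), "\\[0, 1\\)")
  expect_error(network_spec(2, c(4, 8), dropout = c(0.1, 0.1, 0.1)), "one rate per")
})

test_that("specs survive a YAML round trip", {
  spec <- preset_spec("attention3d_aniso")
  f <- withr::local_tempfile(fileext = ".yml")
  spec_to_yaml(spec, f)
  expect_equal(spec_from_yaml(f), spec)
})

test_that("same spec and seed give bit-identical models", {
  spec <- network_spec(2, c(4, 8))
  a <- build_network(spec, seed = 7)
  b <- build_network(spec, seed = 7)
  expect_identical(a$params, b$params)
  c <- build_network(spec, seed = 8)
  expect_false(identical(a$params, c$params))
})

test_that("forward pass preserves spatial shape and stays in [0, 1]", {
  m2 <- build_network(network_spec(2, c(4, 8)), seed = 1)
  p <- predict_patch(m2, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(p), c(32L, 32L))
  expect_true(all(p >= 0 & p <= 1))
  m3 <- build_network(network_spec(3, c(3, 5)), seed = 1)
  p3 <- predict_patch(m3, array(runif(8 * 16 * 16), c(8, 16, 16)))
  expect_equal(dim(p3), c(8L, 16L, 16L))
  # anisotropic net never downsamples Z: odd depth is fine
  ma <- build_network(network_spec(3, c(3, 5), z_down = FALSE), seed = 1)
  pa <- predict_patch(ma, array(runif(5 * 16 * 16), c(5, 16, 16)))
  expect_equal(dim(pa), c(5L, 16L, 16L))
})

test_that("indivisible patch shapes raise an informative error", {
  m <- build_network(network_spec(2, c(4, 8, 16)), seed = 1) # 4x downsampling
  expect_error(predict_patch(m, matrix(0, 30, 32)), "divisible")
})

test_that("a zero-weight network outputs sigmoid(0) = 0.5 everywhere", {
  m <- build_network(network_spec(2, c(4, 8)), seed = 1)
  for (nm in names(m$params)) m$params[[nm]][] <- 0
  p <- predict_patch(m, matrix(runif(16 * 16), 16, 16))
  expect_true(all(abs(p - 0.5) < 1e-12))
})

test_that("parameter counts match independent layer-shape enumeration", {
  m <- build_network(network_spec(2, c(2, 4), dropout = 0), seed = 1)
  rep_ <- count_parameters(m)
  expect_equal(rep_$total_trainable, oracle_count_2level_2d(2, 4))
  expect_equal(rep_$total_trainable, sum(rep_$per_layer$count))
  expect_equal(
    count_parameters(build_network("unet3d", seed = 3))$total_trainable,
    oracle_count_unet3d()
  )
})

test_that("counts are seed-invariant and ordered across variants", {
  c_of <- function(nm, s = 1) count_parameters(build_network(nm, seed = s))$total_trainable
  expect_identical(c_of("unet2d", 1), c_of("unet2d", 99))
  expect_gt(c_of("residual2d"), c_of("unet2d")) # projection shortcuts
  expect_gt(c_of("attention2d"), c_of("unet2d")) # gate projections
  expect_gt(c_of("se2d"), c_of("unet2d")) # gating layers
})

test_that("doubling all filters roughly quadruples the parameter count", {
  base <- network_spec(2, c(16L, 32L, 64L, 128L, 256L), dropout = 0.1)
  dbl <- network_spec(2, 2L * base$filters, dropout = 0.1)
  r <- count_parameters(build_network(dbl, 1))$total_trainable /
    count_parameters(build_network(base, 1))$total_trainable
  expect_gte(r, 3.5)
  expect_lte(r, 4.0)
})

test_that("millions rounding is half-up to two decimals", {
  m <- build_network(network_spec(2, c(2, 4)), seed = 1)
  rep_ <- count_parameters(m)
  expect_equal(rep_$millions, floor(rep_$total_trainable / 1e6 * 100 + 0.5) / 100)
})

test_that("training-only features do not change the eval-mode forward pass", {
  # dropout active only during training; batch norm uses running stats at eval
  m <- build_network(network_spec(2, c(3, 5), dropout = 0.3), seed = 2)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(predict_patch(m, x), predict_patch(m, x))
})
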