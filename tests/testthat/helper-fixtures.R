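# Shared helpers: tiny fixtures and independent oracles used across tests.

# independent hand enumeration of every layer's weight shapes for a
# two-level 2D conv U-Net with filters (f1, f2): the oracle for parameter
# counting (kernel 3x3, transposed conv 2x2, biases everywhere, 1x1 head)
oracle_count_2level_2d <- function(f1, f2) {
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  conv(3, 1, f1) + conv(3, f1, f1) + # encoder block
    conv(3, f1, f2) + conv(3, f2, f2) + # bottleneck block
    (2 * 2 * f2 * f1 + f1) + # transposed conv
    conv(3, 2 * f1, f1) + conv(3, f1, f1) + # decoder block
    conv(1, f1, 1) # head
}

# independent enumeration of the 3D U-Net preset (filters 28/36/48/64):
# three encoder levels, bottleneck, mirrored decoder, 3x3x3 kernels
oracle_count_unet3d <- function() {
  conv <- function(k, cin, cout) k^3 * cin * cout + cout
  up <- function(cin, cout) 8 * cin * cout + cout
  f <- c(28, 36, 48, 64)
  total <- conv(3, 1, f[1]) + conv(3, f[1], f[1])
  for (l in 2:3) total <- total + conv(3, f[l - 1], f[l]) + conv(3, f[l], f[l])
  total <- total + conv(3, f[3], f[4]) + conv(3, f[4], f[4])
  for (l in 3:1) {
    total <- total + up(f[l + 1], f[l]) +
      conv(3, 2 * f[l], f[l]) + conv(3, f[l], f[l])
  }
  total + (f[1] * 1 + 1)
}

# brute-force per-voxel confusion oracle (independent of confusion_counts)
oracle_iou_fg <- function(pred, truth) {
  tp <- 0L
  fp <- 0L
  fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] > 0
    t <- truth[i] > 0
    if (p && t) tp <- tp + 1L
    if (p && !t) fp <- fp + 1L
    if (!p && t) fn <- fn + 1L
  }
  if (tp + fp + fn == 0L) 1 else tp / (tp + fp + fn)
}

# small clean fixture volume shared by several tests
tiny_fixture <- function(seed = 5L) {
  make_volume(fixture_spec(shape = c(10L, 96L, 96L), n_organelles = 6L, seed = seed))
}

# stub "model": a plain function patch -> probabilities
stub_constant <- function(value) function(patch) array(value, dim(patch))
stub_identity <- function(patch) patch

# stub that corrupts a 2-pixel border of every patch it sees (the jagged
# tiling artefact)
stub_border_corrupt <- function(patch) {
  out <- patch
  d <- dim(patch)
  b <- 2L
  out[c(seq_len(b), d[1L] - seq_len(b) + 1L), ] <- 1
  out[, c(seq_len(b), d[2L] - seq_len(b) + 1L)] <- 1
  out
}
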