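# Binary and grayscale morphology with box (square/cube) structuring elements.
# Box elements are separable, so an r-radius filter is a sequence of 1D
# moving-window passes along each axis. Voxels outside the volume count as
# background (0): objects touching the border erode there, the standard
# zero-boundary convention.

# moving window OR / AND along one axis of a 2D or 3D array
.axis_window <- function(x, axis, radius, op = c("max", "min")) {
  op <- match.arg(op)
  d <- dim(x)
  out <- x
  pad_val <- if (op == "max") 0 else 1
  for (off in seq.int(-radius, radius)) {
    if (off == 0L) next
    shifted <- array(pad_val, d)
    n <- d[axis]
    src <- seq.int(max(1L, 1L - off), min(n, n - off))
    dst <- src + off
    idx_src <- lapply(seq_along(d), function(a) if (a == axis) src else seq_len(d[a]))
    idx_dst <- lapply(seq_along(d), function(a) if (a == axis) dst else seq_len(d[a]))
    slab <- do.call(`[`, c(list(x), idx_src, list(drop = FALSE)))
    shifted <- do.call(`[<-`, c(list(shifted), idx_dst, list(value = slab)))
    out <- if (op == "max") pmax(out, shifted) else pmin(out, shifted)
  }
  out
}

# axes: which axes of the array the box extends over (e.g. 2:3 of a (Z,Y,X)
# volume for per-slice in-plane morphology)
morph_box <- function(x, radius, axes, op) {
  for (a in axes) x <- .axis_window(x, a, radius, op)
  x
}

binary_dilate <- function(mask, radius = 1L, axes = NULL) {
  m <- (mask > 0) * 1
  dim(m) <- dim(mask)
  if (is.null(axes)) axes <- seq_along(dim(m))
  morph_box(m, radius, axes, "max")
}

binary_erode <- function(mask, radius = 1L, axes = NULL) {
  m <- (mask > 0) * 1
  dim(m) <- dim(mask)
  if (is.null(axes)) axes <- seq_along(dim(m))
  morph_box(m, radius, axes, "min")
}

# grayscale morphological gradient (dilation - erosion, 3-wide box): the
# relief flooded by the marker-controlled watershed
morph_gradient <- function(image, axes = NULL) {
  if (is.null(axes)) axes <- seq_along(dim(image))
  morph_box(image, 1L, axes, "max") - morph_box(image, 1L, axes, "min")
}

# Otsu's threshold on a numeric array (256-bin histogram); used to show the
# synthetic fixtures are separable by intensity alone
otsu_threshold <- function(x) {
  h <- tabulate(pmin(256L, pmax(1L, as.integer(x * 255) + 1L)), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 0.5) / 255
}
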