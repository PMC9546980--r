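# Patch extraction: systematic grids, probability-map-driven random sampling,
# train/validation splitting and geometric augmentation.
# All coordinates are 0-based, boxes half-open, axis order (Z,)Y,X.

#' Systematic patch grid over a volume
#'
#' Covers every voxel with full-sized patches at a stated overlap. The stride
#' is `round(patch_shape * (1 - overlap))`; with `overlap = 0.5` it is half
#' the patch shape, so interior voxels are covered `2^ndim` times. The last
#' box per axis is either shifted inward to end exactly at the volume border
#' (`pad = "shift"`, used for sampling) or the volume is reflect-padded so
#' the stride divides evenly (`pad = "reflect"`, used for inference so
#' blending windows apply cleanly).
#'
#' @param volume_shape,patch_shape Integer vectors of equal length (2 or 3).
#' @param overlap Fraction in `[0, 1)`, per axis (scalar recycled).
#' @param pad `"shift"` or `"reflect"`.
#' @return A `patch_grid`: list with `starts` (n x ndim matrix of 0-based
#'   box origins in the (possibly padded) volume), `patch_shape`,
#'   `volume_shape`, `padded_shape`, `overlap`, `pad`. Boxes are ordered
#'   lexicographically by axis.
#' @export
#' @examples
#' nrow(systematic_grid(c(512, 512), c(256, 256), 0.5)$starts) # 9
systematic_grid <- function(volume_shape, patch_shape, overlap = 0,
                            pad = c("shift", "reflect")) {
  pad <- match.arg(pad)
  volume_shape <- as.integer(volume_shape)
  patch_shape <- as.integer(patch_shape)
  nd <- length(volume_shape)
  stopifnot(length(patch_shape) == nd)
  overlap <- rep_len(overlap, nd)
  if (any(overlap < 0 | overlap >= 1)) stop("overlap must lie in [0, 1)")
  stride <- pmax(1L, as.integer(round(patch_shape * (1 - overlap))))

  padded <- volume_shape
  axis_starts <- vector("list", nd)
  for (a in seq_len(nd)) {
    L <- volume_shape[a]
    P <- patch_shape[a]
    s <- stride[a]
    if (pad == "shift") {
      if (P > L) stop("patch_shape exceeds volume_shape on axis ", a, " (pad = 'shift')")
      pos <- seq.int(0L, max(0L, L - P), by = s)
      if (pos[length(pos)] != L - P) pos <- c(pos, L - P)
    } else {
      Lp <- if (L <= P) P else P + s * ceiling((L - P) / s)
      padded[a] <- Lp
      pos <- seq.int(0L, Lp - P, by = s)
    }
    axis_starts[[a]] <- as.integer(pos)
  }
  g <- expand.grid(rev(axis_starts), KEEP.OUT.ATTRS = FALSE)
  starts <- as.matrix(g[, rev(seq_len(nd)), drop = FALSE])
  ord <- do.call(order, as.data.frame(starts))
  starts <- starts[ord, , drop = FALSE]
  dimnames(starts) <- NULL
  structure(
    list(
      starts = starts, patch_shape = patch_shape, volume_shape = volume_shape,
      padded_shape = padded, overlap = overlap, pad = pad
    ),
    class = "patch_grid"
  )
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf(
    "<patch_grid> %d boxes of %s over %s (overlap %s, pad %s)\n",
    nrow(x$starts), paste(x$patch_shape, collapse = "x"),
    paste(x$volume_shape, collapse = "x"),
    paste(x$overlap, collapse = "/"), x$pad
  ))
  invisible(x)
}

# reflect-pad (symmetric, edge included) up to `target` along each axis
pad_reflect_to <- function(x, target) {
  d <- dim(x)
  for (a in seq_along(d)) {
    extra <- target[a] - d[a]
    if (extra <= 0) next
    n <- d[a]
    mirror <- seq.int(n, n - extra + 1L)
    if (extra > n) stop("reflect padding larger than the axis itself")
    idx <- c(seq_len(n), mirror)
    args <- lapply(seq_along(d), function(b) if (b == a) idx else seq_len(d[b]))
    x <- do.call(`[`, c(list(x), args, list(drop = FALSE)))
    d <- dim(x)
  }
  x
}

#' Extract the patches of a grid from a volume
#'
#' @param volume Array matching the grid's `volume_shape`.
#' @param grid A [systematic_grid()].
#' @return List of patch arrays, one per grid box.
#' @export
extract_patches <- function(volume, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  if (!identical(as.integer(dim(volume)), grid$volume_shape)) {
    stop("volume shape does not match grid")
  }
  v <- pad_reflect_to(volume, grid$padded_shape)
  ps <- grid$patch_shape
  lapply(seq_len(nrow(grid$starts)), function(i) {
    s <- grid$starts[i, ]
    idx <- lapply(seq_along(ps), function(a) seq.int(s[a] + 1L, s[a] + ps[a]))
    do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  })
}

#' Voxel-weight field for class-balanced patch-centre sampling
#'
#' Foreground voxels receive a common weight chosen so that the total
#' foreground mass equals `fg_mass` (default 0.5: a sampled patch centre is
#' equally likely to be a mitochondrion voxel as a background voxel, however
#' rare the class); background voxels weigh 1 before normalisation. The map
#' sums to 1. With no foreground at all it degrades to the uniform map.
#'
#' @param labels Binary array.
#' @param fg_mass Total probability mass assigned to foreground voxels.
#' @return Numeric array of the same shape, summing to 1.
#' @export
probability_map <- function(labels, fg_mass = 0.5) {
  if (length(labels) == 0L) stop("empty label volume")
  lab <- as.vector(labels) > 0
  n_fg <- sum(lab)
  w <- rep(1, length(lab))
  if (n_fg > 0L && n_fg < length(lab)) {
    n_bg <- length(lab) - n_fg
    w[lab] <- (fg_mass / (1 - fg_mass)) * n_bg / n_fg
  }
  w <- w / sum(w)
  dim(w) <- dim(labels) %||% length(labels)
  w
}

#' Sampling configuration
#'
#' @param mode `"random"` (probability-map-driven centres) or `"systematic"`.
#' @param patches_per_image Patches drawn per image/volume.
#' @param foreground_min_fraction Patches with a smaller foreground fraction
#'   are rejected and redrawn (0 disables discarding; 0.005 is a sensible
#'   value when enabling it).
#' @param use_probability_map Draw centres from [probability_map()] instead of
#'   uniformly.
#' @param val_fraction Fraction of training images held out for validation.
#' @param val_mode `"random"` or `"consecutive"` (trailing block).
#' @param seed RNG seed for sampling and splitting.
#' @return A `sample_config` list.
#' @export
sample_config <- function(mode = c("random", "systematic"), patches_per_image = 2L,
                          foreground_min_fraction = 0,
                          use_probability_map = TRUE,
                          val_fraction = 0.1, val_mode = c("random", "consecutive"),
                          seed = 42L) {
  mode <- match.arg(mode)
  val_mode <- match.arg(val_mode)
  stopifnot(patches_per_image >= 1L, val_fraction > 0, val_fraction < 1)
  structure(
    list(
      mode = mode, patches_per_image = as.integer(patches_per_image),
      foreground_min_fraction = foreground_min_fraction,
      use_probability_map = isTRUE(use_probability_map),
      val_fraction = val_fraction, val_mode = val_mode, seed = as.integer(seed)
    ),
    class = "sample_config"
  )
}

# centre voxel -> clamped 0-based box start
.centre_to_start <- function(centre0, patch_shape, volume_shape) {
  s <- centre0 - patch_shape %/% 2L
  pmin(pmax(s, 0L), volume_shape - patch_shape)
}

#' Draw random training patches
#'
#' Draws `cfg$patches_per_image` patch centres from the label probability map
#' (or uniformly), clamps the boxes inside the volume, and rejects patches
#' whose foreground fraction falls below `cfg$foreground_min_fraction`
#' (bounded retries; if the constraint is unattainable the constraint is
#' dropped with a warning). Fully reproducible for a fixed `cfg$seed`.
#'
#' @param volume,labels Arrays of identical shape (2D image or 3D volume).
#' @param patch_shape Integer vector, same length as `dim(volume)`.
#' @param cfg A [sample_config()].
#' @return List of samples, each `list(image, labels, start)` with `start`
#'   the 0-based box origin.
#' @export
random_patches <- function(volume, labels, patch_shape, cfg = sample_config()) {
  stopifnot(identical(dim(volume), dim(labels)))
  vs <- as.integer(dim(volume))
  patch_shape <- as.integer(rep_len(patch_shape, length(vs)))
  if (any(patch_shape > vs)) stop("patch_shape exceeds volume shape")
  pmap <- if (cfg$use_probability_map) as.vector(probability_map(labels)) else NULL
  nd <- length(vs)
  n <- cfg$patches_per_image
  max_tries <- 50L * n
  out <- vector("list", n)
  withr::with_seed(cfg$seed, {
    got <- 0L
    tries <- 0L
    min_frac <- cfg$foreground_min_fraction
    warned <- FALSE
    while (got < n) {
      tries <- tries + 1L
      if (tries > max_tries && min_frac > 0) {
        warning("foreground_min_fraction unattainable; falling back to unconstrained sampling")
        min_frac <- 0
        warned <- TRUE
        tries <- 0L
      }
      v <- if (is.null(pmap)) {
        sample.int(prod(vs), 1L)
      } else {
        sample.int(prod(vs), 1L, prob = pmap)
      }
      centre <- as.integer(arrayInd(v, vs)) - 1L
      s <- .centre_to_start(centre, patch_shape, vs)
      idx <- lapply(seq_len(nd), function(a) seq.int(s[a] + 1L, s[a] + patch_shape[a]))
      lab <- do.call(`[`, c(list(labels), idx, list(drop = FALSE)))
      if (mean(lab > 0) < min_frac) next
      img <- do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
      got <- got + 1L
      out[[got]] <- list(image = img, labels = lab, start = s)
    }
  })
  out
}

#' Split slice indices into training and validation sets
#'
#' The validation size is `round(val_fraction * n)` with half-up rounding and
#' a minimum of 1. Random mode draws the validation slices with the config
#' seed; consecutive mode takes the trailing block of slices.
#'
#' @param n_slices Number of slices (or a vector whose length is used).
#' @param cfg A [sample_config()] (uses `val_fraction`, `val_mode`, `seed`).
#' @return List with integer vectors `train` and `val` (1-based, disjoint).
#' @export
#' @examples
#' lengths(split_train_val(165, sample_config(val_mode = "consecutive")))
split_train_val <- function(n_slices, cfg = sample_config()) {
  n <- if (length(n_slices) > 1L) length(n_slices) else as.integer(n_slices)
  if (n < 2L) stop("need at least 2 slices to split")
  n_val <- max(1L, as.integer(floor(cfg$val_fraction * n + 0.5)))
  if (n_val >= n) stop("val_fraction leaves no training slices")
  if (cfg$val_mode == "consecutive") {
    val <- seq.int(n - n_val + 1L, n)
  } else {
    val <- sort(withr::with_seed(cfg$seed, sample.int(n, n_val)))
  }
  list(train = setdiff(seq_len(n), val), val = val)
}

# --- geometric augmentation ------------------------------------------------

# k quarter-turns in the (Y,X) plane of a 2D matrix or (Z,Y,X) volume
rot90_yx <- function(x, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) {
    return(x)
  }
  nd <- length(dim(x))
  for (i in seq_len(k)) {
    if (nd == 2L) {
      x <- t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
    } else {
      x <- aperm(x, c(1L, 3L, 2L))
      x <- x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
    }
  }
  x
}

flip_axis <- function(x, axis) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(a) if (a == axis) rev(seq_len(d[a])) else seq_len(d[a]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# smooth random displacement field: iid normal control points on a coarse
# grid, bilinearly upsampled; returns (H,W) fields dy, dx
.elastic_field <- function(hw, alpha, grid_spacing) {
  nc <- pmax(2L, ceiling(hw / grid_spacing) + 1L)
  coarse <- function() matrix(rnorm(prod(nc), 0, alpha), nc[1L], nc[2L])
  up <- function(cm) {
    ys <- seq(1, nc[1L], length.out = hw[1L])
    xs <- seq(1, nc[2L], length.out = hw[2L])
    y0 <- pmin(floor(ys), nc[1L] - 1L)
    x0 <- pmin(floor(xs), nc[2L] - 1L)
    fy <- ys - y0
    fx <- xs - x0
    a <- cm[cbind(rep(y0, length(x0)), rep(x0, each = length(y0)))]
    b <- cm[cbind(rep(y0 + 1L, length(x0)), rep(x0, each = length(y0)))]
    cc <- cm[cbind(rep(y0, length(x0)), rep(x0 + 1L, each = length(y0)))]
    d <- cm[cbind(rep(y0 + 1L, length(x0)), rep(x0 + 1L, each = length(y0)))]
    wy <- rep(fy, length(x0))
    wx <- rep(fx, each = length(y0))
    matrix((1 - wy) * (1 - wx) * a + wy * (1 - wx) * b + (1 - wy) * wx * cc + wy * wx * d,
      hw[1L], hw[2L]
    )
  }
  list(dy = up(coarse()), dx = up(coarse()))
}

# warp one (Y,X) plane by the displacement field; bilinear for images,
# nearest-neighbour for labels so masks stay binary
.warp_plane <- function(m, dy, dx, nearest = FALSE) {
  h <- nrow(m)
  w <- ncol(m)
  ys <- as.vector(pmin(pmax(row(m) + dy, 1), h))
  xs <- as.vector(pmin(pmax(col(m) + dx, 1), w))
  if (nearest) {
    return(matrix(m[cbind(round(ys), round(xs))], h, w))
  }
  y0 <- pmin(floor(ys), h - 1)
  x0 <- pmin(floor(xs), w - 1)
  fy <- ys - y0
  fx <- xs - x0
  v <- (1 - fy) * (1 - fx) * m[cbind(y0, x0)] +
    fy * (1 - fx) * m[cbind(y0 + 1, x0)] +
    (1 - fy) * fx * m[cbind(y0, x0 + 1)] +
    fy * fx * m[cbind(y0 + 1, x0 + 1)]
  matrix(v, h, w)
}

#' Jointly augment an image/label patch pair
#'
#' Applies an identical geometric transform to image and labels: a random
#' number of right-angle rotations in the (Y,X) plane, random vertical and
#' horizontal flips, and (optionally, used for 3D training) an elastic
#' deformation built from a coarse grid of normal displacements bilinearly
#' upsampled to the patch — nearest-neighbour warping keeps labels binary.
#'
#' @param image,labels Patch pair, 2D `(Y,X)` or 3D `(Z,Y,X)` (square in-plane
#'   when rotations are enabled).
#' @param rot90s,flips,elastic Enable each transform family.
#' @param elastic_alpha Displacement amplitude in voxels.
#' @param elastic_grid Control-point spacing in voxels.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (the training loop seeds it once per run).
#' @return `list(image, labels)`.
#' @export
augment <- function(image, labels, rot90s = TRUE, flips = TRUE, elastic = FALSE,
                    elastic_alpha = 8, elastic_grid = 16, seed = NULL) {
  run <- function() {
    nd <- length(dim(image))
    if (rot90s) {
      k <- sample.int(4L, 1L) - 1L
      image <- rot90_yx(image, k)
      labels <- rot90_yx(labels, k)
    }
    if (flips) {
      for (axis in if (nd == 2L) 1:2 else 2:3) {
        if (runif(1) < 0.5) {
          image <- flip_axis(image, axis)
          labels <- flip_axis(labels, axis)
        }
      }
    }
    if (elastic && elastic_alpha > 0) {
      hw <- if (nd == 2L) dim(image) else dim(image)[2:3]
      f <- .elastic_field(hw, elastic_alpha, elastic_grid)
      if (nd == 2L) {
        image <- .warp_plane(image, f$dy, f$dx)
        labels <- .warp_plane(labels, f$dy, f$dx, nearest = TRUE)
      } else {
        for (z in seq_len(dim(image)[1L])) {
          image[z, , ] <- .warp_plane(image[z, , ], f$dy, f$dx)
          labels[z, , ] <- .warp_plane(labels[z, , ], f$dy, f$dx, nearest = TRUE)
        }
      }
    }
    list(image = image, labels = labels)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
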