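# Synthetic EM-like fixtures: grayscale volumes containing dark ellipsoidal
# organelles with a bright rim (membrane analogue) on noisy background, plus
# exact binary labels, and simulated imperfect predictions for exercising
# post-processing and metrics without any training.

#' Specification of a synthetic EM fixture volume
#'
#' The generator emulates the gross appearance of FIB-SEM / ssEM mitochondria
#' data: organelles are randomly rotated, in-plane elongated ellipsoids whose
#' interior is darker than the surrounding cytoplasm-like Gaussian texture,
#' wrapped in a bright 1-2 voxel rim. The `anisotropy` factor compresses
#' organelles across fewer Z slices, mimicking serial-section stacks with
#' coarse axial resolution.
#'
#' @param shape Volume shape `(Z, Y, X)`, minimum `(8, 32, 32)`.
#' @param n_organelles Number of ellipsoids to place.
#' @param semi_axes In-plane semi-axis range (voxels), `c(min, max)`.
#' @param anisotropy Z compression factor (1 = isotropic; larger = organelles
#'   span proportionally fewer slices).
#' @param bg_mean,bg_sd Background intensity model.
#' @param interior_mean,interior_sd Organelle interior intensity model.
#' @param rim_value Rim (membrane) intensity.
#' @param rim_width Rim thickness in voxels (measured inward from the
#'   organelle surface; the rim belongs to the labeled interior).
#' @param seed RNG seed; the spec plus seed fully determines the output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(shape = c(16L, 128L, 128L), n_organelles = 10L,
                         semi_axes = c(5, 14), anisotropy = 1,
                         bg_mean = 0.55, bg_sd = 0.06,
                         interior_mean = 0.25, interior_sd = 0.05,
                         rim_value = 0.85, rim_width = 1.5,
                         seed = 42L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(8L, 32L, 32L))) {
    stop("shape must be (Z, Y, X) with minimum (8, 32, 32)")
  }
  stopifnot(length(semi_axes) == 2L, semi_axes[1L] > 0, anisotropy >= 1)
  structure(
    list(
      shape = shape, n_organelles = as.integer(n_organelles),
      semi_axes = semi_axes, anisotropy = anisotropy,
      bg_mean = bg_mean, bg_sd = bg_sd,
      interior_mean = interior_mean, interior_sd = interior_sd,
      rim_value = rim_value, rim_width = rim_width, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a synthetic volume with paired labels
#'
#' Places `n_organelles` random ellipsoids (rejecting placements that would
#' overlap existing foreground by more than half of their own volume; if no
#' admissible placement is found after bounded retries, fewer organelles are
#' placed with a warning) and renders background texture, dark interiors and
#' bright rims. Labels are the exact ellipsoid interiors (rim included).
#' Intensities are clamped to `[0, 1]`.
#'
#' @param spec A [fixture_spec()].
#' @return List with `image` (numeric `(Z,Y,X)` array in `[0,1]`) and
#'   `labels` (binary array of the same shape).
#' @export
#' @examples
#' fx <- make_volume(fixture_spec(shape = c(8, 48, 48), n_organelles = 3))
#' range(fx$image); sum(fx$labels) > 0
make_volume <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  d <- spec$shape
  withr::with_seed(spec$seed, {
    labels <- array(0, d)
    rim <- array(0, d)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 40L * max(1L, spec$n_organelles)
    while (placed < spec$n_organelles && attempts < max_attempts) {
      attempts <- attempts + 1L
      a_cap <- min(spec$semi_axes[2L], (min(d[2:3]) - 4) / 2)
      a <- runif(1, min(spec$semi_axes[1L], a_cap), a_cap) # in-plane major
      b <- runif(1, min(spec$semi_axes[1L], a), a) # in-plane minor
      cz <- max(1.5, (a + b) / 2 / spec$anisotropy) # axial semi-axis
      cz <- min(cz, (d[1L] - 3) / 2) # thin stacks clip the axial extent
      theta <- runif(1, 0, pi)
      ctr <- c(
        runif(1, cz + 1, d[1L] - cz), runif(1, a + 1, d[2L] - a),
        runif(1, a + 1, d[3L] - a)
      )
      # bounding box of the ellipsoid
      lo <- pmax(1L, floor(ctr - c(cz, a, a)))
      hi <- pmin(d, ceiling(ctr + c(cz, a, a)))
      zz <- seq.int(lo[1L], hi[1L])
      yy <- seq.int(lo[2L], hi[2L])
      xx <- seq.int(lo[3L], hi[3L])
      gz <- rep(zz, times = length(yy) * length(xx)) - ctr[1L]
      gy <- rep(rep(yy, each = length(zz)), times = length(xx)) - ctr[2L]
      gx <- rep(xx, each = length(zz) * length(yy)) - ctr[3L]
      u <- gy * cos(theta) + gx * sin(theta)
      v <- -gy * sin(theta) + gx * cos(theta)
      q <- (u / a)^2 + (v / b)^2 + (gz / cz)^2
      inside <- q <= 1
      if (!any(inside)) next
      sub <- labels[zz, yy, xx]
      overlap <- sum(sub[inside] > 0) / sum(inside)
      if (overlap > 0.5) next
      # rim: between the surface and an ellipsoid shrunk by rim_width voxels
      rw <- spec$rim_width
      qi <- (u / max(a - rw, 0.5))^2 + (v / max(b - rw, 0.5))^2 +
        (gz / max(cz - rw, 0.5))^2
      in_rim <- inside & qi > 1
      sub[inside] <- 1
      labels[zz, yy, xx] <- sub
      subr <- rim[zz, yy, xx]
      subr[in_rim] <- 1
      rim[zz, yy, xx] <- subr
      placed <- placed + 1L
    }
    if (placed < spec$n_organelles) {
      warning(sprintf(
        "placed %d of %d organelles (overcrowded volume)", placed, spec$n_organelles
      ))
    }
    image <- array(rnorm(prod(d), spec$bg_mean, spec$bg_sd), d)
    inner <- labels > 0 & rim == 0
    image[inner] <- rnorm(sum(inner), spec$interior_mean, spec$interior_sd)
    image[rim > 0] <- rnorm(sum(rim > 0), spec$rim_value, spec$interior_sd / 2)
    image <- pmin(pmax(image, 0), 1)
    dim(image) <- d
    list(image = image, labels = labels)
  })
}

#' Simulate an imperfect probability prediction from clean labels
#'
#' Produces a pseudo-prediction for testing post-processing and metrics
#' without training a model: the true labels are softened towards the middle
#' of the probability range, boundary voxels are jittered, random voxels are
#' flipped at `flip_rate`, and small spurious blobs are added on the
#' background. With every rate at zero the output equals the labels exactly.
#'
#' @param labels Binary `(Z, Y, X)` volume.
#' @param flip_rate Per-voxel probability of flipping `p -> 1 - p`.
#' @param border_jitter Probability that a boundary voxel (foreground voxel
#'   adjacent to background, or vice versa) flips.
#' @param spurious_blobs Number of small random foreground blobs to add.
#' @param soften Amplitude of the uniform softening pulling probabilities
#'   away from exactly 0/1.
#' @param seed RNG seed.
#' @return Probability array of the same shape.
#' @export
corrupt_labels <- function(labels, flip_rate = 0.01, border_jitter = 0.2,
                           spurious_blobs = 2L, soften = 0.2, seed = 42L) {
  stopifnot(
    flip_rate >= 0, flip_rate < 1, border_jitter >= 0, border_jitter < 1,
    soften >= 0, soften < 1
  )
  d <- dim(labels)
  lab <- (labels > 0) * 1
  withr::with_seed(seed, {
    p <- lab
    if (soften > 0) {
      n <- length(p)
      off <- runif(n, 0, soften)
      p <- abs(lab - off)
      dim(p) <- d
    }
    if (border_jitter > 0) {
      border <- (binary_dilate(lab, 1L) - binary_erode(lab, 1L)) > 0
      flip <- border & array(runif(length(lab)) < border_jitter, d)
      p[flip] <- 1 - p[flip]
    }
    if (flip_rate > 0) {
      flip <- array(runif(length(lab)) < flip_rate, d)
      p[flip] <- 1 - p[flip]
    }
    if (spurious_blobs > 0) {
      for (i in seq_len(spurious_blobs)) {
        r <- sample(1:2, 1L)
        ctr <- c(
          sample(seq.int(1L + r, d[1L] - r), 1L),
          sample(seq.int(1L + r, d[2L] - r), 1L),
          sample(seq.int(1L + r, d[3L] - r), 1L)
        )
        zz <- seq.int(ctr[1L] - r, ctr[1L] + r)
        yy <- seq.int(ctr[2L] - r, ctr[2L] + r)
        xx <- seq.int(ctr[3L] - r, ctr[3L] + r)
        p[zz, yy, xx] <- pmax(p[zz, yy, xx], runif(1, 0.7, 0.95))
      }
    }
    pmin(pmax(p, 0), 1)
  })
}

#' Intensity-threshold baseline segmentation
#'
#' A deliberately simple non-learned segmenter used to demonstrate that the
#' synthetic fixtures are separable by intensity alone (and hence learnable
#' by small networks): Otsu's threshold computed on the dark half of the
#' intensity histogram isolates the organelle interiors, small speckles are
#' removed, and the mask is dilated in-plane by the rim width so the bright
#' membrane rim (invisible to a dark threshold) is recovered.
#'
#' @param image Grayscale `(Z, Y, X)` volume in `[0, 1]`.
#' @param rim_width Rim thickness of the generating [fixture_spec()].
#' @param min_area Speckle-removal threshold (voxels).
#' @return Binary mask of the same shape.
#' @export
threshold_baseline <- function(image, rim_width = 1.5, min_area = 10L) {
  thr <- otsu_threshold(image[image < stats::median(image)])
  m <- (image < thr) * 1
  dim(m) <- dim(image)
  m <- spurious_filter(m, min_area)
  binary_dilate(m, as.integer(round(rim_width + 0.5)), axes = 2:3)
}

#' Write a ready-to-train fixture directory
#'
#' Mirrors the layout of the public EM mitochondria datasets: `train/x`,
#' `train/y`, `test/x`, `test/y`, each holding one multipage TIFF stack.
#'
#' @param dir Output directory (created if needed).
#' @param train_spec,test_spec [fixture_spec()]s for the two volumes.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dir, train_spec, test_spec) {
  for (sub in c("train/x", "train/y", "test/x", "test/y")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  tr <- make_volume(train_spec)
  te <- make_volume(test_spec)
  write_volume(tr$image, file.path(dir, "train/x/stack.tif"))
  write_volume(tr$labels, file.path(dir, "train/y/stack.tif"))
  write_volume(te$image, file.path(dir, "test/x/stack.tif"))
  write_volume(te$labels, file.path(dir, "test/y/stack.tif"))
  invisible(dir)
}
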