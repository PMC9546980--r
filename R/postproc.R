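# Post-processing operators applied to binarized network output: median
# Z-filtering, small-blob removal, marker-controlled watershed border
# refinement, and their chained application with per-step logging.

#' Threshold a probability map
#'
#' Voxels with probability greater than or equal to the threshold become
#' foreground (ties at exactly the threshold are foreground).
#'
#' @param prob Probability array, values in `[0, 1]`.
#' @param threshold Scalar threshold (default 0.5).
#' @return Binary array of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  m <- (prob >= threshold) * 1
  dim(m) <- dim(prob)
  m
}

#' Median filter along the Z axis
#'
#' Slides an odd-length median window along each (y, x) column of a binary
#' stack, correcting isolated label flips between consecutive sections. For
#' binary input the median is a majority vote. Edges are handled by symmetric
#' reflection (edge slice included), so a constant stack is a fixed point.
#'
#' @param mask Binary `(Z, Y, X)` volume.
#' @param window Odd window length `>= 3`.
#' @return Filtered binary volume.
#' @export
zfilter <- function(mask, window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  d <- dim(mask)
  if (length(d) != 3L) stop("zfilter needs a (Z, Y, X) volume")
  nz <- d[1L]
  if (window > 2L * nz - 1L) stop("window too large for stack depth")
  r <- (window - 1L) %/% 2L
  refl <- c(rev(seq_len(r)), seq_len(nz), nz + 1L - seq_len(r))
  padded <- (mask > 0)[refl, , , drop = FALSE] * 1
  acc <- array(0, d)
  for (off in seq_len(window)) {
    acc <- acc + padded[seq.int(off, off + nz - 1L), , , drop = FALSE]
  }
  (acc > window / 2) * 1
}

#' Remove small connected components
#'
#' Labels the foreground components (per-slice in 2D mode, volumetric in 3D
#' mode) and removes those smaller than `min_area` voxels.
#'
#' @param mask Binary array, `(Y, X)` or `(Z, Y, X)`.
#' @param min_area Minimum component size in voxels to keep.
#' @param mode `"3d"` (volumetric components, default for volumes) or
#'   `"slice"` (components per 2D section).
#' @param connectivity 8 or 4 in 2D slices; 26 or 6 in 3D.
#' @return Filtered binary array.
#' @export
spurious_filter <- function(mask, min_area = 100L, mode = c("3d", "slice"),
                            connectivity = NULL) {
  mode <- match.arg(mode)
  if (min_area <= 0) {
    return((mask > 0) * 1)
  }
  d <- dim(mask)
  if (length(d) == 2L) {
    mode <- "slice"
    mask <- array(mask, c(1L, d))
  }
  dv <- dim(mask)
  keep_big <- function(vol, conn) {
    labs <- .cc_label_cpp(as.vector(vol > 0), as.integer(dim(vol)), as.integer(conn))
    if (max(labs) == 0L) {
      return(array(0, dim(vol)))
    }
    sizes <- tabulate(labs)
    out <- array(as.numeric(labs > 0 & sizes[pmax(labs, 1L)] >= min_area), dim(vol))
    out
  }
  if (mode == "slice") {
    conn <- connectivity %||% 8L
    out <- mask
    for (z in seq_len(dv[1L])) {
      out[z, , ] <- keep_big(array(mask[z, , ], c(1L, dv[2:3])), conn)
    }
  } else {
    conn <- connectivity %||% 26L
    out <- keep_big(mask, conn)
  }
  if (length(d) == 2L) dim(out) <- d
  out
}

#' Marker-controlled watershed border refinement
#'
#' Refines mask borders against the image: foreground markers are the mask
#' eroded by `erosion_radius`, background markers the complement of the mask
#' dilated by `dilation_radius`, and Meyer's watershed floods the
#' morphological gradient of the raw image from both marker sets. Voxels
#' confidently inside/outside (the markers themselves) keep their class; only
#' the uncertain border band is re-assigned to wherever the image gradient
#' puts the object boundary.
#'
#' @param image Raw grayscale array aligned with `mask`.
#' @param mask Binary array, `(Y, X)` or `(Z, Y, X)`.
#' @param erosion_radius,dilation_radius Marker construction radii (pixels).
#' @param mode `"slice"` (per-section, default: EM label stacks are per-slice
#'   annotations) or `"3d"`.
#' @return Refined binary mask. If erosion annihilates every foreground
#'   marker the input mask is returned with a warning.
#' @export
watershed_refine <- function(image, mask, erosion_radius = 2L, dilation_radius = 5L,
                             mode = c("slice", "3d")) {
  mode <- match.arg(mode)
  if (!identical(dim(image), dim(mask))) stop("image and mask are not aligned")
  d <- dim(mask)
  two_d_input <- length(d) == 2L
  if (two_d_input) {
    image <- array(image, c(1L, d))
    mask <- array(mask, c(1L, d))
    mode <- "slice"
  }
  m <- (mask > 0) * 1
  if (sum(m) == 0) {
    warning("empty mask: nothing to refine")
    out <- m
    if (two_d_input) dim(out) <- d
    return(out)
  }
  dv <- dim(m)
  axes <- if (mode == "slice") 2:3 else 1:3
  fg <- binary_erode(m, erosion_radius, axes)
  if (sum(fg) == 0) {
    warning("erosion annihilated all foreground markers; returning input mask")
    out <- m
    if (two_d_input) dim(out) <- d
    return(out)
  }
  bg <- 1 - binary_dilate(m, dilation_radius, axes)
  grad <- morph_gradient(image, axes)
  markers <- array(0L, dv)
  markers[fg > 0] <- 1L
  markers[bg > 0] <- 2L
  run_ws <- function(g, mk) {
    .marker_watershed_cpp(
      as.vector(g), as.integer(mk), as.integer(dim(g)),
      if (mode == "slice") 8L else 26L
    )
  }
  if (mode == "slice") {
    out <- array(0, dv)
    for (z in seq_len(dv[1L])) {
      mk <- array(markers[z, , ], c(1L, dv[2:3]))
      if (sum(mk == 1L) == 0L) {
        # thin sections whose eroded markers vanish are left untouched
        out[z, , ] <- m[z, , ]
        next
      }
      lab <- run_ws(array(grad[z, , ], c(1L, dv[2:3])), mk)
      out[z, , ] <- as.numeric(lab == 1L)
    }
  } else {
    lab <- run_ws(grad, markers)
    out <- array(as.numeric(lab == 1L), dv)
  }
  if (two_d_input) dim(out) <- d
  out
}

#' Post-processing chain
#'
#' Describes an ordered sequence of post-processing steps. `binarize` must
#' come first (all later steps operate on masks).
#'
#' @param steps List of steps; each is either a step name or
#'   `list(step = name, <parameters>)`. Known steps: `binarize` (`threshold`),
#'   `spurious` (`min_area`, `mode`, `connectivity`), `watershed`
#'   (`erosion_radius`, `dilation_radius`, `mode`), `zfilter` (`window`).
#' @return A `postproc_chain`.
#' @export
#' @examples
#' postproc_chain(list("binarize", list(step = "spurious", min_area = 50)))
postproc_chain <- function(steps = list("binarize")) {
  known <- c("binarize", "spurious", "watershed", "zfilter")
  norm <- lapply(steps, function(s) {
    if (is.character(s)) s <- list(step = s)
    if (!s$step %in% known) stop("unknown step '", s$step, "'")
    s
  })
  names_ <- vapply(norm, `[[`, "", "step")
  if (names_[1L] != "binarize") {
    norm <- c(list(list(step = "binarize")), norm)
    names_ <- c("binarize", names_)
  }
  if (any(names_[-1L] == "binarize")) stop("binarize must be the first step only")
  structure(norm, class = "postproc_chain")
}

#' Run a post-processing chain
#'
#' Applies the steps in order to a probability map, recording per step how
#' many voxels changed (and, when `truth` is supplied, the foreground IoU
#' after each step — the incremental-improvement view of a post-processing
#' pipeline).
#'
#' @param prob Probability volume from the network.
#' @param image Raw image volume (needed by the watershed step).
#' @param chain A [postproc_chain()] (or list coercible to one).
#' @param truth Optional reference mask for per-step metrics.
#' @return List with `mask` (final binary volume) and `log` (data frame:
#'   step, voxels_changed, iou_foreground when truth given).
#' @export
run_chain <- function(prob, image = NULL, chain = postproc_chain(), truth = NULL) {
  if (!inherits(chain, "postproc_chain")) chain <- postproc_chain(chain)
  cur <- NULL
  rows <- list()
  for (s in chain) {
    prev <- cur
    cur <- switch(s$step,
      binarize = binarize(prob, s$threshold %||% 0.5),
      spurious = spurious_filter(cur,
        min_area = s$min_area %||% 100L,
        mode = s$mode %||% "3d",
        connectivity = s$connectivity
      ),
      watershed = {
        if (is.null(image)) stop("the watershed step needs the raw image")
        watershed_refine(image, cur,
          erosion_radius = s$erosion_radius %||% 2L,
          dilation_radius = s$dilation_radius %||% 5L,
          mode = s$mode %||% "slice"
        )
      },
      zfilter = zfilter(cur, s$window %||% 3L)
    )
    rows[[length(rows) + 1L]] <- data.frame(
      step = s$step,
      voxels_changed = if (is.null(prev)) NA_integer_ else sum(cur != prev),
      iou_foreground = if (is.null(truth)) NA_real_ else iou(cur, truth)$foreground
    )
  }
  list(mask = cur, log = do.call(rbind, rows))
}
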