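# Output reconstruction: merging per-patch predictions back into full-volume
# probability maps, with flat or spline-window blending and test-time
# augmentation ensembling.

#' Second-order spline blending window
#'
#' Separable taper used to down-weight patch borders when averaging
#' overlapping predictions: along each axis
#' `s(t) = sin(pi * (t + 0.5) / n) ^ power` for `t = 0 .. n-1`, rescaled to
#' peak at 1 and floored at `eps` so border voxels never divide by zero. The
#' window is symmetric under reflection, maximal at the patch centre and
#' strictly positive.
#'
#' @param patch_shape Integer vector (2 or 3 axes).
#' @param power Taper exponent (2 = squared-sine, the default).
#' @param eps Floor applied after rescaling.
#' @return A `blend_window`: list with the weight array `w` (dim =
#'   `patch_shape`) and the parameters.
#' @export
spline_window <- function(patch_shape, power = 2, eps = 1e-3) {
  stopifnot(power >= 1)
  axes <- lapply(as.integer(patch_shape), function(n) {
    s <- sin(pi * (seq_len(n) - 0.5) / n)^power
    pmax(s / max(s), eps)
  })
  w <- Reduce(function(a, b) outer(a, b), axes)
  dim(w) <- as.integer(patch_shape)
  structure(list(w = w, power = power, eps = eps, patch_shape = as.integer(patch_shape)),
    class = "blend_window"
  )
}

#' Merge patch predictions into a full-volume probability map
#'
#' Weighted average per voxel: `out[v] = sum_i w_i(v) p_i(v) / sum_i w_i(v)`
#' over the patches covering `v`. A flat window is plain averaging; a
#' [spline_window()] suppresses the jagged borders of tiled inference.
#' Accumulation happens in double precision; if the grid was built with
#' reflect padding the padded margin is cropped away.
#'
#' @param patches List of prediction arrays, one per grid box, each of the
#'   grid's `patch_shape`.
#' @param grid The [systematic_grid()] the patches came from.
#' @param window `"flat"` or a [spline_window()].
#' @return Array of the grid's `volume_shape` with values in the convex hull
#'   of the predictions.
#' @export
merge_patches <- function(patches, grid, window = "flat") {
  stopifnot(inherits(grid, "patch_grid"))
  if (length(patches) != nrow(grid$starts)) {
    stop("need exactly one prediction per grid box")
  }
  ps <- grid$patch_shape
  nd <- length(ps)
  w <- if (inherits(window, "blend_window")) {
    stopifnot(identical(window$patch_shape, ps))
    window$w
  } else if (identical(window, "flat")) {
    array(1, ps)
  } else {
    stop("window must be \"flat\" or a blend_window")
  }
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!identical(as.integer(dim(p) %||% length(p))[seq_len(nd)], ps)) {
      stop("prediction ", i, " does not match patch_shape")
    }
  }
  # accumulation runs in extended precision (src/convops.cpp) so identical
  # overlapping values merge back bit-exactly; dims are left-padded to 3
  pm <- matrix(unlist(patches, use.names = FALSE), prod(ps), length(patches))
  pad3 <- function(v, fill) c(rep(fill, 3L - nd), v)
  starts3 <- cbind(
    matrix(0L, nrow(grid$starts), 3L - nd),
    grid$starts
  )
  out <- .merge_patches_cpp(
    pm, starts3, as.integer(pad3(ps, 1L)),
    as.integer(pad3(grid$padded_shape, 1L)), as.vector(w)
  )
  dim(out) <- grid$padded_shape
  idx <- lapply(seq_len(nd), function(a) seq_len(grid$volume_shape[a]))
  do.call(`[`, c(list(out), idx, list(drop = FALSE)))
}

# --- test-time augmentation ------------------------------------------------

.tta_desc <- function(ndim) {
  rots <- 0:3
  flips <- c(FALSE, TRUE)
  zflips <- if (ndim == 3L) c(FALSE, TRUE) else FALSE
  out <- list()
  for (zf in zflips) {
    for (fl in flips) {
      for (k in rots) {
        out[[length(out) + 1L]] <- list(rot = k, flip = fl, zflip = zf)
      }
    }
  }
  out
}

# forward transform: optional Z-flip, optional Y-flip, then k quarter-turns
tta_apply <- function(patch, d) {
  nd <- length(dim(patch))
  x <- patch
  if (isTRUE(d$zflip)) x <- flip_axis(x, 1L)
  if (d$flip) x <- flip_axis(x, if (nd == 2L) 1L else 2L)
  rot90_yx(x, d$rot)
}

tta_invert <- function(patch, d) {
  nd <- length(dim(patch))
  x <- rot90_yx(patch, 4L - d$rot)
  if (d$flip) x <- flip_axis(x, if (nd == 2L) 1L else 2L)
  if (isTRUE(d$zflip)) x <- flip_axis(x, 1L)
  x
}

#' Enumerate test-time-augmentation variants of a patch
#'
#' 2D: the 8 elements of the dihedral group (4 right-angle rotations x
#' optional flip). 3D: 16 variants, the 8 in-plane dihedral transforms
#' crossed with an optional Z-flip (in-plane transforms respect the
#' anisotropy of EM stacks). Each variant carries the descriptor of its exact
#' inverse for [tta_collapse()].
#'
#' @param patch 2D `(Y,X)` or 3D `(Z,Y,X)` array with square `(Y,X)` extent.
#' @return List with `patches` (8 or 16 transformed copies) and `desc`.
#' @export
tta_expand <- function(patch) {
  nd <- length(dim(patch))
  stopifnot(nd %in% c(2L, 3L))
  sp <- dim(patch)
  if (sp[nd - 1L] != sp[nd]) stop("TTA rotations need square (Y,X) patches")
  desc <- .tta_desc(nd)
  list(patches = lapply(desc, function(d) tta_apply(patch, d)), desc = desc)
}

#' Average inverse-transformed TTA predictions
#'
#' @param predictions List of per-variant prediction arrays, aligned with
#'   `desc`.
#' @param desc Descriptor list from [tta_expand()].
#' @return The ensembled prediction patch (plain mean in probability space).
#' @export
tta_collapse <- function(predictions, desc) {
  if (length(predictions) != length(desc)) {
    stop("predictions and descriptors differ in length")
  }
  inv <- mapply(function(p, d) tta_invert(p, d), predictions, desc, SIMPLIFY = FALSE)
  Reduce(`+`, inv) / length(inv)
}

#' Reconstruction policy
#'
#' @param mode `"per_patch"` (0-overlap mosaic), `"overlap_50"` (50%-overlap
#'   tiling) or `"full_image"` (single full-size pass).
#' @param blending `"flat"` or `"spline"` (overlap modes only).
#' @param tta Ensemble over the test-time-augmentation group per patch.
#' @param patch_shape Patch extent for the tiled modes.
#' @param force_blend_3d Spline blending of 3D volumes is refused by default
#'   (it is costly and was only ever validated in 2D); set `TRUE` to override.
#' @return A `recon_policy` list.
#' @export
recon_policy <- function(mode = c("overlap_50", "per_patch", "full_image"),
                         blending = c("flat", "spline"), tta = FALSE,
                         patch_shape = NULL, force_blend_3d = FALSE) {
  mode <- match.arg(mode)
  blending <- match.arg(blending)
  if (mode == "full_image" && blending == "spline") {
    stop("full_image mode has a single tile: blending does not apply")
  }
  structure(
    list(
      mode = mode, blending = blending, tta = isTRUE(tta),
      patch_shape = patch_shape, force_blend_3d = isTRUE(force_blend_3d)
    ),
    class = "recon_policy"
  )
}

.predict_one <- function(model, patch, tta) {
  if (!tta) {
    return(predict_patch(model, patch))
  }
  ex <- tta_expand(patch)
  preds <- lapply(ex$patches, function(p) predict_patch(model, p))
  tta_collapse(preds, ex$desc)
}

.model_ndim <- function(model) {
  if (inherits(model, "em_network")) model$spec$ndim else NA_integer_
}

.model_down <- function(model) {
  if (inherits(model, "em_network")) model$down_factor else 1L
}

#' Tiled (or full-image) inference over a whole volume
#'
#' Orchestrates grid construction, optional per-patch test-time augmentation
#' and merging according to the policy. A 2D model applied to a `(Z,Y,X)`
#' stack runs slice by slice. Full-image mode reflect-pads each image to the
#' model's downsampling divisibility and crops the result back. Deterministic
#' given the model weights.
#'
#' @param model An `em_network` or a stub function `patch -> probabilities`.
#' @param volume 2D image or `(Z,Y,X)` stack/volume, values in `[0, 1]`.
#' @param policy A [recon_policy()].
#' @return Probability array shaped like `volume`.
#' @export
predict_volume <- function(model, volume, policy = recon_policy()) {
  stopifnot(inherits(policy, "recon_policy"))
  nd_model <- .model_ndim(model)
  nd_vol <- length(dim(volume) %||% stop("volume must be an array"))
  if (!is.na(nd_model) && nd_model == 2L && nd_vol == 3L) {
    out <- volume
    for (z in seq_len(dim(volume)[1L])) {
      out[z, , ] <- predict_volume(model, volume[z, , ], policy)
    }
    return(out)
  }
  nd <- nd_vol
  if (policy$blending == "spline" && nd == 3L && !policy$force_blend_3d) {
    stop("spline blending of 3D volumes is disabled by default (set force_blend_3d = TRUE)")
  }
  if (policy$mode == "full_image") {
    down <- .model_down(model)
    target <- as.integer(ceiling(dim(volume) / down) * down)
    vp <- pad_reflect_to(volume, target)
    pr <- .predict_one(model, vp, policy$tta)
    idx <- lapply(seq_len(nd), function(a) seq_len(dim(volume)[a]))
    return(do.call(`[`, c(list(pr), idx, list(drop = FALSE))))
  }
  ps <- policy$patch_shape
  if (is.null(ps)) stop("policy$patch_shape is required for tiled modes")
  ps <- as.integer(rep_len(ps, nd))
  overlap <- if (policy$mode == "overlap_50") 0.5 else 0
  grid <- systematic_grid(dim(volume), ps, overlap, pad = "reflect")
  patches <- extract_patches(volume, grid)
  preds <- lapply(patches, function(p) .predict_one(model, p, policy$tta))
  window <- if (policy$blending == "spline") spline_window(ps) else "flat"
  merge_patches(preds, grid, window)
}
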