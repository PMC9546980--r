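#' Declarative description of an encoder-decoder segmentation network
#'
#' A `network_spec` captures everything needed to build one of the lightweight
#' U-Net style architectures: dimensionality, processing-block type, the
#' per-level filter counts (last entry is the bottleneck), dropout schedule,
#' activation, initialiser, and the optional attention-gate /
#' squeeze-and-excitation / batch-normalisation switches. [build_network()]
#' turns a spec into a trainable model; [preset_spec()] returns the tuned
#' configurations used throughout the package.
#'
#' @param ndim Spatial dimensionality, 2 or 3.
#' @param filters Integer vector of channel counts per level, length >= 2;
#'   the last entry is the bottleneck width. The encoder has
#'   `length(filters) - 1` downsampling levels.
#' @param block_kind `"conv"` (two 3x3 convolutions, each followed by
#'   activation and dropout) or `"residual"` (full pre-activation residual
#'   block with identity shortcut, 1x1 projection when channel counts change).
#' @param attention_gates Insert an additive attention gate on every skip
#'   connection before concatenation.
#' @param se_mode `"none"`, `"all_but_bottleneck"` (a squeeze-and-excitation
#'   block after every processing block except the bottleneck) or
#'   `"every_conv"` (after the bottleneck too).
#' @param dropout Numeric vector of per-block dropout rates for the encoder
#'   path including the bottleneck (rates in `[0, 1)`); the decoder mirrors it
#'   in reverse. `NULL` disables dropout.
#' @param activation `"ELU"` or `"ReLU"`.
#' @param kernel_init `"he_normal"` or `"glorot_uniform"`.
#' @param batch_norm Add batch normalisation after each convolution
#'   (off by default; kept as an ablation switch).
#' @param z_down Logical vector, one entry per downsampling level of a 3D
#'   network: whether pooling halves the Z axis at that level. Ignored for 2D.
#'   Anisotropic presets set all entries `FALSE`.
#' @param se_ratio Reduction ratio of the squeeze-and-excitation gating
#'   network.
#' @param out_channels Number of output channels (1 for the binary task).
#'
#' @return An object of class `network_spec`.
#' @seealso [preset_spec()], [build_network()], [count_parameters()]
#' @export
#' @examples
#' spec <- network_spec(2, filters = c(8, 16))
#' spec$filters
network_spec <- function(ndim, filters, block_kind = c("conv", "residual"),
                         attention_gates = FALSE,
                         se_mode = c("none", "all_but_bottleneck", "every_conv"),
                         dropout = NULL,
                         activation = c("ELU", "ReLU"),
                         kernel_init = c("he_normal", "glorot_uniform"),
                         batch_norm = FALSE,
                         z_down = NULL,
                         se_ratio = 8L,
                         out_channels = 1L) {
  ndim <- as.integer(ndim)
  if (!ndim %in% c(2L, 3L)) stop("ndim must be 2 or 3")
  filters <- as.integer(filters)
  if (length(filters) < 2L || any(filters < 1L)) {
    stop("filters must list at least 2 channel counts, all >= 1")
  }
  block_kind <- match.arg(block_kind)
  se_mode <- match.arg(se_mode)
  activation <- match.arg(activation)
  kernel_init <- match.arg(kernel_init)
  n_levels <- length(filters) - 1L
  n_blocks <- length(filters) # encoder blocks + bottleneck
  if (is.null(dropout)) dropout <- rep(0, n_blocks)
  if (length(dropout) == 1L) dropout <- rep(dropout, n_blocks)
  if (length(dropout) != n_blocks) {
    stop("dropout must give one rate per encoder block incl. bottleneck (", n_blocks, ")")
  }
  if (any(dropout < 0 | dropout >= 1)) stop("dropout rates must lie in [0, 1)")
  if (ndim == 2L) {
    z_down <- rep(FALSE, n_levels)
  } else if (is.null(z_down)) {
    z_down <- rep(TRUE, n_levels)
  } else {
    z_down <- rep_len(as.logical(z_down), n_levels)
  }
  structure(
    list(
      ndim = ndim, filters = filters, block_kind = block_kind,
      attention_gates = isTRUE(attention_gates), se_mode = se_mode,
      dropout = as.numeric(dropout), activation = activation,
      kernel_init = kernel_init, batch_norm = isTRUE(batch_norm),
      z_down = z_down, se_ratio = as.integer(se_ratio),
      out_channels = as.integer(out_channels), upsample = "transposed_conv"
    ),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> %dD %s U-Net  filters: %s\n", x$ndim,
    if (x$attention_gates) "attention" else x$block_kind,
    paste(x$filters, collapse = "-")
  ))
  cat(sprintf(
    "  activation %s, init %s, dropout %s, SE %s, batch_norm %s, z_down %s\n",
    x$activation, x$kernel_init, paste(x$dropout, collapse = "/"),
    x$se_mode, x$batch_norm, paste(as.integer(x$z_down), collapse = "")
  ))
  invisible(x)
}

.presets <- c(
  "unet2d", "residual2d", "attention2d", "se2d",
  "unet3d", "residual3d", "attention3d", "se3d",
  "unet3d_aniso", "residual3d_aniso", "attention3d_aniso"
)

# dropout rises from 0.1 to 0.3 into the bottleneck and is mirrored in the
# decoder; the four-level 2D schedule is 0.1/0.1/0.2/0.2/0.3, shallower nets
# interpolate the same endpoints over the available blocks
.dropout_schedule <- function(n_blocks) {
  if (n_blocks == 5L) {
    return(c(0.1, 0.1, 0.2, 0.2, 0.3))
  }
  round(seq(0.1, 0.3, length.out = n_blocks), 3)
}

#' Tuned architecture presets
#'
#' Returns the optimal configuration found for each proposed architecture:
#' the 2D networks are four-level U-Nets with 16 initial filters doubled per
#' level (bottleneck 256), dropout rising from 0.1 to 0.3 into the bottleneck
#' and mirrored on the way up, ELU activations and transposed-convolution
#' upsampling; the 3D networks use three levels with 28/36/48 filters and a
#' 64-filter bottleneck, the residual 3D variant goes one level deeper
#' (28/36/48/64, bottleneck 80); `*_aniso` presets keep three levels and never
#' downsample the Z axis, for anisotropic stacks; `se*` presets add
#' squeeze-and-excitation blocks everywhere except the bottleneck.
#'
#' @param name One of `"unet2d"`, `"residual2d"`, `"attention2d"`, `"se2d"`,
#'   `"unet3d"`, `"residual3d"`, `"attention3d"`, `"se3d"`, `"unet3d_aniso"`,
#'   `"residual3d_aniso"`, `"attention3d_aniso"`.
#' @return A [network_spec()].
#' @export
#' @examples
#' preset_spec("unet3d")$filters # 28 36 48 64
preset_spec <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% .presets) {
    stop(
      "unknown preset '", paste(name, collapse = ","), "'; valid presets: ",
      paste(.presets, collapse = ", ")
    )
  }
  f2d <- c(16L, 32L, 64L, 128L, 256L)
  f3d <- c(28L, 36L, 48L, 64L)
  f3d_res <- c(28L, 36L, 48L, 64L, 80L)
  f3d_aniso <- f3d # three levels
  base <- function(ndim, filters, ...) {
    network_spec(ndim, filters, dropout = .dropout_schedule(length(filters)), ...)
  }
  switch(name,
    unet2d = base(2, f2d),
    residual2d = base(2, f2d, block_kind = "residual"),
    attention2d = base(2, f2d, attention_gates = TRUE),
    se2d = base(2, f2d, se_mode = "all_but_bottleneck"),
    unet3d = base(3, f3d),
    residual3d = base(3, f3d_res, block_kind = "residual"),
    attention3d = base(3, f3d, attention_gates = TRUE),
    se3d = base(3, f3d, se_mode = "all_but_bottleneck"),
    unet3d_aniso = base(3, f3d_aniso, z_down = FALSE),
    residual3d_aniso = base(3, f3d_res, block_kind = "residual", z_down = FALSE),
    attention3d_aniso = base(3, f3d_aniso, attention_gates = TRUE, z_down = FALSE)
  )
}

#' Serialise a network spec to YAML / read it back
#'
#' @param spec A [network_spec()].
#' @param path File path.
#' @return `spec_to_yaml` writes the file and returns `path` invisibly;
#'   `spec_from_yaml` returns a [network_spec()].
#' @export
spec_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  network_spec(
    ndim = x$ndim, filters = unlist(x$filters), block_kind = x$block_kind,
    attention_gates = x$attention_gates, se_mode = x$se_mode,
    dropout = unlist(x$dropout), activation = x$activation,
    kernel_init = x$kernel_init, batch_norm = x$batch_norm,
    z_down = unlist(x$z_down), se_ratio = x$se_ratio,
    out_channels = x$out_channels
  )
}
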