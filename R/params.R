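#' Count trainable parameters of a network
#'
#' Counts every trainable weight and bias (convolutions, transposed
#' convolutions, attention-gate projections, squeeze-and-excitation gating
#' layers, batch-norm scale/shift). Non-trainable running statistics are
#' excluded. The count is a function of the spec alone, never of the
#' initialisation seed.
#'
#' @param model An `em_network` from [build_network()].
#' @return A `parameter_report`: list with `total_trainable`, `millions`
#'   (count / 1e6 rounded half-up to 2 decimals) and a `per_layer` data frame
#'   (name, shape, count).
#' @export
#' @examples
#' count_parameters(build_network("unet3d", seed = 1))$millions # 0.79
count_parameters <- function(model) {
  stopifnot(inherits(model, "em_network"))
  counts <- vapply(model$params, length, 1L)
  shapes <- vapply(model$params, function(p) {
    paste(dim(p) %||% length(p), collapse = "x")
  }, "")
  total <- sum(counts)
  structure(
    list(
      total_trainable = total,
      millions = floor(total / 1e6 * 100 + 0.5) / 100, # round half-up
      per_layer = data.frame(
        name = names(counts), shape = shapes, count = as.integer(counts),
        row.names = NULL, stringsAsFactors = FALSE
      )
    ),
    class = "parameter_report"
  )
}

#' @export
print.parameter_report <- function(x, ...) {
  cat(sprintf(
    "Trainable parameters: %s (%.2fM)\n",
    format(x$total_trainable, big.mark = ","), x$millions
  ))
  df <- x$per_layer
  w <- max(nchar(df$name))
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  %-*s  %12s  %10s\n", w, df$name[i], df$shape[i],
      format(df$count[i], big.mark = ",")
    ))
  }
  invisible(x)
}
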