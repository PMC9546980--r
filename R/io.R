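# Volume I/O: multipage TIFF stacks and directories of 2D TIFF/PNG slices.
# Volumes are numeric (Z, Y, X) arrays with values in [0, 1] in memory;
# writers rescale to the requested bit depth.

#' Read an image volume
#'
#' Accepts a multipage TIFF file or a directory of 2D TIFF/PNG slices
#' (sorted by file name). Returns a `(Z, Y, X)` array with values in
#' `[0, 1]`; multi-channel slices are averaged to grayscale.
#'
#' @param path File or directory path.
#' @return Numeric `(Z, Y, X)` array.
#' @export
read_volume <- function(path) {
  to_gray <- function(m) {
    if (length(dim(m)) == 3L) m <- apply(m, c(1L, 2L), mean)
    m
  }
  slices <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF/PNG slices in ", path)
    unlist(lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        list(to_gray(png::readPNG(f)))
      } else {
        lapply(tiff::readTIFF(f, all = TRUE), to_gray)
      }
    }), recursive = FALSE)
  } else if (file.exists(path)) {
    lapply(tiff::readTIFF(path, all = TRUE), to_gray)
  } else {
    stop("no such file or directory: ", path)
  }
  d <- dim(slices[[1L]])
  vol <- array(0, c(length(slices), d))
  for (z in seq_along(slices)) vol[z, , ] <- slices[[z]]
  vol
}

#' Write a volume as a multipage TIFF stack
#'
#' @param vol Numeric `(Z, Y, X)` array (or 2D matrix) with values in
#'   `[0, 1]`.
#' @param path Output file.
#' @param bits 8 (masks, grayscale) or 32 (float probability maps).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, bits = 8L) {
  if (length(dim(vol)) == 2L) vol <- array(vol, c(1L, dim(vol)))
  stopifnot(length(dim(vol)) == 3L, bits %in% c(8L, 32L))
  pages <- lapply(seq_len(dim(vol)[1L]), function(z) {
    m <- vol[z, , ]
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
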