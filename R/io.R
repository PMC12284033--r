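## Movie import/export as multi-page TIFF (16-bit unsigned).
##
## Counts are stored as 16-bit integers, which covers the EMCCD range used
## here; values are clamped to [0, 65535] on write.

#' Write a movie as multi-page 16-bit TIFF
#'
#' @param stack a [MovieStack-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMovie <- function(stack, path) {
  stopifnot(is(stack, "MovieStack"))
  arr <- frames(stack)
  pages <- lapply(seq_len(dim(arr)[3]), function(t) {
    m <- pmin(pmax(round(arr[, , t]), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF path.
#' @param pixelSize nm per pixel (metadata the file does not carry).
#' @param frameInterval seconds per frame.
#' @param channel channel label.
#' @return A [MovieStack-class] with intensities in camera counts.
#' @export
readMovie <- function(path, pixelSize = 160, frameInterval = 0.1,
                      channel = "unspecified") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * 65535
  movieStack(arr, pixelSize, frameInterval, channel)
}
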