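#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' @param movie a \linkS4class{Movie}; intensities must lie in
#'   [0, 65535].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMovieTiff <- function(movie, path) {
  d <- movie@data
  if (min(d) < 0 || max(d) > 65535)
    stop("intensities outside the 16-bit range")
  pages <- lapply(seq_len(dim(d)[3]), function(t) d[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a Movie
#'
#' @param path TIFF file path.
#' @param pixelSizeUm pixel size, um/px.
#' @param frameIntervalS frame interval, s.
#' @return A \linkS4class{Movie} with intensities on the stored integer
#'   scale.
#' @export
readMovieTiff <- function(path, pixelSizeUm, frameIntervalS) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # collapse any extra channel
    round(p * 65535)
  })
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  Movie(arr, pixelSizeUm, frameIntervalS)
}

#' Write a ground-truth label stack as a multi-page TIFF
#'
#' @param labelStack integer \code{H x W x T} array of domain labels.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLabelStackTiff <- function(labelStack, path) {
  stopifnot(length(dim(labelStack)) == 3L, max(labelStack) <= 65535)
  pages <- lapply(seq_len(dim(labelStack)[3]),
                  function(t) labelStack[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write an analysis table as CSV
#'
#' @param x data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTableCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
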