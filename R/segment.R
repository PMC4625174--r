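#' Rolling-ball background subtraction
#'
#' Estimates the diffuse background of a fluorescence frame by grayscale
#' morphological opening with a disc of the given radius (the rolling-ball
#' estimate) and subtracts it. The disc must be large relative to the
#' puncta so that spots are removed from the background estimate but
#' slowly varying membrane signal is retained. Output is clamped at zero.
#'
#' @param frame numeric matrix.
#' @param radiusPx disc radius in pixels (>= 1, < min image dimension).
#' @return Background-subtracted matrix, non-negative everywhere.
#' @examples
#' f <- matrix(100, 64, 64); f[30:34, 30:34] <- 200
#' b <- subtractBackground(f, 10)
#' range(b)
#' @export
subtractBackground <- function(frame, radiusPx) {
  stopifnot(is.matrix(frame), radiusPx >= 1)
  if (radiusPx >= min(dim(frame)))
    stop("background radius must be smaller than the image")
  brush <- EBImage::makeBrush(2L * floor(radiusPx) + 1L, shape = "disc")
  rng <- range(frame)
  if (rng[2] == rng[1]) return(matrix(0, nrow(frame), ncol(frame)))
  # EBImage grayscale morphology works on [0,1]; opening commutes with
  # increasing affine maps, so rescale, open, and map back
  scaled <- (frame - rng[1]) / (rng[2] - rng[1])
  bg <- EBImage::imageData(EBImage::opening(scaled, brush)) *
    (rng[2] - rng[1]) + rng[1]
  pmax(frame - bg, 0)
}

#' Large-radius unsharp mask
#'
#' Locally enhances contrast: \code{out = in + amount * (in - G(in))}
#' where \code{G} is Gaussian smoothing with standard deviation
#' \code{radiusPx}. With a radius much larger than the PSF this lifts
#' puncta against the diffuse membrane signal while approximately
#' preserving the image mean.
#'
#' @param frame numeric matrix.
#' @param radiusPx Gaussian sigma in pixels (>= 1).
#' @param amount strength of the enhancement (0 = identity).
#' @return Filtered matrix.
#' @export
unsharpMask <- function(frame, radiusPx, amount) {
  stopifnot(is.matrix(frame), radiusPx >= 1)
  if (amount == 0) return(frame)
  # cap the kernel support at the image size (the brush stays normalized)
  support <- min(2L * ceiling(3 * radiusPx) + 1L, min(dim(frame)))
  if (support %% 2L == 0L) support <- support - 1L
  smooth <- EBImage::imageData(EBImage::gblur(frame, sigma = radiusPx,
                                              radius = support))
  frame + amount * (frame - smooth)
}

#' Threshold a filtered frame into a segment mask
#'
#' Pixels at or above the threshold become foreground. With
#' \code{threshold = "otsu"} the threshold is chosen automatically by
#' Otsu's method (for unattended runs); the value actually used and the
#' selection method are recorded as attributes \code{"threshold"} and
#' \code{"method"} on the returned mask.
#'
#' @param filtered numeric matrix (finite values).
#' @param threshold a single intensity value, or \code{"otsu"}.
#' @return Logical matrix with attributes \code{threshold} and
#'   \code{method} (\code{"manual"} or \code{"otsu"}).
#' @export
makeMask <- function(filtered, threshold) {
  stopifnot(is.matrix(filtered), all(is.finite(filtered)))
  method <- "manual"
  if (identical(threshold, "otsu")) {
    rng <- range(filtered)
    if (rng[2] > rng[1]) {
      scaled <- (filtered - rng[1]) / (rng[2] - rng[1])
      th01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
      threshold <- rng[1] + th01 * (rng[2] - rng[1])
    } else threshold <- rng[1]
    method <- "otsu"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    if (threshold > max(filtered) || threshold <= min(filtered))
      warning("threshold outside image range: mask is empty or full")
  }
  mask <- filtered >= threshold
  attr(mask, "threshold") <- as.numeric(threshold)
  attr(mask, "method") <- method
  mask
}

#' Measure segmented domains
#'
#' Labels the 8-connected components of a segment mask, drops components
#' smaller than \code{minAreaPx}, and measures each surviving domain on
#' the background-subtracted image (not the contrast-enhanced one): area,
#' mean intensity, and intensity-unweighted centroid. Labels are ordered
#' by each component's (top-most, left-most) first pixel.
#'
#' @param mask logical matrix (segment mask).
#' @param bgSubtracted numeric matrix, same shape: the background-
#'   subtracted frame on which intensities are measured.
#' @param params a \linkS4class{SegParams} (supplies \code{minAreaPx}).
#' @param frame frame index recorded in the output.
#' @param pixelSizeUm optional pixel size; fills \code{area_um2}.
#' @return data.frame with columns \code{frame}, \code{label},
#'   \code{area_px}, \code{area_um2}, \code{mean_intensity},
#'   \code{centroid_row_px}, \code{centroid_col_px} (0-based).
#' @export
measureDomains <- function(mask, bgSubtracted, params = SegParams(),
                           frame = 1L, pixelSizeUm = NA_real_) {
  stopifnot(is.matrix(mask), identical(dim(mask), dim(bgSubtracted)))
  lab <- .labelComponents8(mask)
  nLab <- max(lab)
  empty <- data.frame(frame = integer(), label = integer(),
    area_px = integer(), area_um2 = numeric(), mean_intensity = numeric(),
    centroid_row_px = numeric(), centroid_col_px = numeric())
  if (nLab == 0L) return(empty)
  areas <- tabulate(lab, nbins = nLab)
  keep <- which(areas >= params@minAreaPx)
  if (!length(keep)) return(empty)
  idx <- which(lab > 0L)
  labv <- lab[idx]
  rowv <- (idx - 1L) %% nrow(mask)      # 0-based row
  colv <- (idx - 1L) %/% nrow(mask)     # 0-based col
  sumI <- rowsum(bgSubtracted[idx], labv)[, 1]
  cenR <- rowsum(as.numeric(rowv), labv)[, 1] / areas
  cenC <- rowsum(as.numeric(colv), labv)[, 1] / areas
  data.frame(frame = as.integer(frame), label = seq_along(keep),
    area_px = areas[keep],
    area_um2 = areas[keep] * pixelSizeUm^2,
    mean_intensity = sumI[keep] / areas[keep],
    centroid_row_px = cenR[keep], centroid_col_px = cenC[keep])
}

#' Count domains per cell
#'
#' Assigns each domain to the cell whose label sits at the domain's
#' rounded centroid in a cell label image (0 = outside any cell); domains
#' landing on label 0 are dropped, with the dropped count reported as an
#' attribute.
#'
#' @param domains data.frame from \code{\link{measureDomains}}.
#' @param cellMask integer matrix of cell labels (0 = background).
#' @return data.frame with columns \code{cell_id}, \code{n_domains};
#'   attribute \code{"dropped"} holds the number of unassigned domains.
#' @export
domainsPerCell <- function(domains, cellMask) {
  stopifnot(is.matrix(cellMask), all(cellMask >= 0))
  if (nrow(domains) > 0) {
    r <- round(domains$centroid_row_px) + 1L
    c <- round(domains$centroid_col_px) + 1L
    if (any(r < 1L | r > nrow(cellMask) | c < 1L | c > ncol(cellMask)))
      stop("domain centroid outside cell mask")
    cellId <- cellMask[cbind(r, c)]
  } else cellId <- integer()
  dropped <- sum(cellId == 0L)
  if (dropped > 0)
    message(dropped, " domain(s) outside any cell dropped")
  tab <- table(cellId[cellId > 0L])
  out <- data.frame(cell_id = as.integer(names(tab)),
                    n_domains = as.integer(tab))
  attr(out, "dropped") <- dropped
  out
}

#' Segment a frame into measured domains
#'
#' Runs the full segmentation chain on one frame: rolling-ball background
#' subtraction, large-radius unsharp mask, thresholding, and domain
#' measurement on the background-subtracted image.
#'
#' @param frame numeric matrix.
#' @param params a \linkS4class{SegParams}.
#' @param frameIndex frame index recorded in the output.
#' @param pixelSizeUm optional pixel size; fills \code{area_um2}.
#' @return As \code{\link{measureDomains}}, with attributes
#'   \code{threshold} and \code{method} from \code{\link{makeMask}}.
#' @export
segmentFrame <- function(frame, params = SegParams(), frameIndex = 1L,
                         pixelSizeUm = NA_real_) {
  bgsub <- subtractBackground(frame, params@backgroundRadiusPx)
  filt <- unsharpMask(bgsub, params@unsharpRadiusPx, params@unsharpAmount)
  mask <- makeMask(filt, params@threshold)
  out <- measureDomains(mask, bgsub, params, frame = frameIndex,
                        pixelSizeUm = pixelSizeUm)
  attr(out, "threshold") <- attr(mask, "threshold")
  attr(out, "method") <- attr(mask, "method")
  out
}

#' Segment a movie into measured domains
#'
#' @param movie a \linkS4class{Movie}.
#' @param params a \linkS4class{SegParams}.
#' @param frames frame indices to segment (default: all).
#' @return Row-bound \code{\link{segmentFrame}} results; attribute
#'   \code{"thresholds"} records the threshold used per frame.
#' @export
segmentMovie <- function(movie, params = SegParams(), frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nFrames(movie))
  res <- lapply(frames, function(t)
    segmentFrame(getFrame(movie, t), params, frameIndex = t,
                 pixelSizeUm = pixelSize(movie)))
  out <- do.call(rbind, res)
  attr(out, "thresholds") <- data.frame(frame = frames,
    threshold = vapply(res, attr, 0, "threshold"),
    method = vapply(res, attr, "", "method"))
  out
}
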