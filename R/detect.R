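#' A-trous B3-spline wavelet decomposition
#'
#' Undecimated wavelet transform of a frame with the separable B3-spline
#' kernel (1/16)[1, 4, 6, 4, 1], hole spacing doubling at each level and
#' mirror boundary handling. Detail plane l is the difference of
#' successive smoothings; the input is recovered exactly as the sum of
#' all detail planes plus the residual.
#'
#' @param frame numeric matrix.
#' @param nLevels number of levels (>= 1); the image must be larger than
#'   the dilated kernel support at the deepest level.
#' @return A list with \code{details} (list of \code{nLevels} matrices)
#'   and \code{residual} (the final smooth plane).
#' @examples
#' x <- matrix(rnorm(32 * 32), 32)
#' d <- atrousDecompose(x, 3)
#' max(abs(Reduce(`+`, d$details) + d$residual - x))  # ~0
#' @export
atrousDecompose <- function(frame, nLevels = 3) {
  stopifnot(is.matrix(frame), all(is.finite(frame)), nLevels >= 1)
  support <- 4 * 2^(nLevels - 1) + 1
  if (support > min(dim(frame)))
    stop("image smaller than kernel support at deepest level")
  details <- vector("list", nLevels)
  smooth <- frame
  for (l in seq_len(nLevels)) {
    nxt <- .b3smooth(smooth, spacing = 2^(l - 1))
    details[[l]] <- smooth - nxt
    smooth <- nxt
  }
  list(details = details, residual = smooth)
}

# separable B3-spline smoothing with dilated taps and mirror boundary
.b3smooth <- function(x, spacing) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * as.integer(spacing)
  conv1 <- function(m, n, along) {
    out <- 0
    for (k in seq_along(w)) {
      idx <- .mirrorIndex(seq_len(n) + off[k], n)
      out <- out + w[k] * (if (along == 1) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(x, nrow(x), 1), ncol(x), 2)
}

# mirror (symmetric, edge-pixel-centered) index reflection into 1..n
.mirrorIndex <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n - i, i)
  # a second pass covers offsets up to ~2n (never needed for valid sizes)
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

#' Detect fluorescent spots by wavelet thresholding
#'
#' Hard-thresholds the detail plane at \code{detectionLevel} at
#' \code{kSigma} times a robust noise estimate (median absolute
#' deviation of the plane scaled to the Gaussian sigma, MAD/0.6745).
#' 8-connected supra-threshold components of at least \code{minAreaPx}
#' pixels become spots; the subpixel position is the intensity-weighted
#' centroid of the component computed on the detail plane (which is
#' background-free by construction), and the reported intensity is the
#' component's summed detail-plane signal.
#'
#' @param frame numeric matrix (finite).
#' @param params a \linkS4class{WaveletParams}.
#' @param minAreaPx minimum component area in pixels. The default of 8
#'   is about half the level-2 footprint of a diffraction-limited spot
#'   while sitting above the area of correlated-noise excursions of the
#'   smoothed detail plane, so sub-PSF specks are rejected as noise.
#' @return data.frame with columns \code{id}, \code{row_px},
#'   \code{col_px} (0-based subpixel), \code{intensity}. May be empty.
#' @export
detectSpots <- function(frame, params = WaveletParams(), minAreaPx = 8) {
  stopifnot(is(params, "WaveletParams"))
  validObject(params)
  dec <- atrousDecompose(frame, params@nLevels)
  plane <- dec$details[[params@detectionLevel]]
  sigma <- stats::mad(plane)
  thr <- params@kSigma * sigma
  mask <- plane > thr
  lab <- .labelComponents8(mask)
  nLab <- max(lab)
  empty <- data.frame(id = integer(), row_px = numeric(),
                      col_px = numeric(), intensity = numeric())
  if (nLab == 0L) return(empty)
  areas <- tabulate(lab, nbins = nLab)
  keep <- which(areas >= minAreaPx)
  if (!length(keep)) return(empty)
  idx <- which(lab > 0L)
  labv <- lab[idx]
  wv <- plane[idx]
  rowv <- (idx - 1L) %% nrow(frame)
  colv <- (idx - 1L) %/% nrow(frame)
  sumW <- rowsum(wv, labv)[, 1]
  cenR <- rowsum(wv * rowv, labv)[, 1] / sumW
  cenC <- rowsum(wv * colv, labv)[, 1] / sumW
  data.frame(id = seq_along(keep), row_px = cenR[keep],
             col_px = cenC[keep], intensity = sumW[keep])
}

#' Detect spots in every frame of a movie
#'
#' @param movie a \linkS4class{Movie}.
#' @param params a \linkS4class{WaveletParams}.
#' @param minAreaPx minimum component area (see \code{\link{detectSpots}}).
#' @return data.frame with columns \code{frame}, \code{id},
#'   \code{row_px}, \code{col_px}, \code{intensity}; ids unique within
#'   each frame.
#' @export
detectMovie <- function(movie, params = WaveletParams(), minAreaPx = 8) {
  res <- lapply(seq_len(nFrames(movie)), function(t) {
    s <- detectSpots(getFrame(movie, t), params, minAreaPx)
    if (nrow(s)) cbind(frame = t, s) else
      data.frame(frame = integer(), id = integer(), row_px = numeric(),
                 col_px = numeric(), intensity = numeric())
  })
  do.call(rbind, res)
}
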