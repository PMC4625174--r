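#' @useDynLib raftrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Movie: a calibrated time-lapse intensity stack
#'
#' Container for a single-channel fluorescence time-lapse: a numeric
#' \code{H x W x T} array plus the physical calibration needed to convert
#' pixel displacements into speeds (pixel size in micrometres, frame
#' interval in seconds). Row/column pixel coordinates used throughout the
#' package are 0-based with the origin at the top-left corner and rows
#' increasing downwards.
#'
#' @slot data numeric array, \code{height x width x n_frames}.
#' @slot pixelSizeUm pixel size, micrometres per pixel.
#' @slot frameIntervalS frame interval, seconds.
#' @export
setClass("Movie",
  representation(data = "array", pixelSizeUm = "numeric",
                 frameIntervalS = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array (height x width x frames)")
    else if (dim(object@data)[3] < 1L)
      msg <- c(msg, "movie must contain at least one frame")
    if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0)
      msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(object@frameIntervalS) != 1L ||
        !is.finite(object@frameIntervalS) || object@frameIntervalS <= 0)
      msg <- c(msg, "frameIntervalS must be a single positive number")
    if (anyNA(object@data))
      msg <- c(msg, "movie data must not contain NA")
    if (length(msg)) msg else TRUE
  })

#' Construct a Movie
#'
#' @param data numeric \code{H x W x T} array (a matrix is promoted to a
#'   single-frame stack).
#' @param pixelSizeUm pixel size, micrometres per pixel.
#' @param frameIntervalS frame interval, seconds.
#' @return A \linkS4class{Movie}.
#' @examples
#' m <- Movie(array(0, c(32, 32, 5)), pixelSizeUm = 0.16, frameIntervalS = 2)
#' nFrames(m)
#' @export
Movie <- function(data, pixelSizeUm, frameIntervalS) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("Movie", data = data, pixelSizeUm = pixelSizeUm,
      frameIntervalS = frameIntervalS)
}

#' Simulation parameters for synthetic receptor-domain movies
#'
#' Holds the acquisition geometry, motion model and camera noise model of
#' the synthetic time-lapse generator. Defaults emulate the study
#' conditions: 60 frames at a 2 s lapse (a 2-minute movie), 0.16 um
#' pixels, punctate Gaussian spots of peak signal-to-background-noise
#' ratio ~8, and free diffusion at 0.01 um^2/s. In the clustered
#' condition a \code{clusterFraction} share of spots is bound to cluster
#' centers: a captured spot keeps its free-motion step size but is
#' tethered, its excursions reflected into a disc of
#' \code{clusterTetherRadiusUm} around its center, emulating confined
#' motion of receptor clusters at treatment steady state.
#'
#' @slot nFrames number of frames (>= 2).
#' @slot frameIntervalS frame interval, seconds.
#' @slot pixelSizeUm pixel size, micrometres per pixel.
#' @slot heightPx,widthPx image size in pixels.
#' @slot nSpots number of fluorescent spots.
#' @slot diffusionUm2S diffusion coefficient, um^2/s.
#' @slot clusterFraction fraction of spots bound to cluster centers, in [0,1].
#' @slot nClusterCenters number of cluster centers.
#' @slot clusterCaptureRadiusUm capture zone radius around a center, um.
#' @slot clusterTetherRadiusUm tether radius confining a captured spot, um.
#' @slot psfSigmaPx Gaussian PSF standard deviation, pixels.
#' @slot spotAmplitude peak intensity of one rendered spot.
#' @slot backgroundLevel constant background intensity.
#' @slot readNoiseSd Gaussian read noise standard deviation.
#' @slot seed RNG seed; identical parameters give bit-identical output.
#' @export
setClass("SimParams",
  representation(nFrames = "integer", frameIntervalS = "numeric",
    pixelSizeUm = "numeric", heightPx = "integer", widthPx = "integer",
    nSpots = "integer", diffusionUm2S = "numeric",
    clusterFraction = "numeric", nClusterCenters = "integer",
    clusterCaptureRadiusUm = "numeric", clusterTetherRadiusUm = "numeric",
    psfSigmaPx = "numeric", spotAmplitude = "numeric",
    backgroundLevel = "numeric", readNoiseSd = "numeric",
    seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
    pos <- c(frameIntervalS = object@frameIntervalS,
             pixelSizeUm = object@pixelSizeUm,
             heightPx = object@heightPx, widthPx = object@widthPx,
             nClusterCenters = object@nClusterCenters,
             clusterCaptureRadiusUm = object@clusterCaptureRadiusUm,
             clusterTetherRadiusUm = object@clusterTetherRadiusUm,
             psfSigmaPx = object@psfSigmaPx)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
      msg <- c(msg, paste0(paste(bad, collapse = ", "), " must be > 0"))
    if (!is.finite(object@diffusionUm2S) || object@diffusionUm2S < 0)
      msg <- c(msg, "diffusionUm2S must be finite and >= 0")
    if (object@nSpots < 1L) msg <- c(msg, "nSpots must be >= 1")
    if (!is.finite(object@clusterFraction) || object@clusterFraction < 0 ||
        object@clusterFraction > 1)
      msg <- c(msg, "clusterFraction must be in [0, 1]")
    if (object@spotAmplitude < 0 || object@backgroundLevel < 0 ||
        object@readNoiseSd < 0)
      msg <- c(msg, "intensity parameters must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct simulation parameters
#'
#' @param nFrames,frameIntervalS,pixelSizeUm,heightPx,widthPx,nSpots
#'   acquisition geometry; see \linkS4class{SimParams}.
#' @param diffusionUm2S,clusterFraction,nClusterCenters,clusterCaptureRadiusUm,clusterTetherRadiusUm
#'   motion model; see \linkS4class{SimParams}.
#' @param psfSigmaPx,spotAmplitude,backgroundLevel,readNoiseSd optics and
#'   camera noise.
#' @param seed RNG seed.
#' @return A \linkS4class{SimParams}.
#' @examples
#' cfg <- SimParams(nSpots = 20, seed = 7)
#' @export
SimParams <- function(nFrames = 60, frameIntervalS = 2, pixelSizeUm = 0.16,
                      heightPx = 256, widthPx = 256, nSpots = 60,
                      diffusionUm2S = 0.01, clusterFraction = 0.8,
                      nClusterCenters = 20, clusterCaptureRadiusUm = 0.5,
                      clusterTetherRadiusUm = 0.25, psfSigmaPx = 1.3,
                      spotAmplitude = 90, backgroundLevel = 100,
                      readNoiseSd = 5, seed = 1) {
  new("SimParams", nFrames = as.integer(nFrames),
      frameIntervalS = frameIntervalS, pixelSizeUm = pixelSizeUm,
      heightPx = as.integer(heightPx), widthPx = as.integer(widthPx),
      nSpots = as.integer(nSpots), diffusionUm2S = diffusionUm2S,
      clusterFraction = clusterFraction,
      nClusterCenters = as.integer(nClusterCenters),
      clusterCaptureRadiusUm = clusterCaptureRadiusUm,
      clusterTetherRadiusUm = clusterTetherRadiusUm,
      psfSigmaPx = psfSigmaPx, spotAmplitude = spotAmplitude,
      backgroundLevel = backgroundLevel, readNoiseSd = readNoiseSd,
      seed = as.integer(seed))
}

#' Segmentation parameters for domain morphometrics
#'
#' @slot backgroundRadiusPx rolling-ball (disc opening) radius, pixels.
#' @slot unsharpRadiusPx Gaussian radius of the unsharp mask, pixels.
#' @slot unsharpAmount unsharp strength, in (0, 2].
#' @slot threshold numeric intensity threshold, or the string
#'   \code{"otsu"} for automatic selection (flagged in output metadata).
#' @slot minAreaPx minimum component area kept, pixels.
#' @export
setClass("SegParams",
  representation(backgroundRadiusPx = "numeric", unsharpRadiusPx = "numeric",
    unsharpAmount = "numeric", threshold = "ANY", minAreaPx = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@backgroundRadiusPx < 1 || object@unsharpRadiusPx < 1)
      msg <- c(msg, "radii must be >= 1 px")
    if (object@unsharpAmount <= 0 || object@unsharpAmount > 2)
      msg <- c(msg, "unsharpAmount must be in (0, 2]")
    th <- object@threshold
    if (!(identical(th, "otsu") ||
          (is.numeric(th) && length(th) == 1L && is.finite(th))))
      msg <- c(msg, "threshold must be a single finite number or \"otsu\"")
    if (object@minAreaPx < 1L) msg <- c(msg, "minAreaPx must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct segmentation parameters
#'
#' @param backgroundRadiusPx,unsharpRadiusPx,unsharpAmount,threshold,minAreaPx
#'   see \linkS4class{SegParams}.
#' @return A \linkS4class{SegParams}.
#' @export
SegParams <- function(backgroundRadiusPx = 50, unsharpRadiusPx = 25,
                      unsharpAmount = 0.9, threshold = "otsu",
                      minAreaPx = 4) {
  new("SegParams", backgroundRadiusPx = backgroundRadiusPx,
      unsharpRadiusPx = unsharpRadiusPx, unsharpAmount = unsharpAmount,
      threshold = threshold, minAreaPx = as.integer(minAreaPx))
}

#' Wavelet spot-detection parameters
#'
#' Parameters of the a-trous B3-spline wavelet detector: number of
#' decomposition levels, the detail plane used for detection, and the
#' hard-threshold multiplier applied to the robust (MAD-based) noise
#' estimate of that plane.
#'
#' @slot nLevels number of wavelet levels.
#' @slot detectionLevel detail plane index used for detection.
#' @slot kSigma threshold multiplier (threshold = kSigma * sigma-hat).
#' @export
setClass("WaveletParams",
  representation(nLevels = "integer", detectionLevel = "integer",
                 kSigma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nLevels < 1L) msg <- c(msg, "nLevels must be >= 1")
    if (object@detectionLevel < 1L || object@detectionLevel > object@nLevels)
      msg <- c(msg, "detectionLevel must be in 1..nLevels")
    if (!is.finite(object@kSigma) || object@kSigma <= 0)
      msg <- c(msg, "kSigma must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct wavelet detection parameters
#'
#' @param nLevels,detectionLevel,kSigma see \linkS4class{WaveletParams}.
#' @return A \linkS4class{WaveletParams}.
#' @export
WaveletParams <- function(nLevels = 3, detectionLevel = 2, kSigma = 3) {
  new("WaveletParams", nLevels = as.integer(nLevels),
      detectionLevel = as.integer(detectionLevel), kSigma = kSigma)
}

#' Track-linking parameters
#'
#' The linker admits a frame-to-frame link only if it implies a speed of
#' at most \code{maxSpeedUmMin} (default 42 um/min); every spot may
#' alternatively terminate (death) or start (birth) at cost
#' \code{nonlinkCostFactor} times the squared maximum displacement, so
#' any admissible link is preferred to a birth/death pair.
#'
#' @slot maxSpeedUmMin speed cap, micrometres per minute.
#' @slot pixelSizeUm pixel size, micrometres per pixel.
#' @slot frameIntervalS frame interval, seconds.
#' @slot nonlinkCostFactor birth/death cost factor (dimensionless).
#' @export
setClass("LinkParams",
  representation(maxSpeedUmMin = "numeric", pixelSizeUm = "numeric",
    frameIntervalS = "numeric", nonlinkCostFactor = "numeric"),
  validity = function(object) {
    v <- c(maxSpeedUmMin = object@maxSpeedUmMin,
           pixelSizeUm = object@pixelSizeUm,
           frameIntervalS = object@frameIntervalS,
           nonlinkCostFactor = object@nonlinkCostFactor)
    bad <- names(v)[!is.finite(v) | v <= 0]
    if (length(bad)) paste0(paste(bad, collapse = ", "), " must be > 0")
    else TRUE
  })

#' Construct linking parameters
#'
#' @param maxSpeedUmMin,pixelSizeUm,frameIntervalS,nonlinkCostFactor see
#'   \linkS4class{LinkParams}.
#' @return A \linkS4class{LinkParams}.
#' @examples
#' lp <- LinkParams(pixelSizeUm = 0.16, frameIntervalS = 2)
#' maxDispPx(lp)  # 8.75 px
#' @export
LinkParams <- function(maxSpeedUmMin = 42, pixelSizeUm = 0.16,
                       frameIntervalS = 2, nonlinkCostFactor = 1.05) {
  new("LinkParams", maxSpeedUmMin = maxSpeedUmMin,
      pixelSizeUm = pixelSizeUm, frameIntervalS = frameIntervalS,
      nonlinkCostFactor = nonlinkCostFactor)
}

#' Result of a permutation test for a difference of means
#'
#' @slot observedDiff observed mean(x) - mean(y).
#' @slot pValue permutation p-value.
#' @slot nPermutations number of label permutations evaluated.
#' @slot seed RNG seed used (ignored in exhaustive mode).
#' @slot twoSided whether the test was two-sided.
#' @slot exhaustive whether all label assignments were enumerated.
#' @slot nX,nY group sizes.
#' @export
setClass("PermutationResult",
  representation(observedDiff = "numeric", pValue = "numeric",
    nPermutations = "integer", seed = "integer", twoSided = "logical",
    exhaustive = "logical", nX = "integer", nY = "integer"),
  validity = function(object) {
    if (object@pValue <= 0 || object@pValue > 1) "pValue must be in (0, 1]"
    else TRUE
  })

setMethod("show", "Movie", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "Movie: %d frame(s) of %d x %d px | %.4g um/px, %.4g s/frame\n",
    d[3], d[1], d[2], object@pixelSizeUm, object@frameIntervalS))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %d frames @ %.3g s | %d x %d px @ %.3g um/px | %d spots\n",
    object@nFrames, object@frameIntervalS, object@heightPx, object@widthPx,
    object@pixelSizeUm, object@nSpots))
  cat(sprintf(
    "  D = %.3g um^2/s | cluster fraction %.2f (%d centers, tether %.3g um)\n",
    object@diffusionUm2S, object@clusterFraction, object@nClusterCenters,
    object@clusterTetherRadiusUm))
  cat(sprintf("  PSF sigma %.2f px | amp %.3g on bg %.3g, read sd %.3g | seed %d\n",
    object@psfSigmaPx, object@spotAmplitude, object@backgroundLevel,
    object@readNoiseSd, object@seed))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "Permutation test for means (%s-sided%s): diff = %.6g, p = %.6g\n",
    if (object@twoSided) "two" else "one",
    if (object@exhaustive) ", exhaustive" else "",
    object@observedDiff, object@pValue))
  cat(sprintf("  n = %d vs %d, %d permutations, seed %d\n",
              object@nX, object@nY, object@nPermutations, object@seed))
})

#' @rdname Movie-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname Movie-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname Movie-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname Movie-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Movie accessors
#'
#' @param x a \linkS4class{Movie}.
#' @param i frame index (1-based).
#' @return \code{nFrames}: number of frames; \code{pixelSize}: um/px;
#'   \code{frameInterval}: seconds; \code{getFrame}: a numeric matrix.
#' @name Movie-accessors
#' @aliases nFrames pixelSize frameInterval getFrame
NULL

#' @rdname Movie-accessors
setMethod("nFrames", "Movie", function(x) dim(x@data)[3])
#' @rdname Movie-accessors
setMethod("pixelSize", "Movie", function(x) x@pixelSizeUm)
#' @rdname Movie-accessors
setMethod("frameInterval", "Movie", function(x) x@frameIntervalS)
#' @rdname Movie-accessors
setMethod("getFrame", "Movie", function(x, i) x@data[, , i])

#' @rdname PermutationResult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname PermutationResult-accessors
#' @export
setGeneric("observedDiff", function(x) standardGeneric("observedDiff"))

#' PermutationResult accessors
#'
#' @param x a \linkS4class{PermutationResult}.
#' @return \code{pValue}: the permutation p-value; \code{observedDiff}:
#'   the observed difference of means.
#' @name PermutationResult-accessors
#' @aliases pValue observedDiff
NULL

#' @rdname PermutationResult-accessors
setMethod("pValue", "PermutationResult", function(x) x@pValue)
#' @rdname PermutationResult-accessors
setMethod("observedDiff", "PermutationResult", function(x) x@observedDiff)
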