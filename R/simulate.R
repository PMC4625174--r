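#' Simulate freely diffusing spot trajectories
#'
#' Generates \code{nSpots} Brownian trajectories of \code{nFrames} points
#' each. Per-axis increments are Normal(0, sqrt(2 D dt)) in micrometres,
#' converted to pixels; positions are reflected at the image borders so
#' no track leaves the field. This emulates the untreated condition, in
#' which receptor domains diffuse freely in the membrane.
#'
#' @param cfg a \linkS4class{SimParams}.
#' @return A data.frame with columns \code{track_id}, \code{frame},
#'   \code{row_px}, \code{col_px} (0-based subpixel coordinates).
#' @examples
#' tr <- simulateBrownianTracks(SimParams(nSpots = 5, nFrames = 10))
#' head(tr)
#' @export
simulateBrownianTracks <- function(cfg) {
  stopifnot(is(cfg, "SimParams"))
  validObject(cfg)
  .withSeed(cfg@seed, .brownianTracks(cfg, cfg@nSpots))
}

# core generator; assumes RNG already seeded by the caller
.brownianTracks <- function(cfg, n, ids = seq_len(n)) {
  stepSdPx <- sqrt(2 * cfg@diffusionUm2S * cfg@frameIntervalS) /
    cfg@pixelSizeUm
  H <- cfg@heightPx; W <- cfg@widthPx; T <- cfg@nFrames
  r0 <- runif(n, 0, H - 1)
  c0 <- runif(n, 0, W - 1)
  # n x T coordinate matrices: cumulative sums of Gaussian steps
  rowCumsum <- function(m) {
    cs <- apply(m, 1, cumsum)
    if (is.null(dim(cs))) matrix(cs, ncol = 1L) else t(cs)
  }
  dr <- matrix(rnorm(n * (T - 1), 0, stepSdPx), n, T - 1)
  dc <- matrix(rnorm(n * (T - 1), 0, stepSdPx), n, T - 1)
  rows <- cbind(r0, r0 + rowCumsum(dr))
  cols <- cbind(c0, c0 + rowCumsum(dc))
  data.frame(track_id = rep(ids, each = T),
             frame = rep(seq_len(T), n),
             row_px = as.vector(t(.reflect(rows, 0, H - 1))),
             col_px = as.vector(t(.reflect(cols, 0, W - 1))))
}

# reflect coordinates into [lo, hi] (mirror boundary)
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Simulate clustered/immobilized spot trajectories
#'
#' Emulates the treated condition at clustering steady state: a
#' \code{clusterFraction} share of spots is bound to one of
#' \code{nClusterCenters} anchored cluster domains and co-localizes with
#' it (a fixed offset within the cluster). Each domain jitters as a
#' rigid body: its center moves with the free-diffusion step size but is
#' tethered to its anchor -- excursions are folded back into a disc of
#' \code{clusterTetherRadiusUm} -- so bound spots show confined motion,
#' not a free random walk. The remaining spots diffuse freely as in
#' \code{\link{simulateBrownianTracks}}.
#'
#' @param cfg a \linkS4class{SimParams} with \code{nClusterCenters <
#'   nSpots}.
#' @return A list with \code{tracks} (data.frame as in
#'   \code{\link{simulateBrownianTracks}}) and \code{assignments}, a
#'   data.frame mapping \code{track_id} to \code{center_id} (NA for free
#'   spots) and the center coordinates.
#' @export
simulateClusteredTracks <- function(cfg) {
  stopifnot(is(cfg, "SimParams"))
  validObject(cfg)
  if (cfg@clusterFraction > 0 && cfg@nClusterCenters >= cfg@nSpots)
    stop("nClusterCenters must be smaller than nSpots")
  .withSeed(cfg@seed, {
  n <- cfg@nSpots
  if (cfg@clusterFraction == 0) {
    tracks <- .brownianTracks(cfg, n)
    return(list(tracks = tracks,
                assignments = data.frame(track_id = seq_len(n),
                  center_id = NA_integer_, center_row_px = NA_real_,
                  center_col_px = NA_real_)))
  }
  H <- cfg@heightPx; W <- cfg@widthPx; T <- cfg@nFrames
  tetherPx <- cfg@clusterTetherRadiusUm / cfg@pixelSizeUm
  stepSdPx <- sqrt(2 * cfg@diffusionUm2S * cfg@frameIntervalS) /
    cfg@pixelSizeUm
  nCap <- round(cfg@clusterFraction * n)
  nFree <- n - nCap
  # centers kept clear of the border so tether discs stay in the field
  margin <- min(tetherPx + 2, (min(H, W) - 1) / 4)
  ctrR <- runif(cfg@nClusterCenters, margin, H - 1 - margin)
  ctrC <- runif(cfg@nClusterCenters, margin, W - 1 - margin)
  centerOf <- sample.int(cfg@nClusterCenters, nCap, replace = TRUE)
  # each cluster is an anchored domain that jitters as a rigid body:
  # its center performs tethered diffusion (free-motion step size,
  # excursions folded back into the tether disc around the anchor)
  ctrPath <- lapply(seq_len(cfg@nClusterCenters), function(k) {
    offR <- numeric(T); offC <- numeric(T)
    dR <- rnorm(T - 1, 0, stepSdPx); dC <- rnorm(T - 1, 0, stepSdPx)
    for (t in seq_len(T - 1)) {
      pr <- offR[t] + dR[t]; pc <- offC[t] + dC[t]
      rho <- sqrt(pr^2 + pc^2)
      if (rho > tetherPx) { # radial fold back into the tether disc
        fold <- max(min(2 * tetherPx - rho, tetherPx), 0)
        pr <- pr * fold / max(rho, 1e-12); pc <- pc * fold / max(rho, 1e-12)
      }
      offR[t + 1] <- pr; offC[t + 1] <- pc
    }
    cbind(ctrR[k] + offR, ctrC[k] + offC)
  })
  # captured spots co-localize with their (moving) center: a fixed
  # offset inside the cluster, rigid with the domain
  capTracks <- vector("list", nCap)
  for (s in seq_len(nCap)) {
    th <- runif(1, 0, 2 * pi); rad <- (tetherPx / 2) * sqrt(runif(1))
    path <- ctrPath[[centerOf[s]]]
    capTracks[[s]] <- data.frame(track_id = s, frame = seq_len(T),
      row_px = .reflect(path[, 1] + rad * cos(th), 0, H - 1),
      col_px = .reflect(path[, 2] + rad * sin(th), 0, W - 1))
  }
  tracks <- do.call(rbind, capTracks)
  if (nFree > 0)
    tracks <- rbind(tracks, .brownianTracks(cfg, nFree, ids = nCap + seq_len(nFree)))
  assignments <- data.frame(track_id = seq_len(n),
    center_id = c(centerOf, rep(NA_integer_, nFree)),
    center_row_px = c(ctrR[centerOf], rep(NA_real_, nFree)),
    center_col_px = c(ctrC[centerOf], rep(NA_real_, nFree)))
  list(tracks = tracks, assignments = assignments)
  })
}

#' Render trajectories into a noisy fluorescence movie
#'
#' Each spot is rendered as an isotropic Gaussian of standard deviation
#' \code{psfSigmaPx} and peak \code{spotAmplitude}; overlapping spots
#' sum. A constant \code{backgroundLevel} is added, then (unless
#' \code{noise = FALSE}) Poisson shot noise is applied, Gaussian read
#' noise of sd \code{readNoiseSd} added, and the result rounded and
#' clipped to the 16-bit range. The returned ground truth carries, per
#' frame, an integer label image of the noiseless signal regions at or
#' above 50\% of the single-spot peak (8-connected, labels consecutive
#' in raster order).
#'
#' @param tracks data.frame with \code{track_id}, \code{frame},
#'   \code{row_px}, \code{col_px}; coordinates must lie inside the field.
#' @param cfg a \linkS4class{SimParams}.
#' @param noise apply the camera noise model (default TRUE).
#' @return A list with \code{movie} (a \linkS4class{Movie}) and
#'   \code{groundTruth}: \code{trueTracks}, and \code{labelStack}
#'   (integer \code{H x W x T} array).
#' @export
renderMovie <- function(tracks, cfg, noise = TRUE) {
  stopifnot(is(cfg, "SimParams"))
  H <- cfg@heightPx; W <- cfg@widthPx; T <- cfg@nFrames
  if (nrow(tracks) > 0 &&
      (any(tracks$row_px < 0 | tracks$row_px > H - 1) ||
       any(tracks$col_px < 0 | tracks$col_px > W - 1)))
    stop("track coordinates outside image bounds")
  sig <- cfg@psfSigmaPx
  halo <- ceiling(4 * sig)
  signal <- array(0, c(H, W, T))
  byFrame <- split(tracks, tracks$frame)
  for (fname in names(byFrame)) {
    t <- as.integer(fname)
    fr <- byFrame[[fname]]
    plane <- matrix(0, H, W)
    for (s in seq_len(nrow(fr))) {
      r0 <- fr$row_px[s]; c0 <- fr$col_px[s]
      ri <- max(1, floor(r0 + 1 - halo)):min(H, ceiling(r0 + 1 + halo))
      ci <- max(1, floor(c0 + 1 - halo)):min(W, ceiling(c0 + 1 + halo))
      g <- cfg@spotAmplitude *
        exp(-((ri - 1 - r0)^2) / (2 * sig^2)) %o%
        exp(-((ci - 1 - c0)^2) / (2 * sig^2))
      plane[ri, ci] <- plane[ri, ci] + g
    }
    signal[, , t] <- plane
  }
  labelStack <- array(0L, c(H, W, T))
  for (t in seq_len(T))
    labelStack[, , t] <- .labelComponents8(signal[, , t] >= 0.5 * cfg@spotAmplitude)
  img <- signal + cfg@backgroundLevel
  if (noise) {
    img <- .withSeed(cfg@seed + 1L, {
      noisy <- array(rpois(length(img), lambda = pmax(img, 0)), dim(img)) +
        array(rnorm(length(img), 0, cfg@readNoiseSd), dim(img))
      round(pmin(pmax(noisy, 0), 65535))
    })
  }
  if (all(img >= 65535))
    warning("all pixels saturated; check spotAmplitude/backgroundLevel")
  list(movie = Movie(img, cfg@pixelSizeUm, cfg@frameIntervalS),
       groundTruth = list(trueTracks = tracks, labelStack = labelStack))
}

#' Simulate a complete movie for one experimental condition
#'
#' Convenience wrapper: generates trajectories for the requested
#' condition and renders them.
#'
#' @param cfg a \linkS4class{SimParams}.
#' @param condition \code{"brownian"} (free diffusion, untreated-like) or
#'   \code{"clustered"} (tethered clusters, treated-like).
#' @param noise apply the camera noise model.
#' @return As \code{\link{renderMovie}}, with the cluster
#'   \code{assignments} added to the ground truth for the clustered
#'   condition.
#' @examples
#' sim <- simulateMovie(SimParams(nSpots = 10, heightPx = 64, widthPx = 64,
#'                                nFrames = 5))
#' sim$movie
#' @export
simulateMovie <- function(cfg, condition = c("brownian", "clustered"),
                          noise = TRUE) {
  condition <- match.arg(condition)
  if (condition == "brownian") {
    tracks <- simulateBrownianTracks(cfg)
    out <- renderMovie(tracks, cfg, noise = noise)
  } else {
    sim <- simulateClusteredTracks(cfg)
    out <- renderMovie(sim$tracks, cfg, noise = noise)
    out$groundTruth$assignments <- sim$assignments
  }
  out
}

#' Simulate a scintillation count pair for the efflux assay
#'
#' Splits \code{totalCounts} between the media and cell compartments with
#' media counts ~ Binomial(totalCounts, trueFraction), mimicking
#' radiolabeled-cholesterol partitioning at a given true efflux fraction.
#'
#' @param trueFraction true efflux fraction in [0, 1].
#' @param totalCounts total scintillation counts (> 0).
#' @param seed RNG seed.
#' @return A list with \code{countsMedia} and \code{countsCells}.
#' @examples
#' simulateEffluxCounts(0.3, 1e6, seed = 1)
#' @export
simulateEffluxCounts <- function(trueFraction, totalCounts, seed = 1) {
  stopifnot(trueFraction >= 0, trueFraction <= 1, totalCounts > 0)
  media <- .withSeed(seed,
    rbinom(1, size = as.integer(totalCounts), prob = trueFraction))
  list(countsMedia = media, countsCells = as.integer(totalCounts) - media)
}
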