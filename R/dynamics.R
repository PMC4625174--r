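#' Frame-to-frame step displacements of a track
#'
#' @param track data.frame with columns \code{row_px}, \code{col_px},
#'   one row per frame, ordered by frame; at least two points.
#' @return Numeric vector of Euclidean step lengths in pixels.
#' @examples
#' tr <- data.frame(row_px = c(0, 3, 3), col_px = c(0, 0, 4))
#' stepDisplacements(tr)  # 3, 4
#' @export
stepDisplacements <- function(track) {
  if (nrow(track) < 2L) stop("track must have at least two points")
  sqrt(diff(track$row_px)^2 + diff(track$col_px)^2)
}

#' Mean speed of a track in micrometres per minute
#'
#' Mean frame-to-frame step length converted to physical units:
#' \code{mean(steps) * pixelSizeUm / (frameIntervalS / 60)}.
#'
#' @param track as in \code{\link{stepDisplacements}}.
#' @param pixelSizeUm pixel size, um/px.
#' @param frameIntervalS frame interval, s.
#' @return Speed in um/min.
#' @examples
#' tr <- data.frame(row_px = 0:5, col_px = 0)
#' meanSpeed(tr, 0.16, 2)  # 4.8 um/min
#' @export
meanSpeed <- function(track, pixelSizeUm, frameIntervalS) {
  stopifnot(pixelSizeUm > 0, frameIntervalS > 0)
  mean(stepDisplacements(track)) * pixelSizeUm / (frameIntervalS / 60)
}

#' Confinement ratio rho of a track
#'
#' The ratio of the head-to-tail distance (first point to end point) to
#' the total distance traveled along the trajectory. Values near 1
#' indicate directed, linear motion; values near 0 indicate confined or
#' random motion (a path returning exactly to its start gives 0).
#'
#' @param track as in \code{\link{stepDisplacements}}; total path length
#'   must be positive (strictly stationary tracks are removed beforehand
#'   by \code{\link{stationaryFilter}}).
#' @return rho, dimensionless, in [0, 1].
#' @examples
#' trackRho(data.frame(row_px = 0:9, col_px = 0))         # 1
#' trackRho(data.frame(row_px = c(0, 1, 1, 0, 0),
#'                     col_px = c(0, 0, 1, 1, 0)))        # 0
#' @export
trackRho <- function(track) {
  steps <- stepDisplacements(track)
  path <- sum(steps)
  if (path == 0) stop("rho undefined for a zero-path-length track")
  n <- nrow(track)
  net <- sqrt((track$row_px[n] - track$row_px[1])^2 +
              (track$col_px[n] - track$col_px[1])^2)
  net / path
}

#' Exclude stationary tracks
#'
#' Retains tracks whose mean frame-to-frame step is at least
#' \code{minMeanStepPx} pixels per frame (boundary inclusive), excluding
#' stationary areas from the motion analysis. Length-1 tracks have no
#' steps and are excluded.
#'
#' @param tracks data.frame with \code{track_id}, \code{row_px},
#'   \code{col_px}.
#' @param minMeanStepPx threshold in px/frame (default 1.0).
#' @return The filtered data.frame.
#' @export
stationaryFilter <- function(tracks, minMeanStepPx = 1.0) {
  if (nrow(tracks) == 0L) return(tracks)
  byTrack <- split(tracks, tracks$track_id)
  keep <- vapply(byTrack, function(tr)
    nrow(tr) >= 2L && mean(stepDisplacements(tr)) >= minMeanStepPx,
    logical(1))
  out <- do.call(rbind, byTrack[keep])
  if (is.null(out)) tracks[0, , drop = FALSE] else
    `rownames<-`(out, NULL)
}

#' Per-track mobility metrics
#'
#' Computes, for every track with at least two points, the step and
#' speed statistics and the confinement ratio rho.
#'
#' @param tracks data.frame with \code{track_id}, \code{frame},
#'   \code{row_px}, \code{col_px}.
#' @param pixelSizeUm pixel size, um/px.
#' @param frameIntervalS frame interval, s.
#' @return data.frame with columns \code{track_id}, \code{n_frames},
#'   \code{mean_step_px}, \code{mean_speed_um_min},
#'   \code{net_displacement_um}, \code{path_length_um}, \code{rho} (NA
#'   for zero-path tracks).
#' @export
trackMetrics <- function(tracks, pixelSizeUm, frameIntervalS) {
  stopifnot(pixelSizeUm > 0, frameIntervalS > 0)
  byTrack <- split(tracks, tracks$track_id)
  byTrack <- byTrack[vapply(byTrack, nrow, 0L) >= 2L]
  rows <- lapply(byTrack, function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    steps <- stepDisplacements(tr)
    path <- sum(steps)
    n <- nrow(tr)
    net <- sqrt((tr$row_px[n] - tr$row_px[1])^2 +
                (tr$col_px[n] - tr$col_px[1])^2)
    data.frame(track_id = tr$track_id[1], n_frames = n,
      mean_step_px = mean(steps),
      mean_speed_um_min = mean(steps) * pixelSizeUm / (frameIntervalS / 60),
      net_displacement_um = net * pixelSizeUm,
      path_length_um = path * pixelSizeUm,
      rho = if (path > 0) net / path else NA_real_)
  })
  if (!length(rows))
    return(data.frame(track_id = integer(), n_frames = integer(),
      mean_step_px = numeric(), mean_speed_um_min = numeric(),
      net_displacement_um = numeric(), path_length_um = numeric(),
      rho = numeric()))
  `rownames<-`(do.call(rbind, rows), NULL)
}

#' Box-plot summary of a condition endpoint
#'
#' Order statistics in the box-plot convention used for condition
#' summaries: median, 25th/75th percentiles (box), 10th/90th percentiles
#' (whiskers), plus the arithmetic mean and sample size. Percentiles use
#' linear interpolation between closest ranks (R quantile type 7).
#'
#' @param values numeric vector, at least one finite value.
#' @return One-row data.frame with columns \code{n}, \code{mean},
#'   \code{median}, \code{q25}, \code{q75}, \code{p10}, \code{p90}.
#' @examples
#' summarizeCondition(1:9)
#' @export
summarizeCondition <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to summarize")
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       type = 7, names = FALSE)
  data.frame(n = length(values), mean = mean(values), median = q[3],
             q25 = q[2], q75 = q[4], p10 = q[1], p90 = q[5])
}
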