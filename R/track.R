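#' Maximum admissible frame-to-frame displacement
#'
#' Converts the physical speed cap into pixels per frame interval:
#' \code{maxSpeedUmMin * (frameIntervalS / 60) / pixelSizeUm}. At the
#' defaults (42 um/min, 2 s, 0.16 um/px) this is 8.75 px.
#'
#' @param params a \linkS4class{LinkParams}.
#' @return Maximum displacement in pixels.
#' @examples
#' maxDispPx(LinkParams(42, 0.16, 2))  # 8.75
#' @export
maxDispPx <- function(params) {
  stopifnot(is(params, "LinkParams"))
  validObject(params)
  params@maxSpeedUmMin * (params@frameIntervalS / 60) / params@pixelSizeUm
}

#' Optimally link spots between two consecutive frames
#'
#' Poses frame-to-frame correspondence as an exact linear assignment
#' problem: linking spot a to spot b costs the squared displacement in
#' px^2 and is admissible only if the displacement does not exceed
#' \code{maxDispPx(params)}; every spot may instead terminate (death) or
#' start (birth) at the alternative cost
#' \code{nonlinkCostFactor * maxDispPx^2}. The returned links minimize
#' the total cost over all admissible partial matchings (solved exactly,
#' not greedily), so each spot appears in at most one link.
#'
#' @param spotsA,spotsB data.frames with columns \code{id},
#'   \code{row_px}, \code{col_px} for frames t and t+1; ids must be
#'   unique within each frame.
#' @param params a \linkS4class{LinkParams}.
#' @return data.frame with columns \code{id_a}, \code{id_b},
#'   \code{cost} (squared displacement, px^2). May be empty.
#' @export
linkFramePair <- function(spotsA, spotsB, params) {
  stopifnot(is(params, "LinkParams"))
  if (anyDuplicated(spotsA$id) || anyDuplicated(spotsB$id))
    stop("duplicate spot ids within a frame")
  na <- nrow(spotsA); nb <- nrow(spotsB)
  emptyLinks <- data.frame(id_a = integer(), id_b = integer(),
                           cost = numeric())
  if (na == 0L || nb == 0L) return(emptyLinks)
  maxd <- maxDispPx(params)
  d2 <- outer(spotsA$row_px, spotsB$row_px, "-")^2 +
        outer(spotsA$col_px, spotsB$col_px, "-")^2
  # small relative tolerance so displacements exactly at the cap link
  admissible <- d2 <= (maxd^2) * (1 + 1e-9)
  alt <- params@nonlinkCostFactor * maxd^2
  BIG <- (alt + maxd^2 + 1) * (na + nb + 1) # inadmissible, finite
  n <- na + nb
  cost <- matrix(BIG, n, n)
  cost[seq_len(na), seq_len(nb)] <- ifelse(admissible, d2, BIG)
  for (i in seq_len(na)) cost[i, nb + i] <- alt       # death of a_i
  for (j in seq_len(nb)) cost[na + j, j] <- alt       # birth of b_j
  cost[na + seq_len(nb), nb + seq_len(na)] <- 0       # slack block
  assign <- .solveLAP(cost)
  ia <- which(assign[seq_len(na)] <= nb)
  ia <- ia[admissible[cbind(ia, assign[ia])]]
  if (!length(ia)) return(emptyLinks)
  jb <- assign[ia]
  out <- data.frame(id_a = spotsA$id[ia], id_b = spotsB$id[jb],
                    cost = d2[cbind(ia, jb)])
  out[order(out$id_a), , drop = FALSE]
}

#' Assemble tracks from per-frame-pair links
#'
#' Chains frame-pair links into gap-free tracks; spots with no incoming
#' link start a new track and spots with no outgoing link end one, so
#' unlinked spots become length-1 tracks and no track ever spans a frame
#' gap (gap closing is deliberately not performed). Track ids are
#' assigned in order of (first frame, first spot id).
#'
#' @param links list of link data.frames (as returned by
#'   \code{\link{linkFramePair}}), named by the earlier frame index of
#'   each consecutive pair.
#' @param spots data.frame of all spots with columns \code{frame},
#'   \code{id} and any measurement columns.
#' @return The \code{spots} data.frame with a \code{track_id} column
#'   prepended, ordered by (track_id, frame).
#' @export
buildTracks <- function(links, spots) {
  stopifnot(all(c("frame", "id") %in% names(spots)))
  frames <- sort(unique(spots$frame))
  trackOf <- new.env(hash = TRUE, parent = emptyenv())
  nextId <- 0L
  spots <- spots[order(spots$frame, spots$id), , drop = FALSE]
  trackCol <- integer(nrow(spots))
  rowsOf <- split(seq_len(nrow(spots)), spots$frame)
  for (f in frames) {
    # incoming links from frame f-1
    lk <- links[[as.character(f - 1L)]]
    incoming <- new.env(hash = TRUE, parent = emptyenv())
    if (!is.null(lk) && nrow(lk)) {
      if (anyDuplicated(lk$id_a) || anyDuplicated(lk$id_b))
        stop("conflicting links: a spot appears in two links")
      for (k in seq_len(nrow(lk)))
        assign(as.character(lk$id_b[k]),
               get(paste0(f - 1L, ":", lk$id_a[k]), envir = trackOf),
               envir = incoming)
    }
    for (r in rowsOf[[as.character(f)]]) {
      idc <- as.character(spots$id[r])
      if (exists(idc, envir = incoming, inherits = FALSE)) {
        tid <- get(idc, envir = incoming)
      } else {
        nextId <- nextId + 1L
        tid <- nextId
      }
      trackCol[r] <- tid
      assign(paste0(f, ":", idc), tid, envir = trackOf)
    }
  }
  out <- cbind(track_id = trackCol, spots)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Link all frames of a spot table into tracks
#'
#' Runs \code{\link{linkFramePair}} on every consecutive frame pair and
#' assembles the result with \code{\link{buildTracks}}. Frames with no
#' detected spots break all tracks crossing them (no gap closing).
#'
#' @param spots data.frame from \code{\link{detectMovie}}.
#' @param params a \linkS4class{LinkParams}.
#' @return As \code{\link{buildTracks}}.
#' @export
linkMovie <- function(spots, params) {
  if (nrow(spots) == 0L)
    return(cbind(track_id = integer(), spots))
  byFrame <- split(spots, spots$frame)
  frames <- sort(as.integer(names(byFrame)))
  links <- list()
  for (f in frames) {
    a <- byFrame[[as.character(f)]]
    b <- byFrame[[as.character(f + 1L)]]
    if (!is.null(b))
      links[[as.character(f)]] <- linkFramePair(a, b, params)
  }
  buildTracks(links, spots)
}

#' Filter tracks by lifetime
#'
#' Retains tracks observed in at least \code{minFrames} frames. The
#' default of 5 reads the inclusion rule "a lifetime of over four
#' frames" as five or more track points.
#'
#' @param tracks data.frame with a \code{track_id} column (one row per
#'   spot).
#' @param minFrames minimum number of frames (track points) retained.
#' @return The filtered data.frame.
#' @export
lifetimeFilter <- function(tracks, minFrames = 5) {
  if (nrow(tracks) == 0L) return(tracks)
  len <- table(tracks$track_id)
  keep <- names(len)[len >= minFrames]
  tracks[as.character(tracks$track_id) %in% keep, , drop = FALSE]
}
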