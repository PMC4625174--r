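# Independent oracles and small fixture builders used across the suite.

# Brute-force minimum-cost partial matching between two spot sets under
# the speed cap, with birth/death alternatives: recursion over all
# admissible matchings. Independent of the assignment solver.
bruteForceLinkCost <- function(a, b, params) {
  maxd2 <- maxDispPx(params)^2 * (1 + 1e-9)
  alt <- params@nonlinkCostFactor * maxDispPx(params)^2
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 && nb == 0) return(0)
  d2 <- outer(a$row_px, b$row_px, "-")^2 + outer(a$col_px, b$col_px, "-")^2
  best <- Inf
  rec <- function(i, usedB, cost) {
    if (cost >= best) return()
    if (i > na) { best <<- min(best, cost + alt * sum(!usedB)); return() }
    rec(i + 1L, usedB, cost + alt) # a_i unmatched (death)
    if (nb > 0) for (j in which(!usedB)) if (d2[i, j] <= maxd2) {
      usedB[j] <- TRUE
      rec(i + 1L, usedB, cost + d2[i, j])
      usedB[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nb), 0)
  best
}

# total assignment cost implied by a linker output (links + non-links)
linkSolutionCost <- function(links, na, nb, params) {
  alt <- params@nonlinkCostFactor * maxDispPx(params)^2
  sum(links$cost) + alt * (na - nrow(links) + nb - nrow(links))
}

# Independent 8-connected labeling by queue-based flood fill.
floodFillLabel8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% H + 1L; c <- (p - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        nr <- r + dr; nc <- c + dc
        if (nr >= 1 && nr <= H && nc >= 1 && nc <= W) {
          q <- nr + (nc - 1L) * H
          if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

# Direct (non-separable) B3-spline smoothing with explicit dilated 2-D
# kernel and mirror boundary, written independently of the package.
directB3Smooth <- function(x, spacing) {
  k <- c(1, 4, 6, 4, 1) / 16
  off <- (-2:2) * spacing
  H <- nrow(x); W <- ncol(x)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  out <- matrix(0, H, W)
  for (a in 1:5) for (b in 1:5) {
    ri <- refl(seq_len(H) + off[a], H)
    ci <- refl(seq_len(W) + off[b], W)
    out <- out + k[a] * k[b] * x[ri, ci]
  }
  out
}

# Render a single frame containing spots at given (row, col) positions.
spotFrame <- function(positions, cfg, noise = TRUE) {
  tracks <- data.frame(track_id = seq_len(nrow(positions)), frame = 1L,
                       row_px = positions[, 1], col_px = positions[, 2])
  cfg@nFrames <- 2L # renderer is happiest with the generic path
  tracks <- rbind(tracks, transform(tracks, frame = 2L))
  renderMovie(tracks, cfg, noise = noise)
}

# Greedy nearest-neighbour matching of detections to ground truth.
matchDetections <- function(det, truth, radius = 2) {
  if (nrow(det) == 0 || nrow(truth) == 0)
    return(list(tp = 0, fp = nrow(det), fn = nrow(truth), pairs = NULL))
  d <- sqrt(outer(det$row_px, truth$row_px, "-")^2 +
            outer(det$col_px, truth$col_px, "-")^2)
  pairs <- NULL
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (!is.finite(d[m]) || d[m] > radius) break
    pairs <- rbind(pairs, cbind(det = m[1], truth = m[2], dist = d[m]))
    d[m[1], ] <- Inf; d[, m[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  tp <- if (is.null(pairs)) 0 else nrow(pairs)
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp, pairs = pairs)
}
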