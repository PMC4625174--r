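test_that("zero diffusion gives perfectly stationary tracks", {
  cfg <- SimParams(nSpots = 5, nFrames = 10, diffusionUm2S = 0, seed = 3)
  tr <- simulateBrownianTracks(cfg)
  for (id in unique(tr$track_id)) {
    t1 <- tr[tr$track_id == id, ]
    expect_equal(diff(t1$row_px), rep(0, 9))
    expect_equal(diff(t1$col_px), rep(0, 9))
  }
})

test_that("mean squared 2-D step matches the Brownian closed form 4*D*dt", {
  cfg <- SimParams(nSpots = 500, nFrames = 60, diffusionUm2S = 0.01,
                   frameIntervalS = 2, seed = 11)
  tr <- simulateBrownianTracks(cfg)
  sq <- unlist(lapply(split(tr, tr$track_id), function(t1)
    (diff(t1$row_px)^2 + diff(t1$col_px)^2) * cfg@pixelSizeUm^2))
  expect_lt(abs(mean(sq) - 4 * 0.01 * 2) / (4 * 0.01 * 2), 0.05)
})

test_that("MSD slope over the first 10 lags recovers the diffusion coefficient", {
  cfg <- SimParams(nSpots = 300, nFrames = 60, diffusionUm2S = 0.01, seed = 21)
  tr <- simulateBrownianTracks(cfg)
  byTrack <- split(tr, tr$track_id)
  lags <- 1:10
  msd <- vapply(lags, function(L) {
    mean(unlist(lapply(byTrack, function(t1) {
      n <- nrow(t1)
      ((t1$row_px[(1 + L):n] - t1$row_px[1:(n - L)])^2 +
       (t1$col_px[(1 + L):n] - t1$col_px[1:(n - L)])^2) * cfg@pixelSizeUm^2
    })))
  }, numeric(1))
  slope <- coef(lm(msd ~ I(lags * cfg@frameIntervalS)))[2]
  expect_lt(abs(slope / 4 - 0.01) / 0.01, 0.10)
})

test_that("identical simulation parameters give bit-identical output", {
  cfg <- SimParams(nSpots = 10, nFrames = 10, seed = 9, heightPx = 64,
                   widthPx = 64, nClusterCenters = 3)
  expect_identical(simulateBrownianTracks(cfg), simulateBrownianTracks(cfg))
  s1 <- simulateClusteredTracks(cfg)
  s2 <- simulateClusteredTracks(cfg)
  expect_identical(s1, s2)
  m1 <- renderMovie(s1$tracks, cfg)
  m2 <- renderMovie(s2$tracks, cfg)
  expect_identical(m1$movie@data, m2$movie@data)
  expect_identical(m1$groundTruth$labelStack, m2$groundTruth$labelStack)
})

test_that("invalid motion parameters are rejected", {
  expect_error(SimParams(diffusionUm2S = -1), "diffusionUm2S")
  expect_error(SimParams(diffusionUm2S = NaN), "diffusionUm2S")
  expect_error(SimParams(nFrames = 1), "nFrames")
  expect_error(SimParams(clusterFraction = 1.2), "clusterFraction")
  expect_error(simulateClusteredTracks(
    SimParams(nSpots = 5, nClusterCenters = 5)), "nClusterCenters")
})

test_that("clustered mode with fraction 0 reduces to free diffusion", {
  cfg <- SimParams(nSpots = 8, nFrames = 12, clusterFraction = 0, seed = 5)
  s <- simulateClusteredTracks(cfg)
  expect_identical(s$tracks, simulateBrownianTracks(cfg))
  expect_true(all(is.na(s$assignments$center_id)))
})

test_that("fully clustered spots stay confined at their centers", {
  cfg <- SimParams(nSpots = 30, nFrames = 30, clusterFraction = 1,
                   nClusterCenters = 6, seed = 13,
                   clusterCaptureRadiusUm = 100) # capture zone >> field
  s <- simulateClusteredTracks(cfg)
  tetherPx <- cfg@clusterTetherRadiusUm / cfg@pixelSizeUm
  for (id in unique(s$tracks$track_id)) {
    t1 <- s$tracks[s$tracks$track_id == id, ]
    a <- s$assignments[s$assignments$track_id == id, ]
    d <- sqrt((t1$row_px - a$center_row_px)^2 +
              (t1$col_px - a$center_col_px)^2)
    # rigid offset within tether/2 plus tethered center within tether
    expect_true(all(d <= 1.5 * tetherPx + 1e-9))
  }
  # confined jitter is slower than free diffusion with the same D
  free <- simulateBrownianTracks(cfg)
  stepMed <- function(tr) median(unlist(lapply(split(tr, tr$track_id),
    function(t1) sqrt(diff(t1$row_px)^2 + diff(t1$col_px)^2))))
  expect_lt(stepMed(s$tracks), stepMed(free))
})

test_that("most clustered spots end within the capture radius of a center", {
  cfg <- SimParams(nSpots = 100, nFrames = 20, clusterFraction = 0.8,
                   nClusterCenters = 10, seed = 17)
  s <- simulateClusteredTracks(cfg)
  capPx <- cfg@clusterCaptureRadiusUm / cfg@pixelSizeUm
  last <- s$tracks[s$tracks$frame == cfg@nFrames, ]
  ctr <- unique(s$assignments[!is.na(s$assignments$center_id),
                              c("center_row_px", "center_col_px")])
  dmin <- apply(last, 1, function(p)
    min(sqrt((as.numeric(p["row_px"]) - ctr$center_row_px)^2 +
             (as.numeric(p["col_px"]) - ctr$center_col_px)^2)))
  expect_gte(sum(dmin <= capPx), 70)
})

test_that("clustered median per-frame step is below the Brownian one", {
  stepMed <- function(tr) median(unlist(lapply(split(tr, tr$track_id),
    function(t1) sqrt(diff(t1$row_px)^2 + diff(t1$col_px)^2))))
  for (seed in 1:5) {
    cfg <- SimParams(nSpots = 50, nFrames = 30, clusterFraction = 0.8,
                     seed = seed)
    expect_lt(stepMed(simulateClusteredTracks(cfg)$tracks),
              stepMed(simulateBrownianTracks(cfg)))
  }
})

test_that("an empty field renders to background plus noise", {
  cfg <- SimParams(nSpots = 1, nFrames = 3, heightPx = 64, widthPx = 64,
                   seed = 2)
  empty <- data.frame(track_id = integer(), frame = integer(),
                      row_px = numeric(), col_px = numeric())
  out <- renderMovie(empty, cfg)
  noiseSd <- sqrt(cfg@backgroundLevel + cfg@readNoiseSd^2)
  for (t in 1:3)
    expect_lt(abs(mean(out$movie@data[, , t]) - cfg@backgroundLevel),
              3 * noiseSd / sqrt(64 * 64))
})

test_that("a noiseless static spot peaks at its rounded position", {
  cfg <- SimParams(nSpots = 1, nFrames = 3, heightPx = 48, widthPx = 48)
  tr <- data.frame(track_id = 1, frame = 1:3, row_px = 20.3, col_px = 31.8)
  out <- renderMovie(tr, cfg, noise = FALSE)
  for (t in 1:3) {
    pk <- which(out$movie@data[, , t] == max(out$movie@data[, , t]),
                arr.ind = TRUE)
    expect_equal(as.vector(pk[1, ]), c(20 + 1, 32 + 1))
  }
})

test_that("rendering is additive for well-separated spots", {
  cfg <- SimParams(nSpots = 2, nFrames = 2, heightPx = 64, widthPx = 64)
  sep <- 10 * cfg@psfSigmaPx
  p1 <- c(25, 20); p2 <- c(25, 20 + sep)
  both <- spotFrame(rbind(p1, p2), cfg, noise = FALSE)$movie@data[, , 1]
  one <- spotFrame(rbind(p1), cfg, noise = FALSE)$movie@data[, , 1]
  two <- spotFrame(rbind(p2), cfg, noise = FALSE)$movie@data[, , 1]
  bg <- cfg@backgroundLevel * 64 * 64
  expect_lt(abs(sum(both) - (sum(one) + sum(two) - bg)) / sum(both), 0.001)
})

test_that("noiseless total intensity conserves background plus Gaussian masses", {
  cfg <- SimParams(nSpots = 4, nFrames = 2, heightPx = 96, widthPx = 96)
  pos <- cbind(c(20, 40, 60, 75), c(25, 55, 30, 70)) # interior spots
  out <- spotFrame(pos, cfg, noise = FALSE)$movie@data[, , 1]
  expected <- cfg@backgroundLevel * 96 * 96 +
    4 * cfg@spotAmplitude * 2 * pi * cfg@psfSigmaPx^2
  expect_lt(abs(sum(out) - expected) / expected, 0.005)
})

test_that("every rendered spot has a ground-truth track and labels are consecutive", {
  cfg <- SimParams(nSpots = 12, nFrames = 6, heightPx = 96, widthPx = 96,
                   seed = 8, nClusterCenters = 4)
  sim <- simulateMovie(cfg, "clustered")
  gt <- sim$groundTruth
  expect_equal(sort(unique(gt$trueTracks$track_id)), 1:12)
  expect_equal(unname(table(gt$trueTracks$track_id)[1]), 6,
               ignore_attr = TRUE)
  for (t in 1:6) {
    labs <- setdiff(unique(as.vector(gt$labelStack[, , t])), 0L)
    if (length(labs)) expect_equal(sort(labs), seq_along(labs))
  }
})

test_that("out-of-bounds coordinates are rejected by the renderer", {
  cfg <- SimParams(nFrames = 2, heightPx = 32, widthPx = 32)
  bad <- data.frame(track_id = 1, frame = 1:2, row_px = c(5, 40), col_px = 5)
  expect_error(renderMovie(bad, cfg), "bounds")
})

test_that("simulated efflux counts recover the true fraction", {
  expect_equal(simulateEffluxCounts(0, 1e4, seed = 1)$countsMedia, 0)
  expect_equal(simulateEffluxCounts(1, 1e4, seed = 1)$countsCells, 0)
  cnt <- simulateEffluxCounts(0.3, 1e6, seed = 4)
  expect_lt(abs(effluxPercent(cnt$countsMedia, cnt$countsCells) - 30), 0.5)
})
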