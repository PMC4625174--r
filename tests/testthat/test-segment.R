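test_that("background subtraction maps a flat field to zero", {
  expect_equal(subtractBackground(matrix(77, 40, 40), 10),
               matrix(0, 40, 40))
})

test_that("background subtraction keeps spot peaks and flattens the far field", {
  cfg <- SimParams(nFrames = 2, heightPx = 96, widthPx = 96,
                   backgroundLevel = 100, spotAmplitude = 200)
  f <- spotFrame(rbind(c(48, 48)), cfg, noise = FALSE)$movie@data[, , 1]
  b <- subtractBackground(f, 30)
  expect_lt(abs(max(b) - 200) / 200, 0.05)
  far <- b[1:20, 1:20] # > 30 px from the spot
  expect_true(all(abs(far) <= 2))
  expect_true(all(b >= 0))
})

test_that("background subtraction clamps random input at zero", {
  set.seed(1)
  x <- matrix(rnorm(50 * 50, 10, 5), 50, 50)
  expect_gte(min(subtractBackground(x, 8)), 0)
  expect_error(subtractBackground(x, 50), "smaller")
})

test_that("unsharp mask is the identity at amount zero and on flat fields", {
  set.seed(2)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(unsharpMask(x, 5, 0), x)
  expect_equal(unsharpMask(matrix(3, 64, 64), 5, 1), matrix(3, 64, 64))
})

test_that("unsharp mask raises peak-to-surround contrast and preserves the mean", {
  cfg <- SimParams(nFrames = 2, heightPx = 96, widthPx = 96)
  f <- spotFrame(rbind(c(48, 48)), cfg, noise = FALSE)$movie@data[, , 1]
  u <- unsharpMask(f, 25, 0.9)
  ring <- round(5 * cfg@psfSigmaPx)
  contrast <- function(img) img[49, 49] - img[49, 49 + ring]
  expect_gt(contrast(u), contrast(f))
  expect_lt(abs(mean(u) - mean(f)) / mean(f), 0.01)
})

test_that("thresholding produces the expected masks at the extremes", {
  x <- matrix(c(10, 200), 8, 8)
  expect_warning(m <- makeMask(x, 500), "range")
  expect_false(any(m))
  expect_warning(m <- makeMask(x, 10), "range")
  expect_true(all(m))
  m <- makeMask(x, 100)
  expect_identical(as.vector(m), as.vector(x == 200))
  expect_identical(attr(m, "method"), "manual")
})

test_that("otsu thresholding separates a two-level image and is flagged", {
  x <- matrix(10, 20, 20); x[5:10, 5:10] <- 200
  m <- makeMask(x, "otsu")
  expect_identical(attr(m, "method"), "otsu")
  expect_identical(as.vector(m), as.vector(x == 200))
})

test_that("domain measurement matches a constructed square", {
  mask <- matrix(FALSE, 12, 12); mask[4:6, 7:9] <- TRUE
  img <- matrix(0, 12, 12); img[mask] <- 50
  d <- measureDomains(mask, img, SegParams(minAreaPx = 4), frame = 2,
                      pixelSizeUm = 0.5)
  expect_equal(nrow(d), 1)
  expect_equal(d$area_px, 9)
  expect_equal(d$area_um2, 9 * 0.25)
  expect_equal(d$mean_intensity, 50)
  expect_equal(d$centroid_row_px, 4) # 0-based centre of rows 4:6
  expect_equal(d$centroid_col_px, 7)
  expect_equal(d$frame, 2L)
})

test_that("domains below the minimum area are dropped", {
  mask <- matrix(FALSE, 12, 12)
  mask[2:4, 2:4] <- TRUE  # area 9
  mask[9, 9:10] <- TRUE   # area 2
  d <- measureDomains(mask, matrix(1, 12, 12), SegParams(minAreaPx = 4))
  expect_equal(nrow(d), 1)
  expect_equal(d$area_px, 9)
  d0 <- measureDomains(matrix(FALSE, 5, 5), matrix(0, 5, 5))
  expect_equal(nrow(d0), 0)
})

test_that("component areas agree with an independent flood fill", {
  set.seed(33)
  mask <- matrix(runif(60 * 60) < 0.35, 60, 60)
  d <- measureDomains(mask, matrix(1, 60, 60), SegParams(minAreaPx = 1))
  oracle <- floodFillLabel8(mask)
  expect_equal(sort(d$area_px), sort(as.vector(tabulate(oracle[oracle > 0]))))
  expect_equal(sum(d$area_px), sum(mask))
})

test_that("measurements are invariant to component discovery order", {
  set.seed(34)
  mask <- matrix(runif(40 * 40) < 0.3, 40, 40)
  img <- matrix(runif(40 * 40, 0, 10), 40, 40)
  d1 <- measureDomains(mask, img, SegParams(minAreaPx = 2))
  # reversing both axes reverses the raster discovery order
  d2 <- measureDomains(mask[40:1, 40:1], img[40:1, 40:1],
                       SegParams(minAreaPx = 2))
  expect_equal(sort(d1$area_px), sort(d2$area_px))
  expect_equal(sort(d1$mean_intensity), sort(d2$mean_intensity),
               tolerance = 1e-12)
})

test_that("domains are assigned to cells by centroid lookup", {
  mask <- matrix(FALSE, 20, 20)
  mask[2:4, 2:4] <- TRUE; mask[2:4, 15:17] <- TRUE; mask[15:17, 3:5] <- TRUE
  d <- measureDomains(mask, matrix(1, 20, 20), SegParams(minAreaPx = 4))
  cells <- matrix(0L, 20, 20)
  cells[1:10, ] <- 1L; cells[11:20, 1:10] <- 2L
  pc <- domainsPerCell(d, cells)
  expect_equal(pc$n_domains[pc$cell_id == 1], 2)
  expect_equal(pc$n_domains[pc$cell_id == 2], 1)
  expect_equal(nrow(domainsPerCell(d[0, ], cells)), 0)
  onecell <- matrix(1L, 20, 20)
  expect_equal(domainsPerCell(d, onecell)$n_domains, 3)
})

test_that("segmentation recalls every ground-truth domain on a noiseless movie", {
  cfg <- SimParams(nSpots = 20, nFrames = 2, heightPx = 128, widthPx = 128,
                   seed = 6)
  sim <- simulateMovie(cfg, "brownian", noise = FALSE)
  gtLab <- sim$groundTruth$labelStack[, , 1]
  seg <- SegParams(threshold = 0.5 * cfg@spotAmplitude)
  f <- getFrame(sim$movie, 1)
  bgsub <- subtractBackground(f, seg@backgroundRadiusPx)
  mask <- makeMask(bgsub, seg@threshold) # noiseless: threshold raw signal
  det <- floodFillLabel8(mask)
  for (g in setdiff(unique(as.vector(gtLab)), 0L)) {
    if (sum(gtLab == g) < seg@minAreaPx) next
    hits <- setdiff(unique(det[gtLab == g]), 0L)
    expect_equal(length(hits), 1)
    inter <- sum(gtLab == g & det == hits)
    uni <- sum(gtLab == g | det == hits)
    expect_gte(inter / uni, 0.5)
  }
})

test_that("clustered movies show larger, brighter, fewer domains than Brownian ones", {
  wins <- matrix(0, 10, 3)
  segP <- SegParams(threshold = 100)
  for (i in 1:10) {
    cfgA <- SimParams(seed = 200 + i, nFrames = 2)
    a <- segmentFrame(getFrame(simulateMovie(cfgA, "brownian")$movie, 1),
                      segP, pixelSizeUm = cfgA@pixelSizeUm)
    b <- segmentFrame(getFrame(simulateMovie(cfgA, "clustered")$movie, 1),
                      segP, pixelSizeUm = cfgA@pixelSizeUm)
    wins[i, ] <- c(median(b$area_px) > median(a$area_px),
                   mean(b$mean_intensity) > mean(a$mean_intensity),
                   nrow(b) < nrow(a))
  }
  expect_gte(sum(wins[, 1]), 9)
  expect_gte(sum(wins[, 2]), 9)
  expect_gte(sum(wins[, 3]), 9)
})
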