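#' Run the full analysis on one condition's movie
#'
#' Executes the stages in order -- wavelet spot detection, globally
#' optimal frame-pair linking (no gap closing), lifetime filtering,
#' mobility metrics with the stationary exclusion applied to rho, and
#' domain segmentation/morphometrics -- and logs the row count after
#' every filtering stage.
#'
#' @param movie a \linkS4class{Movie}.
#' @param segParams a \linkS4class{SegParams}.
#' @param wavParams a \linkS4class{WaveletParams}.
#' @param linkParams a \linkS4class{LinkParams}; by default derived from
#'   the movie calibration with the standard 42 um/min speed cap.
#' @param minFrames lifetime filter threshold (frames).
#' @param minMeanStepPx stationary filter threshold (px/frame).
#' @param applyStationaryToSpeed also exclude stationary tracks from the
#'   speed endpoint (default FALSE: the exclusion applies to rho only).
#' @param segmentFrames frame indices to segment (default: all).
#' @param cellMask optional integer cell label matrix for per-cell domain
#'   counts; without it, domains are counted per frame (one field = one
#'   observational unit).
#' @param outDir optional directory; when given, writes
#'   \code{spots.csv}, \code{tracks.csv}, \code{track_metrics.csv},
#'   \code{domains.csv} and \code{run_log.csv} there.
#' @return A list with \code{domains}, \code{domainCounts},
#'   \code{spots}, \code{tracks}, \code{metrics} (speed endpoint, after
#'   the lifetime filter), \code{rhoMetrics} (after lifetime and
#'   stationary filters), \code{log} (stage row counts) and
#'   \code{params} (the resolved analysis parameters, used as a
#'   confound guard by \code{\link{compareConditions}}).
#' @export
runCondition <- function(movie, segParams = SegParams(),
                         wavParams = WaveletParams(), linkParams = NULL,
                         minFrames = 5, minMeanStepPx = 1.0,
                         applyStationaryToSpeed = FALSE,
                         segmentFrames = NULL, cellMask = NULL,
                         outDir = NULL) {
  stopifnot(is(movie, "Movie"))
  if (is.null(linkParams))
    linkParams <- LinkParams(pixelSizeUm = pixelSize(movie),
                             frameIntervalS = frameInterval(movie))
  spots <- detectMovie(movie, wavParams)
  tracks <- linkMovie(spots, linkParams)
  kept <- lifetimeFilter(tracks, minFrames)
  speedTracks <- if (applyStationaryToSpeed)
    stationaryFilter(kept, minMeanStepPx) else kept
  rhoTracks <- stationaryFilter(kept, minMeanStepPx)
  metrics <- trackMetrics(speedTracks, pixelSize(movie),
                          frameInterval(movie))
  rhoMetrics <- trackMetrics(rhoTracks, pixelSize(movie),
                             frameInterval(movie))
  domains <- segmentMovie(movie, segParams, frames = segmentFrames)
  domainCounts <- if (is.null(cellMask)) {
    tab <- table(domains$frame)
    data.frame(frame = as.integer(names(tab)), n_domains = as.integer(tab))
  } else domainsPerCell(domains, cellMask)
  log <- data.frame(
    stage = c("spots", "tracks", "lifetime_filtered",
              "stationarity_filtered", "domains"),
    rows = c(nrow(spots), length(unique(tracks$track_id)),
             length(unique(kept$track_id)),
             length(unique(rhoTracks$track_id)), nrow(domains)))
  params <- list(segParams = segParams, wavParams = wavParams,
                 linkParams = linkParams, minFrames = minFrames,
                 minMeanStepPx = minMeanStepPx,
                 applyStationaryToSpeed = applyStationaryToSpeed)
  out <- list(domains = domains, domainCounts = domainCounts,
              spots = spots, tracks = tracks, metrics = metrics,
              rhoMetrics = rhoMetrics, log = log, params = params)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTableCsv(spots, file.path(outDir, "spots.csv"))
    writeTableCsv(tracks, file.path(outDir, "tracks.csv"))
    writeTableCsv(metrics, file.path(outDir, "track_metrics.csv"))
    writeTableCsv(domains, file.path(outDir, "domains.csv"))
    writeTableCsv(log, file.path(outDir, "run_log.csv"))
  }
  out
}

#' Compare two processed conditions
#'
#' Runs the permutation test for means on the five condition endpoints
#' -- domain area and domain brightness (first segmented frame of each
#' movie, matching the convention of reporting domains present in the
#' first image of a series), domains per cell/field, per-track mean
#' speed, and per-track rho -- and produces box-plot style summaries for
#' each. Both conditions must have been processed with identical
#' analysis parameters; a mismatch is an error, as it would confound the
#' comparison.
#'
#' @param a,b results of \code{\link{runCondition}} for the two
#'   conditions (a = reference/untreated, b = treated); observed
#'   differences are mean(a) - mean(b).
#' @param nPermutations permutations per endpoint test.
#' @param seed base RNG seed (offset per endpoint).
#' @param twoSided two-sided tests (default).
#' @return A list of class \code{"RunReport"}: per-endpoint
#'   \code{test} (a \linkS4class{PermutationResult}), \code{summaryA},
#'   \code{summaryB}, and \code{n}; plus \code{params} and a
#'   \code{timestamp}.
#' @export
compareConditions <- function(a, b, nPermutations = 10000, seed = 1,
                              twoSided = TRUE) {
  if (!identical(a$params, b$params))
    stop("conditions were processed with different analysis parameters")
  firstA <- a$domains[a$domains$frame == min(a$domains$frame), ]
  firstB <- b$domains[b$domains$frame == min(b$domains$frame), ]
  endpoints <- list(
    domain_area = list(x = firstA$area_um2, y = firstB$area_um2),
    domain_brightness = list(x = firstA$mean_intensity,
                             y = firstB$mean_intensity),
    domains_per_cell = list(x = a$domainCounts$n_domains,
                            y = b$domainCounts$n_domains),
    speed = list(x = a$metrics$mean_speed_um_min,
                 y = b$metrics$mean_speed_um_min),
    rho = list(x = a$rhoMetrics$rho, y = b$rhoMetrics$rho))
  report <- list()
  for (k in seq_along(endpoints)) {
    e <- endpoints[[k]]
    nm <- names(endpoints)[k]
    report[[nm]] <- list(
      test = permutationTestMeans(e$x, e$y, nPermutations = nPermutations,
                                  seed = seed + k, twoSided = twoSided),
      summaryA = summarizeCondition(e$x),
      summaryB = summarizeCondition(e$y),
      n = c(a = length(e$x), b = length(e$y)))
  }
  report$params <- a$params
  report$timestamp <- format(Sys.time(), tz = "UTC")
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Condition comparison (permutation tests for means)\n")
  for (nm in setdiff(names(x), c("params", "timestamp"))) {
    e <- x[[nm]]
    cat(sprintf("  %-18s diff = %10.4g  p = %-8.4g  (n = %d vs %d)\n",
                nm, observedDiff(e$test), pValue(e$test),
                e$n["a"], e$n["b"]))
  }
  invisible(x)
}

#' Read or write an experiment configuration
#'
#' Experiment configurations are plain YAML mappings; a configuration
#' written by \code{writeExperimentConfig} reads back identical, and
#' every \code{\link{runExperiment}} call writes the resolved
#' configuration next to its results.
#'
#' @param path YAML file path.
#' @return \code{readExperimentConfig}: the configuration as a named
#'   list.
#' @export
readExperimentConfig <- function(path) yaml::read_yaml(path)

#' @rdname readExperimentConfig
#' @param cfg configuration list.
#' @export
writeExperimentConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Default experiment configuration
#'
#' @param seed base seed for both simulated conditions.
#' @return A configuration list accepted by \code{\link{runExperiment}}.
#' @export
defaultExperimentConfig <- function(seed = 1) {
  sim <- SimParams(seed = seed)
  simList <- list(n_frames = sim@nFrames, frame_interval_s = sim@frameIntervalS,
    pixel_size_um = sim@pixelSizeUm, height_px = sim@heightPx,
    width_px = sim@widthPx, n_spots = sim@nSpots,
    diffusion_um2_s = sim@diffusionUm2S,
    cluster_fraction = sim@clusterFraction,
    n_cluster_centers = sim@nClusterCenters,
    cluster_capture_radius_um = sim@clusterCaptureRadiusUm,
    cluster_tether_radius_um = sim@clusterTetherRadiusUm,
    psf_sigma_px = sim@psfSigmaPx, spot_amplitude = sim@spotAmplitude,
    background_level = sim@backgroundLevel, read_noise_sd = sim@readNoiseSd)
  list(seed = seed,
    condition_a = c(list(condition = "brownian"), simList),
    condition_b = c(list(condition = "clustered"), simList),
    segmentation = list(background_radius_px = 50, unsharp_radius_px = 25,
      unsharp_amount = 0.9, threshold = 100, min_area_px = 4),
    wavelet = list(n_levels = 3, detection_level = 2, k_sigma = 3),
    linking = list(max_speed_um_min = 42, nonlink_cost_factor = 1.05),
    dynamics = list(min_frames = 5, min_mean_step_px = 1.0,
      apply_stationary_to_speed = FALSE),
    stats = list(n_permutations = 10000, two_sided = TRUE))
}

.simParamsFromList <- function(x, seed) {
  SimParams(nFrames = x$n_frames, frameIntervalS = x$frame_interval_s,
    pixelSizeUm = x$pixel_size_um, heightPx = x$height_px,
    widthPx = x$width_px, nSpots = x$n_spots,
    diffusionUm2S = x$diffusion_um2_s,
    clusterFraction = x$cluster_fraction,
    nClusterCenters = x$n_cluster_centers,
    clusterCaptureRadiusUm = x$cluster_capture_radius_um,
    clusterTetherRadiusUm = x$cluster_tether_radius_um,
    psfSigmaPx = x$psf_sigma_px, spotAmplitude = x$spot_amplitude,
    backgroundLevel = x$background_level, readNoiseSd = x$read_noise_sd,
    seed = seed)
}

#' Run a complete two-condition simulated experiment
#'
#' Simulates both conditions from the configuration, analyzes each with
#' identical parameters, and compares them. When \code{outDir} is given,
#' all stage tables, the comparison report and the resolved
#' configuration are written there.
#'
#' @param cfg configuration list (see
#'   \code{\link{defaultExperimentConfig}}).
#' @param outDir optional output directory.
#' @return A list with \code{conditionA}, \code{conditionB} (results of
#'   \code{\link{runCondition}}) and \code{report} (a
#'   \code{\link{compareConditions}} report).
#' @export
runExperiment <- function(cfg, outDir = NULL) {
  seed <- cfg$seed
  mk <- function(cnd, offset) {
    sp <- .simParamsFromList(cnd, seed + offset)
    simulateMovie(sp, condition = cnd$condition)
  }
  simA <- mk(cfg$condition_a, 0L)
  simB <- mk(cfg$condition_b, 100000L)
  segParams <- SegParams(cfg$segmentation$background_radius_px,
    cfg$segmentation$unsharp_radius_px, cfg$segmentation$unsharp_amount,
    cfg$segmentation$threshold, cfg$segmentation$min_area_px)
  wavParams <- WaveletParams(cfg$wavelet$n_levels,
    cfg$wavelet$detection_level, cfg$wavelet$k_sigma)
  run <- function(sim, sub) {
    lp <- LinkParams(cfg$linking$max_speed_um_min,
      pixelSize(sim$movie), frameInterval(sim$movie),
      cfg$linking$nonlink_cost_factor)
    runCondition(sim$movie, segParams, wavParams, lp,
      minFrames = cfg$dynamics$min_frames,
      minMeanStepPx = cfg$dynamics$min_mean_step_px,
      applyStationaryToSpeed = cfg$dynamics$apply_stationary_to_speed,
      outDir = if (is.null(outDir)) NULL else file.path(outDir, sub))
  }
  a <- run(simA, "condition_a")
  b <- run(simB, "condition_b")
  report <- compareConditions(a, b,
    nPermutations = cfg$stats$n_permutations, seed = seed,
    twoSided = cfg$stats$two_sided)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeExperimentConfig(cfg, file.path(outDir, "config.yaml"))
    tests <- do.call(rbind, lapply(
      setdiff(names(report), c("params", "timestamp")), function(nm)
        data.frame(endpoint = nm,
                   observed_diff = observedDiff(report[[nm]]$test),
                   p_value = pValue(report[[nm]]$test),
                   n_a = report[[nm]]$n["a"], n_b = report[[nm]]$n["b"])))
    writeTableCsv(tests, file.path(outDir, "comparison.csv"))
    jsonlite::write_json(
      lapply(setdiff(names(report), c("params", "timestamp")),
             function(nm) list(endpoint = nm,
               observed_diff = observedDiff(report[[nm]]$test),
               p_value = pValue(report[[nm]]$test))),
      file.path(outDir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  }
  list(conditionA = a, conditionB = b, report = report)
}

#' Permutation test on a two-column CSV
#'
#' Reads a CSV with columns \code{value} and \code{group} (exactly two
#' groups), runs \code{\link{permutationTestMeans}}, and optionally
#' writes a small JSON report.
#'
#' @param inPath input CSV path.
#' @param outPath optional JSON report path.
#' @param ... passed to \code{\link{permutationTestMeans}}.
#' @return A \linkS4class{PermutationResult}.
#' @export
permutationTestCsv <- function(inPath, outPath = NULL, ...) {
  d <- utils::read.csv(inPath)
  stopifnot(all(c("value", "group") %in% names(d)))
  g <- unique(d$group)
  if (length(g) != 2L) stop("expected exactly two groups")
  res <- permutationTestMeans(d$value[d$group == g[1]],
                              d$value[d$group == g[2]], ...)
  if (!is.null(outPath))
    jsonlite::write_json(list(observed_diff = res@observedDiff,
      p_value = res@pValue, n_permutations = res@nPermutations,
      seed = res@seed), outPath, auto_unbox = TRUE, digits = NA)
  res
}
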