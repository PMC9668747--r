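# End-to-end orchestration: synthesize -> process -> classify -> simulate
# chains -> plateau model -> compare, with every stage's output persisted
# so each reported number is re-derivable from the run directory.

#' Default end-to-end run configuration
#'
#' All stage parameters with their defaults; any entry can be overridden
#' via \code{...}.  A run is reproducible from its saved configuration
#' alone.
#'
#' @param ... overrides of the listed fields.
#' @return a named list
#' @export
defaultRunConfig <- function(...) {
  config <- list(
    schemaVersion = 1L,
    environment = "A",
    nLaps = 60L,
    nCells = 200L,
    fracPlace = 0.4,
    nAxonChains = 100L,
    nChains = 2000L,
    nNeurons = 10000L,
    nShuffles = 100L,
    mergeThreshold = 0.45,
    enhancedTuning = FALSE,
    seedBehavior = 101L, seedCa1 = 102L, seedEc3 = 103L,
    seedChains = 104L, seedPlateau = 105L, seedClassify = 106L)
  over <- list(...)
  bad <- setdiff(names(over), names(config))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  config[names(over)] <- over
  config
}

#' Run the full analysis end to end
#'
#' Stages: synthetic behaviour; CA1 traces -> dF/F -> transient detection ->
#' activity map -> place-cell classification; EC3 axonal ROIs (driven by a
#' small chain population) -> noise-correlation merge; full chain
#' population -> plateau model with the session's running dwell profile ->
#' model/data density comparison.  Every stage writes its artefacts into
#' \code{outDir}; a manifest records the configuration and package version.
#' A failed stage leaves the completed artefacts in place and propagates
#' the error with the stage name.
#'
#' @param config list from \code{\link{defaultRunConfig}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list of the stage results
#' @export
runEndToEnd <- function(config = defaultRunConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(config, file.path(outDir, "run_config.yaml"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " [environment=", config$environment, "]", call. = FALSE))
  }

  env <- config$environment
  behavior <- stage("behavior", generateBehavior(
    config$nLaps, env, seed = config$seedBehavior))
  writeBehaviorCsv(behavior, file.path(outDir, "behavior.csv"))

  ca1 <- stage("synth_ca1", generateCa1Traces(
    behavior, nCells = config$nCells, fracPlace = config$fracPlace,
    seed = config$seedCa1))
  ca1$traces <- stage("dff", computeDff(ca1$traces))
  ca1Map <- stage("maps", buildActivityMap(ca1$traces, behavior))
  writeActivityMapCsv(ca1Map, file.path(outDir, "ca1_map.csv"))
  records <- stage("place_cells", classifyPlaceCells(
    ca1Map, ca1$traces, behavior, nShuffles = config$nShuffles,
    seed = config$seedClassify))
  write.csv(records, file.path(outDir, "place_field_records.csv"),
            row.names = FALSE)
  write.csv(ca1$truth, file.path(outDir, "ground_truth_ca1.csv"),
            row.names = FALSE)

  axonChains <- stage("ec3_chains_small", simulateChains(
    chainConfig("uniform", nChains = as.integer(config$nAxonChains),
                nLaps = as.integer(config$nLaps)),
    seed = config$seedChains))
  ec3 <- stage("synth_ec3", generateEc3Rois(axonChains, behavior,
                                            seed = config$seedEc3))
  ec3$traces <- stage("dff_ec3", computeDff(ec3$traces))
  grouping <- stage("merge", mergeRoisByNoiseCorrelation(
    ec3$traces, threshold = config$mergeThreshold))
  write.csv(data.frame(roi = seq_along(grouping@roiToAxon),
                       axon = grouping@roiToAxon,
                       true_axon = ec3$truth$axonId),
            file.path(outDir, "axon_grouping.csv"), row.names = FALSE)

  # scale the modulated/homogeneous split with the population size, keeping
  # the default 70/30 (A) and 92.5/7.5 (B) proportions and the env-A
  # requirement of an integer chain count per phase
  nCh <- as.integer(config$nChains)
  nHomA <- nCh - 100L * (nCh * 7L %/% 1000L)
  nHomB <- max(1L, as.integer(round(nCh * 0.075)))
  chains <- stage("chains", simulateChains(
    chainConfig(if (env == "habituation") "uniform" else env,
                enhancedTuning = isTRUE(config$enhancedTuning),
                nChains = nCh, nHomogeneousA = nHomA,
                nHomogeneousB = nHomB),
    seed = config$seedChains))
  met <- stage("chain_metrics", chainMetrics(mapTimeToSpace(chains)))
  write.csv(met, file.path(outDir, "chain_metrics.csv"), row.names = FALSE)

  dwellRaw <- colMeans(occupancy(ca1Map))
  dwell <- stage("plateau", spaceMapping(pmax(dwellRaw, 1e-3)))
  drives <- stage("plateau", simulatePopulationDrive(
    chains, nNeurons = as.integer(config$nNeurons),
    seed = config$seedPlateau))
  cal <- stage("plateau", calibrateThreshold(drives))
  plateau <- stage("plateau", crossingProfile(drives, cal$threshold, dwell))
  density50 <- tabulate(records$peakBin[records$isPlaceCell], 50L)
  comparison <- tryCatch(
    compareProfiles(plateau, density50,
                    zone = zoneBinsAround((ca1Map@rewardBin - 0.5) * 3.6)),
    error = function(e) list(R = NA_real_, error = conditionMessage(e)))
  summaryJson <- list(
    environment = env,
    n_place_cells = sum(records$isPlaceCell),
    n_units = nrow(records),
    recruited_fraction = cal$recruitedFraction,
    threshold = cal$threshold,
    model_data_R = comparison$R,
    crossing_profile = crossingProfileOf(plateau),
    place_cell_density_50bin = density50)
  jsonlite::write_json(summaryJson, file.path(outDir, "plateau_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(package = "ec3btsp",
                   version = as.character(utils::packageVersion("ec3btsp")),
                   config = config,
                   environment = env,
                   cue_position_cm = behavior@cuePosition,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(behavior = behavior, records = records, truth = ca1$truth,
                 grouping = grouping, ec3Truth = ec3$truth,
                 chainMetrics = met, plateau = plateau,
                 comparison = comparison))
}

#' Summarise a completed run directory
#'
#' Re-reads the persisted stage outputs and produces a human-readable
#' summary (returned list + markdown table written to summary.md).  Missing
#' artefacts are reported by name.
#'
#' @param runDir directory written by \code{\link{runEndToEnd}}.
#' @return the summary list
#' @export
reportSummary <- function(runDir) {
  need <- c("run_config.yaml", "place_field_records.csv",
            "chain_metrics.csv", "plateau_summary.json", "manifest.json")
  missing <- need[!file.exists(file.path(runDir, need))]
  if (length(missing))
    stop("missing artefacts: ", paste(missing, collapse = ", "))
  records <- read.csv(file.path(runDir, "place_field_records.csv"))
  met <- read.csv(file.path(runDir, "chain_metrics.csv"))
  pj <- jsonlite::read_json(file.path(runDir, "plateau_summary.json"),
                            simplifyVector = TRUE)
  nPc <- sum(records$isPlaceCell)
  lines <- c("| quantity | value |", "|---|---|",
             sprintf("| units analysed | %d |", nrow(records)),
             sprintf("| place cells | %d |", nPc))
  out <- list(nUnits = nrow(records), nPlaceCells = nPc,
              recruitedFraction = pj$recruited_fraction,
              modelDataR = pj$model_data_R)
  if (nPc > 0) {
    pc <- records[records$isPlaceCell, ]
    out$medianPeakShift <- median(pc$peakShift, na.rm = TRUE)
    out$meanWidthCm <- mean(pc$widthCm, na.rm = TRUE)
    lines <- c(lines,
      sprintf("| median peak shift (cm) | %.2f |", out$medianPeakShift),
      sprintf("| mean field width (cm) | %.1f |", out$meanWidthCm))
  } else {
    lines <- c(lines, "| plasticity signatures | skipped (no place cells) |")
  }
  out$medianOddEven <- median(met$oddEvenCorr, na.rm = TRUE)
  out$fracWellCorrelated <- mean(met$wellCorrelated, na.rm = TRUE)
  lines <- c(lines,
    sprintf("| median chain odd-even corr | %.3f |", out$medianOddEven),
    sprintf("| fraction well-correlated chains | %.3f |",
            out$fracWellCorrelated),
    sprintf("| recruited fraction | %.3f |", pj$recruited_fraction),
    sprintf("| model-data density R | %s |",
            if (is.null(pj$model_data_R) ||
                !is.finite(suppressWarnings(as.numeric(pj$model_data_R))))
              "NA" else sprintf("%.3f", as.numeric(pj$model_data_R))))
  writeLines(lines, file.path(runDir, "summary.md"))
  jsonlite::write_json(out, file.path(runDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}
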