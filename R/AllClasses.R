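#' @import methods
#' @importFrom stats cor cor.test quantile sd runif rnorm rpois rlnorm median lm coef setNames
#' @importFrom utils head tail read.csv write.csv
NULL

#' BehaviorSession: treadmill behaviour for one imaging session
#'
#' Time-indexed record of an animal's behaviour on a circular belt
#' (default length 180 cm), sampled on the imaging frame grid.  Position is
#' piecewise non-decreasing within a lap and wraps to 0 at lap boundaries;
#' velocity is the wrap-aware frame-to-frame derivative of position.
#'
#' @slot time numeric, seconds, uniform grid at \code{frameRate}.
#' @slot position numeric, cm in [0, beltLength).
#' @slot velocity numeric, cm/s, >= 0.
#' @slot lick integer, 0/1 lick event per frame.
#' @slot lapIndex integer, 0-based lap counter per frame.
#' @slot rewardPosition numeric, cm.
#' @slot cuePosition numeric, cm (NA when the environment has no cue).
#' @slot beltLength numeric, cm.
#' @slot environment character, one of "A", "B", "habituation".
#' @slot frameRate numeric, Hz.
#'
#' @exportClass BehaviorSession
setClass("BehaviorSession",
  representation(
    time = "numeric", position = "numeric", velocity = "numeric",
    lick = "integer", lapIndex = "integer",
    rewardPosition = "numeric", cuePosition = "numeric",
    beltLength = "numeric", environment = "character", frameRate = "numeric"
  )
)

setValidity("BehaviorSession", function(object) {
  n <- length(object@time)
  msg <- character()
  if (length(object@position) != n || length(object@velocity) != n ||
      length(object@lick) != n || length(object@lapIndex) != n)
    msg <- c(msg, "time, position, velocity, lick and lapIndex must share length")
  if (any(object@position < 0) || any(object@position >= object@beltLength))
    msg <- c(msg, "position must lie in [0, beltLength)")
  if (any(object@velocity < -1e-9))
    msg <- c(msg, "velocity must be non-negative")
  if (!object@environment %in% c("A", "B", "habituation"))
    msg <- c(msg, "environment must be A, B or habituation")
  if (n > 1) {
    dl <- diff(object@lapIndex)
    if (any(!dl %in% c(0L, 1L)))
      msg <- c(msg, "lapIndex must increment by exactly 1 at lap boundaries")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BehaviorSession number of frames
#' @param x,object a \code{BehaviorSession}
#' @export
setMethod("length", "BehaviorSession", function(x) length(x@time))

setMethod("show", "BehaviorSession", function(object) {
  cat("BehaviorSession:", length(object@time), "frames,",
      nLaps(object), "laps, environment", object@environment, "\n")
  cat("  belt", object@beltLength, "cm, reward at", object@rewardPosition,
      "cm, frame rate", round(object@frameRate, 2), "Hz\n")
})

#' ActivityMap: unit x lap x spatial-bin activity tensor
#'
#' Mean dF/F per unit, lap and spatial bin (50 bins of 3.6 cm on a 180-cm
#' belt), built from running frames only (velocity > 2 cm/s), smoothed with a
#' circular three-point boxcar per lap, and rotated so the reward sits in
#' bin 26 (environment A) or bin 24 (environment B).  Occupancy (running
#' seconds per lap and bin) and the binned significant-transient mask are
#' carried alongside.
#'
#' @slot meanDff numeric array [unit, lap, bin].
#' @slot occupancy numeric matrix [lap, bin], seconds of running time.
#' @slot significant logical array [unit, lap, bin].
#' @slot nLaps integer, number of usable laps.
#' @slot rewardBin integer (1-based) aligned reward bin.
#' @slot alignShift integer, circular shift applied to raw bins.
#' @slot binWidth numeric, cm.
#' @slot environment character.
#' @slot excludedLaps integer, laps dropped for lack of running frames.
#'
#' @exportClass ActivityMap
setClass("ActivityMap",
  representation(
    meanDff = "array", occupancy = "matrix", significant = "array",
    nLaps = "integer", rewardBin = "integer", alignShift = "integer",
    binWidth = "numeric", environment = "character", excludedLaps = "integer"
  )
)

setValidity("ActivityMap", function(object) {
  msg <- character()
  d <- dim(object@meanDff)
  if (length(d) != 3) msg <- c(msg, "meanDff must be a 3-d array")
  if (length(d) == 3 && d[3] != ncol(object@occupancy))
    msg <- c(msg, "meanDff and occupancy must agree on bin count")
  if (length(d) == 3 && !all(dim(object@significant) == d))
    msg <- c(msg, "significant mask must match meanDff dimensions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ActivityMap", function(object) {
  d <- dim(object@meanDff)
  cat("ActivityMap:", d[1], "units x", d[2], "laps x", d[3], "bins (",
      object@binWidth, "cm ), env", object@environment,
      ", reward bin", object@rewardBin, "\n")
  if (length(object@excludedLaps))
    cat("  excluded laps:", paste(object@excludedLaps, collapse = ", "), "\n")
})

#' AxonGrouping: partition of EC3 ROIs into putative axons
#'
#' Result of the noise-correlation merge: ROIs whose dF/F traces correlate
#' above the threshold are linked, connected components form axons, and the
#' per-axon trace is the pixel-size-weighted mean of member ROI traces.
#'
#' @slot roiToAxon integer, axon label per ROI (1..nAxons).
#' @slot mergeThreshold numeric, Pearson correlation threshold.
#' @slot mergedDff numeric matrix [axon, frame].
#' @slot axonSize numeric, summed pixel count per axon.
#'
#' @exportClass AxonGrouping
setClass("AxonGrouping",
  representation(roiToAxon = "integer", mergeThreshold = "numeric",
                 mergedDff = "matrix", axonSize = "numeric")
)

setValidity("AxonGrouping", function(object) {
  msg <- character()
  k <- max(object@roiToAxon)
  if (!all(sort(unique(object@roiToAxon)) == seq_len(k)))
    msg <- c(msg, "axon labels must be 1..nAxons with no gaps")
  if (nrow(object@mergedDff) != k)
    msg <- c(msg, "mergedDff must have one row per axon")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AxonGrouping", function(object) {
  cat("AxonGrouping:", length(object@roiToAxon), "ROIs ->",
      nrow(object@mergedDff), "axons (threshold",
      object@mergeThreshold, ")\n")
})

#' ChainConfig: configuration of a two-state Markov-chain population
#'
#' Describes a population of two-state (inactive/active) Markov chains
#' emulating EC3 persistent activity: baseline activation rate
#' \code{p01Base} (per second), inactivation rate \code{p10}, and a
#' spatial-tuning plan in which a subset of chains has its activation rate
#' stepped up to a boost value for a 1-s window at a fixed within-lap phase
#' recurring every lap.
#'
#' @slot nChains integer.
#' @slot dt numeric, time step (s).
#' @slot lapSteps integer, steps per lap (100).
#' @slot nLaps integer, laps retained after burn-in (50).
#' @slot burnIn integer, discarded initial steps (100).
#' @slot p01Base numeric, baseline activation rate (1/s).
#' @slot p10 numeric, inactivation rate (1/s).
#' @slot boostP01 numeric per chain, boosted activation rate (NA = never boosted).
#' @slot phaseStep integer per chain, preferred within-lap step in 1..lapSteps
#'   (NA for homogeneous chains); the 1-s boost window ends at this step.
#' @slot boostSteps integer, boost window length in steps (10).
#' @slot environment character, "uniform", "A" or "B".
#' @slot enhanced logical, whether the enhanced-tuning subpopulation is present.
#' @slot zoneCenterStep integer, within-lap step of the salient location
#'   (reward for A, cue for B; NA for uniform).
#'
#' @exportClass ChainConfig
setClass("ChainConfig",
  representation(
    nChains = "integer", dt = "numeric", lapSteps = "integer",
    nLaps = "integer", burnIn = "integer",
    p01Base = "numeric", p10 = "numeric",
    boostP01 = "numeric", phaseStep = "integer",
    boostSteps = "integer", environment = "character",
    enhanced = "logical", zoneCenterStep = "integer"
  )
)

setValidity("ChainConfig", function(object) {
  msg <- character()
  pr <- c(object@p01Base, object@p10,
          object@boostP01[!is.na(object@boostP01)]) * object@dt
  if (any(pr < 0 | pr > 1))
    msg <- c(msg, "per-step transition probabilities must lie in [0, 1]")
  if (length(object@boostP01) != object@nChains ||
      length(object@phaseStep) != object@nChains)
    msg <- c(msg, "boostP01 and phaseStep must have one entry per chain")
  if (any(xor(is.na(object@boostP01), is.na(object@phaseStep))))
    msg <- c(msg, "boostP01 and phaseStep must be NA together")
  ph <- object@phaseStep[!is.na(object@phaseStep)]
  if (length(ph) && (any(ph < 1L) || any(ph > object@lapSteps)))
    msg <- c(msg, "phaseStep must lie in 1..lapSteps")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChainConfig", function(object) {
  nmod <- sum(!is.na(object@boostP01))
  cat("ChainConfig: env", object@environment, "-", object@nChains, "chains (",
      nmod, "modulated,", object@nChains - nmod, "homogeneous ),",
      object@nLaps, "laps x", object@lapSteps, "steps, dt", object@dt, "s\n")
  cat("  P01 base ", object@p01Base, "/s, P10 ", object@p10, "/s",
      if (object@enhanced) ", enhanced tuning on" else "", "\n", sep = "")
})

#' ChainPopulation: simulated binary states of a chain population
#'
#' @slot states integer matrix [chain, step], 0/1, burn-in already removed.
#' @slot config the \code{ChainConfig} that produced it.
#'
#' @exportClass ChainPopulation
setClass("ChainPopulation",
  representation(states = "matrix", config = "ChainConfig"))

setValidity("ChainPopulation", function(object) {
  msg <- character()
  if (!all(object@states %in% c(0L, 1L)))
    msg <- c(msg, "states must be 0/1")
  cfg <- object@config
  if (ncol(object@states) != cfg@nLaps * cfg@lapSteps)
    msg <- c(msg, "states must hold nLaps x lapSteps columns (post burn-in)")
  if (nrow(object@states) != cfg@nChains)
    msg <- c(msg, "states must have one row per chain")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChainPopulation", function(object) {
  cat("ChainPopulation:", nrow(object@states), "chains x",
      ncol(object@states), "steps, env", object@config@environment,
      "; mean active fraction", round(mean(object@states), 3), "\n")
})

#' SpaceMapping: dwell-time profile and step-to-bin assignment
#'
#' Converts within-lap time steps to spatial bins through a dwell-time
#' profile (seconds per bin per lap, summing to the model lap duration).
#' Steps are assigned to bins by cumulative dwell, so a bin holding twice
#' the dwell time receives twice the steps.
#'
#' @slot dwell numeric, seconds per bin per lap.
#' @slot stepBin integer, bin index per within-lap step.
#' @slot nBins integer.
#' @slot dt numeric, step duration (s).
#'
#' @exportClass SpaceMapping
setClass("SpaceMapping",
  representation(dwell = "numeric", stepBin = "integer",
                 nBins = "integer", dt = "numeric"))

setValidity("SpaceMapping", function(object) {
  msg <- character()
  if (length(object@dwell) != object@nBins)
    msg <- c(msg, "dwell must have nBins entries")
  if (any(tabulate(object@stepBin, object@nBins) == 0))
    msg <- c(msg, "every bin must receive at least one step")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpaceMapping", function(object) {
  cat("SpaceMapping:", length(object@stepBin), "steps ->", object@nBins,
      "bins; lap duration", sum(object@dwell), "s\n")
})

#' PlateauResult: plateau-threshold model output
#'
#' Spatial profile of dendritic-plateau initiation probability predicted by
#' thresholding summed EC3 input drive in a population of model CA1 neurons.
#' Each model neuron sums a random 5% of the chain population minus global
#' feedforward inhibition; the threshold is calibrated so that the fraction
#' of neurons with at least one upward crossing matches the observed
#' fraction of CA1 cells gaining a place field in a session (20-25%).
#'
#' @slot nNeurons integer.
#' @slot nInputs integer, excitatory inputs sampled per neuron.
#' @slot inhibitionScale numeric.
#' @slot threshold numeric, drive units.
#' @slot recruitedFraction numeric, fraction of neurons with >= 1 crossing.
#' @slot crossingProfile numeric per bin: crossings / nNeurons under the
#'   supplied dwell profile.
#' @slot crossingProfileConstant numeric per bin: same under constant speed.
#' @slot dwell the \code{SpaceMapping} used.
#'
#' @exportClass PlateauResult
setClass("PlateauResult",
  representation(
    nNeurons = "integer", nInputs = "integer", inhibitionScale = "numeric",
    threshold = "numeric", recruitedFraction = "numeric",
    crossingProfile = "numeric", crossingProfileConstant = "numeric",
    dwell = "SpaceMapping"
  )
)

setValidity("PlateauResult", function(object) {
  msg <- character()
  if (any(object@crossingProfile < 0) || any(!is.finite(object@crossingProfile)))
    msg <- c(msg, "crossingProfile must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlateauResult", function(object) {
  cat("PlateauResult:", object@nNeurons, "model neurons,",
      object@nInputs, "inputs each; threshold",
      round(object@threshold, 3), "-> recruited fraction",
      round(object@recruitedFraction, 3), "\n")
})
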