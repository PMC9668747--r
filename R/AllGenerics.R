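# Accessor generics shared across the package's S4 classes.

#' Number of laps in an object
#' @param x a BehaviorSession, ActivityMap or ChainPopulation
#' @return integer lap count
#' @export
setGeneric("nLaps", function(x) standardGeneric("nLaps"))

#' @rdname nLaps
#' @export
setMethod("nLaps", "BehaviorSession", function(x) max(x@lapIndex) + 1L)

#' @rdname nLaps
#' @export
setMethod("nLaps", "ActivityMap", function(x) x@nLaps)

#' @rdname nLaps
#' @export
setMethod("nLaps", "ChainPopulation", function(x) x@config@nLaps)

#' Chain state matrix
#' @param x a ChainPopulation
#' @return integer matrix [chain, step] of 0/1 states
#' @export
setGeneric("chainStates", function(x) standardGeneric("chainStates"))

#' @rdname chainStates
#' @export
setMethod("chainStates", "ChainPopulation", function(x) x@states)

#' Lap-indexed view of chain states
#'
#' Pure reshape of the state matrix into [chain, lap, within-lap step];
#' flattening it back reproduces the states bit-exactly.
#' @param x a ChainPopulation
#' @return integer array [chain, lap, step]
#' @export
setGeneric("lapView", function(x) standardGeneric("lapView"))

#' @rdname lapView
#' @export
setMethod("lapView", "ChainPopulation", function(x) {
  cfg <- x@config
  arr <- array(0L, c(cfg@nChains, cfg@nLaps, cfg@lapSteps))
  for (l in seq_len(cfg@nLaps)) {
    cols <- ((l - 1L) * cfg@lapSteps + 1L):(l * cfg@lapSteps)
    arr[, l, ] <- x@states[, cols]
  }
  arr
})

#' Mean dF/F tensor of an ActivityMap
#' @param x an ActivityMap
#' @return numeric array [unit, lap, bin]
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "ActivityMap", function(x) x@meanDff)

#' Occupancy matrix of an ActivityMap
#' @param x an ActivityMap
#' @return numeric matrix [lap, bin], running seconds
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname occupancy
#' @export
setMethod("occupancy", "ActivityMap", function(x) x@occupancy)

#' Binned significant-transient mask of an ActivityMap
#' @param x an ActivityMap
#' @return logical array [unit, lap, bin]
#' @export
setGeneric("significantMask", function(x) standardGeneric("significantMask"))

#' @rdname significantMask
#' @export
setMethod("significantMask", "ActivityMap", function(x) x@significant)

#' Crossing profile of a PlateauResult
#' @param x a PlateauResult
#' @param constantSpeed return the constant-speed reference profile instead
#' @return numeric per-bin crossings / nNeurons
#' @export
setGeneric("crossingProfileOf",
           function(x, constantSpeed = FALSE) standardGeneric("crossingProfileOf"))

#' @rdname crossingProfileOf
#' @export
setMethod("crossingProfileOf", "PlateauResult", function(x, constantSpeed = FALSE) {
  if (constantSpeed) x@crossingProfileConstant else x@crossingProfile
})
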