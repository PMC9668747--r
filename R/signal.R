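# Fluorescence trace processing: dF/F conversion, significant-transient
# detection, noise-correlation ROI merging, and spatial activity maps.

# half-sample mode: repeatedly zoom into the shortest interval holding
# half the remaining data; converges to the densest point (the baseline)
# and is insensitive to the transient tail and to the noise scale
halfSampleMode <- function(x) {
  x <- sort(x)
  while (length(x) > 3L) {
    n2 <- ceiling(length(x) / 2)
    widths <- x[n2:length(x)] - x[seq_len(length(x) - n2 + 1L)]
    i <- which.min(widths)
    x <- x[i:(i + n2 - 1L)]
  }
  mean(x)
}

#' Convert raw fluorescence to dF/F
#'
#' Per ROI, the baseline F0 is the mode of the fluorescence distribution
#' and dff = (F - F0)/F0.  The default estimator is the half-sample mode
#' (shortest-half recursion) over the 1st-99th percentile of F, whose
#' precision scales with the baseline noise itself; \code{method =
#' "histogram"} uses a fixed 100-bin histogram instead (centre of the
#' tallest bin).  The fixed histogram becomes coarse relative to the
#' baseline noise when large transients stretch the trace range, and the
#' resulting baseline offset corrupts downstream noise-level thresholds,
#' hence the adaptive default.  Near-constant traces fall back to the
#' median.
#'
#' @param traces a \code{\link{RoiTraceSet}} with >= minFrames frames.
#' @param method "shorth" (half-sample mode, default) or "histogram".
#' @param nBreaks histogram bin count for \code{method = "histogram"}.
#' @param minFrames minimum trace length.
#' @return the \code{RoiTraceSet} with a "dff" assay added
#' @examples
#' rts <- RoiTraceSet(matrix(100, 1, 1200), 10L, 30, "ca1_soma")
#' range(dffValues(computeDff(rts)))   # identically 0
#' @export
computeDff <- function(traces, method = c("shorth", "histogram"),
                       nBreaks = 100L, minFrames = 1000L) {
  stopifnot(is(traces, "RoiTraceSet"))
  method <- match.arg(method)
  F <- rawF(traces)
  if (ncol(F) < minFrames)
    stop("traces must have at least ", minFrames, " frames")
  dff <- matrix(0, nrow(F), ncol(F))
  for (i in seq_len(nrow(F))) {
    f <- F[i, ]
    qs <- quantile(f, c(0.01, 0.99), names = FALSE)
    f0 <- if (qs[2] - qs[1] < .Machine$double.eps * max(abs(qs), 1) * 100) {
      median(f)
    } else if (method == "shorth") {
      halfSampleMode(f[f >= qs[1] & f <= qs[2]])
    } else {
      br <- seq(qs[1], qs[2], length.out = nBreaks + 1L)
      counts <- tabulate(findInterval(f, br, rightmost.closed = TRUE,
                                      all.inside = TRUE), nBreaks)
      (br[which.max(counts)] + br[which.max(counts) + 1L]) / 2
    }
    if (!is.finite(f0) || f0 <= 0)
      stop("non-positive baseline F0 estimate for ROI ", i)
    dff[i, ] <- (f - f0) / f0
  }
  assay(traces, "dff", withDimnames = FALSE) <- dff
  validObject(traces)
  traces
}

# noise sd of a dff trace: negative excursions mirrored about zero
noiseSigma <- function(dff) {
  neg <- dff[dff < 0]
  if (!length(neg)) return(0)
  sqrt(mean(neg^2))
}

# transient mask for a matrix of dff traces (rows = units)
transientMaskMatrix <- function(dff, nSigma = 3, onsetSigma = 2,
                                minDuration = 2L) {
  mask <- matrix(FALSE, nrow(dff), ncol(dff))
  for (i in seq_len(nrow(dff))) {
    s <- noiseSigma(dff[i, ])
    if (s == 0)
      stop("zero noise estimate for unit ", i, " (degenerate trace)")
    runs <- trueRuns(dff[i, ] > onsetSigma * s)
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      a <- runs[r, 1]; b <- runs[r, 2]
      if (b - a + 1L >= minDuration && max(dff[i, a:b]) > nSigma * s)
        mask[i, a:b] <- TRUE
    }
  }
  mask
}

#' Detect significant calcium transients
#'
#' Frames are marked significant iff they belong to an excursion of the
#' dF/F trace whose peak exceeds \code{nSigma} (default 3) times the noise
#' standard deviation, estimated from negative dF/F values mirrored about
#' zero (robust to transients).  Excursions are contiguous runs above
#' \code{onsetSigma} x sigma; runs shorter than \code{minDuration} frames
#' are discarded as shot noise.
#'
#' @param traces a \code{\link{RoiTraceSet}} with dff computed, or a
#'   numeric dff matrix [unit, frame].
#' @param nSigma peak threshold in noise sd units.
#' @param onsetSigma excursion onset/offset level in noise sd units.
#' @param minDuration minimum excursion length, frames.
#' @return logical matrix [unit, frame]
#' @export
detectTransients <- function(traces, nSigma = 3, onsetSigma = 2,
                             minDuration = 2L) {
  dff <- if (is.matrix(traces)) traces else dffValues(traces)
  if (is.null(dff)) stop("dff not present; run computeDff first")
  transientMaskMatrix(dff, nSigma, onsetSigma, minDuration)
}

#' Merge EC3 ROIs into axons by noise correlation
#'
#' Computes all pairwise Pearson correlations between ROI dF/F traces,
#' links ROI pairs correlated at or above the threshold, and takes
#' connected components as putative axons (ROIs from one axon share its
#' calcium signal, so they correlate strongly; unrelated ROIs do not).
#' The merged axon trace is the pixel-size-weighted mean of its member
#' ROI traces; a singleton's merged trace equals its own.
#'
#' @param traces a \code{\link{RoiTraceSet}} (modality "ec3_axon") with dff.
#' @param threshold Pearson correlation threshold in (0, 1); default 0.45,
#'   the midpoint of the 0.4-0.5 range used for axonal data.
#' @return an \code{\link{AxonGrouping}}
#' @export
mergeRoisByNoiseCorrelation <- function(traces, threshold = 0.45) {
  stopifnot(is(traces, "RoiTraceSet"))
  if (modality(traces) != "ec3_axon")
    stop("noise-correlation merging applies to EC3 axonal data")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  dff <- dffValues(traces)
  if (is.null(dff)) stop("dff not present; run computeDff first")
  nR <- nrow(dff)
  if (nR < 1) stop("at least one ROI is required")
  sizes <- roiSize(traces)

  # connected components of the correlation graph (union-find)
  parent <- seq_len(nR)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nR > 1) {
    cm <- cor(t(dff))
    for (i in seq_len(nR - 1L)) for (j in (i + 1L):nR) {
      if (cm[i, j] >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(nR), find, integer(1))
  labels <- as.integer(factor(roots, levels = unique(roots)))
  k <- max(labels)
  merged <- matrix(0, k, ncol(dff))
  axonSize <- numeric(k)
  for (a in seq_len(k)) {
    mem <- which(labels == a)
    w <- sizes[mem] / sum(sizes[mem])
    merged[a, ] <- as.numeric(w %*% dff[mem, , drop = FALSE])
    axonSize[a] <- sum(sizes[mem])
  }
  obj <- new("AxonGrouping", roiToAxon = labels, mergeThreshold = threshold,
             mergedDff = merged, axonSize = axonSize)
  validObject(obj)
  obj
}

#' Build a reward-aligned spatial activity map
#'
#' Bins each unit's dF/F into 50 spatial bins (3.6 cm) per lap using only
#' running frames (velocity > 2 cm/s), fills empty bins by circular linear
#' interpolation, smooths each lap with a circular three-point boxcar, and
#' rotates the bins so the reward sits in bin 26 (environment A) or bin 24
#' (environment B).  Running occupancy (seconds per lap and bin) and the
#' binned significant-transient mask are carried alongside.  Laps with no
#' running frames are flagged and excluded.
#'
#' @param x a \code{\link{RoiTraceSet}} with dff, an
#'   \code{\link{AxonGrouping}}, or a dff matrix [unit, frame].
#' @param behavior the matching \code{\link{BehaviorSession}}.
#' @param maxLap use only laps 1..maxLap (default: all).
#' @param significant optional logical matrix [unit, frame]; computed with
#'   \code{\link{detectTransients}} when omitted.
#' @param nBins spatial bin count.
#' @param runningThreshold cm/s.
#' @param align rotate to the environment's reward bin (26 for A, 24 for B).
#' @return an \code{\link{ActivityMap}}
#' @export
buildActivityMap <- function(x, behavior, maxLap = NULL, significant = NULL,
                             nBins = 50L, runningThreshold = 2,
                             align = TRUE) {
  dff <- if (is(x, "RoiTraceSet")) dffValues(x)
         else if (is(x, "AxonGrouping")) x@mergedDff
         else x
  if (is.null(dff)) stop("dff not present; run computeDff first")
  if (ncol(dff) != length(behavior))
    stop("traces and behaviour must share the frame grid")
  if (is.null(significant))
    significant <- transientMaskMatrix(dff)
  nU <- nrow(dff)
  L <- nLaps(behavior)
  if (!is.null(maxLap)) L <- min(L, as.integer(maxLap))
  binW <- behavior@beltLength / nBins

  lap1 <- behavior@lapIndex + 1L
  keep <- lap1 <= L
  running <- behavior@velocity > runningThreshold & keep
  bins <- positionToBin(behavior@position, behavior@beltLength, nBins)
  group <- (lap1 - 1L) * nBins + bins   # lap x bin cell index
  nCells <- L * nBins

  cnt <- tabulate(group[running], nCells)
  sums <- rowsum(t(dff[, running, drop = FALSE]), group[running])
  sigs <- rowsum(t(significant[, running, drop = FALSE]) * 1, group[running])
  idx <- as.integer(rownames(sums))

  meanDff <- array(NA_real_, c(nU, L, nBins))
  sigArr <- array(FALSE, c(nU, L, nBins))
  occ <- matrix(0, L, nBins)
  occ[cbind((idx - 1L) %/% nBins + 1L, (idx - 1L) %% nBins + 1L)] <-
    cnt[idx] / behavior@frameRate

  for (u in seq_len(nU)) {
    m <- matrix(NA_real_, L, nBins)
    m[cbind((idx - 1L) %/% nBins + 1L, (idx - 1L) %% nBins + 1L)] <-
      sums[, u] / cnt[idx]
    s <- matrix(FALSE, L, nBins)
    s[cbind((idx - 1L) %/% nBins + 1L, (idx - 1L) %% nBins + 1L)] <-
      sigs[, u] > 0
    m <- t(apply(m, 1, fillCircularNA))
    meanDff[u, , ] <- boxcar3Rows(m)
    sigArr[u, , ] <- s
  }

  excluded <- which(vapply(seq_len(L), function(l)
    sum(running & lap1 == l) == 0, logical(1)))

  rewardBin <- if (behavior@environment == "B") 24L else 26L
  shift <- 0L
  if (align && behavior@environment != "habituation") {
    rawReward <- positionToBin(behavior@rewardPosition,
                               behavior@beltLength, nBins)
    shift <- alignShiftFor(rawReward, rewardBin, nBins)
    if (shift != 0L) {
      ord <- ((seq_len(nBins) - 1L - shift) %% nBins) + 1L
      meanDff <- meanDff[, , ord, drop = FALSE]
      sigArr <- sigArr[, , ord, drop = FALSE]
      occ <- occ[, ord, drop = FALSE]
    }
  } else {
    rewardBin <- positionToBin(behavior@rewardPosition,
                               behavior@beltLength, nBins)
  }

  obj <- new("ActivityMap", meanDff = meanDff, occupancy = occ,
             significant = sigArr, nLaps = L,
             rewardBin = as.integer(rewardBin), alignShift = shift,
             binWidth = binW, environment = behavior@environment,
             excludedLaps = as.integer(excluded))
  validObject(obj)
  obj
}

#' Per-bin lick-rate and velocity maps
#'
#' Lick rate (licks per second) and mean velocity per spatial bin, on the
#' same 50-bin grid and reward alignment as the activity maps.
#'
#' @param behavior a \code{\link{BehaviorSession}} with >= 1 complete lap.
#' @param nBins bin count.
#' @param align rotate to the environment's reward bin.
#' @return list(lickRate, velocity, occupancySeconds, rewardBin, alignShift)
#' @export
behaviorMaps <- function(behavior, nBins = 50L, align = TRUE) {
  if (nLaps(behavior) < 1) stop("at least one complete lap is required")
  bins <- positionToBin(behavior@position, behavior@beltLength, nBins)
  secs <- tabulate(bins, nBins) / behavior@frameRate
  licks <- as.numeric(rowsum(behavior@lick * 1.0, bins,
                             reorder = TRUE)[, 1])
  lickFull <- numeric(nBins); velFull <- rep(NA_real_, nBins)
  present <- sort(unique(bins))
  lickFull[present] <- licks
  vel <- rowsum(behavior@velocity, bins)[, 1] / tabulate(bins, nBins)[present]
  velFull[present] <- vel
  velFull <- fillCircularNA(velFull)
  lickRate <- ifelse(secs > 0, lickFull / secs, 0)

  rewardBin <- if (behavior@environment == "B") 24L else 26L
  shift <- 0L
  if (align && behavior@environment != "habituation") {
    rawReward <- positionToBin(behavior@rewardPosition,
                               behavior@beltLength, nBins)
    shift <- alignShiftFor(rawReward, rewardBin, nBins)
    ord <- ((seq_len(nBins) - 1L - shift) %% nBins) + 1L
    lickRate <- lickRate[ord]; velFull <- velFull[ord]; secs <- secs[ord]
  } else {
    rewardBin <- positionToBin(behavior@rewardPosition,
                               behavior@beltLength, nBins)
  }
  list(lickRate = lickRate, velocity = velFull, occupancySeconds = secs,
       rewardBin = as.integer(rewardBin), alignShift = shift)
}
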