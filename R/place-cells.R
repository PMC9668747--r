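# Place-cell identification and plasticity-signature metrics.
#
# A unit is a place cell when (i) it has an eventual place field (the
# maximal circularly contiguous run of bins above 20% of the peak mean
# dF/F containing the global peak), (ii) a detectable induction lap
# (first lap with significant field activity confirmed in >= 2 of the 5
# following laps), (iii) spatial information on post-induction laps
# exceeding the 95th percentile of 100 trace shuffles, and (iv) significant
# field activity in > 30% of post-induction laps.

#' Find the eventual place field of a mean activity map
#'
#' Returns the maximal circularly contiguous run of bins whose smoothed
#' mean dF/F exceeds 20\% of the peak, containing the global peak (ties on
#' the peak broken toward the lowest bin index).
#'
#' @param meanMap numeric per-bin smoothed mean dF/F.
#' @param thresholdFrac field threshold as a fraction of the peak.
#' @return list(fieldBins (circular order, starts at the run start),
#'   peakBin, widthCm) or NULL when the map is silent (no positive peak)
#' @export
findEventualField <- function(meanMap, thresholdFrac = 0.2) {
  nBins <- length(meanMap)
  meanMap[is.na(meanMap)] <- 0
  pk <- which.max(meanMap)
  if (meanMap[pk] <= 0) return(NULL)
  above <- meanMap > thresholdFrac * meanMap[pk]
  lo <- pk
  while (above[((lo - 2L) %% nBins) + 1L] && lo != ((pk %% nBins) + 1L))
    lo <- ((lo - 2L) %% nBins) + 1L
  hi <- pk
  while (above[(hi %% nBins) + 1L] && (hi %% nBins) + 1L != lo)
    hi <- (hi %% nBins) + 1L
  field <- if (lo <= hi) lo:hi
           else c(lo:nBins, 1:hi)
  list(fieldBins = field, peakBin = pk,
       widthCm = length(field) * 180 / nBins)
}

#' Detect the place-field induction lap
#'
#' The induction lap is the earliest lap X with significant activity in
#' the eventual field such that at least 2 of the 5 following laps also
#' show significant field activity.  If the field then disappears for more
#' than \code{maxGap} consecutive laps, the search resumes after the gap
#' (the earlier, weak field is discarded).
#'
#' @param sigLapBin logical matrix [lap, bin], binned significance of one unit.
#' @param fieldBins integer bin indices of the eventual field.
#' @param followWindow laps inspected after a candidate (default 5).
#' @param needed required confirmations within the window (default 2).
#' @param maxGap tolerated silent-gap length in laps (default 20).
#' @return integer induction lap or NA
#' @export
detectInductionLap <- function(sigLapBin, fieldBins, followWindow = 5L,
                               needed = 2L, maxGap = 20L) {
  L <- nrow(sigLapBin)
  active <- apply(sigLapBin[, fieldBins, drop = FALSE], 1, any)
  qualifies <- function(x) {
    win <- (x + 1L):min(x + followWindow, L)
    x < L && active[x] && sum(active[win]) >= needed
  }
  cand <- which(vapply(seq_len(L), qualifies, logical(1)))
  if (!length(cand)) return(NA_integer_)
  x <- cand[1]
  repeat {
    after <- which(active & seq_len(L) >= x)
    gaps <- diff(after) - 1L
    big <- which(gaps > maxGap)
    if (!length(big)) return(x)
    resume <- after[big[1] + 1L]          # first active lap after the gap
    nxt <- cand[cand >= resume]
    if (!length(nxt)) return(x)           # no later qualifying lap: keep x
    x <- nxt[1]
  }
}

#' Spatial information of an activity map
#'
#' SI = sum_i P_i * lambda_i * log2(lambda_i / lambda), with lambda the
#' occupancy-weighted mean sum_i P_i * lambda_i (this guarantees SI >= 0).
#' Bins with lambda_i <= 0 contribute 0 (negative mean dF/F is clamped to
#' zero); a silent unit (lambda = 0) has SI defined as 0.
#'
#' @param lambda numeric per-bin mean activity (dF/F).
#' @param P numeric per-bin occupancy probability (non-negative, sums to 1).
#' @param weightedMean use the occupancy-weighted mean for lambda (default);
#'   otherwise the unweighted bin mean.
#' @return SI in bits
#' @examples
#' spatialInformation(c(2, 0), c(0.5, 0.5))   # 1 bit
#' @export
spatialInformation <- function(lambda, P, weightedMean = TRUE) {
  stopifnot(length(lambda) == length(P))
  if (any(P < -1e-12) || abs(sum(P) - 1) > 1e-6)
    stop("P must be non-negative and sum to 1")
  lambda <- pmax(lambda, 0)
  lbar <- if (weightedMean) sum(P * lambda) else mean(lambda)
  if (lbar <= 0) return(0)
  pos <- lambda > 0
  sum(P[pos] * lambda[pos] * log2(lambda[pos] / lbar))
}

# occupancy-weighted smoothed mean map of one dff trace over given frames
siMapOf <- function(dff, bins, running, nBins) {
  use <- running
  cnt <- tabulate(bins[use], nBins)
  lam <- numeric(nBins)
  sums <- rowsum(dff[use], bins[use])
  lam[as.integer(rownames(sums))] <- sums[, 1]
  lam <- ifelse(cnt > 0, lam / pmax(cnt, 1), NA_real_)
  lam <- boxcar3(fillCircularNA(lam))
  P <- cnt / sum(cnt)
  list(lambda = lam, P = P)
}

#' Shuffle test for spatial information
#'
#' Compares the observed SI of a trace against 100 shuffles, each built by
#' circularly shifting the dF/F trace by an offset uniform in
#' [minShift, T - minShift], then cutting the shifted trace into six equal
#' chunks and permuting their order (identity permutation excluded).  The
#' unit passes when the observed SI exceeds the 95th percentile (linear
#' interpolation) of the shuffle values.
#'
#' @param dff numeric dF/F trace of one unit.
#' @param behavior the matching \code{\link{BehaviorSession}}.
#' @param frames optional integer frame subset (e.g. post-induction laps).
#' @param nShuffles number of shuffles (default 100).
#' @param seed integer RNG seed.
#' @param minShift minimum circular shift, frames (default 500).
#' @param nChunks chunk count (default 6).
#' @param nBins spatial bin count.
#' @return list(si, shuffles, passes, percentile)
#' @export
siShuffleTest <- function(dff, behavior, frames = NULL, nShuffles = 100L,
                          seed = 1L, minShift = 500L, nChunks = 6L,
                          nBins = 50L) {
  if (is.null(frames)) frames <- seq_along(dff)
  x <- dff[frames]
  T <- length(x)
  if (T < 3 * minShift)
    stop("trace too short for a ", minShift, "-frame circular shift")
  bins <- positionToBin(behavior@position[frames], behavior@beltLength, nBins)
  running <- behavior@velocity[frames] > 2
  obs <- siMapOf(x, bins, running, nBins)
  si <- spatialInformation(obs$lambda, obs$P)

  set.seed(as.integer(seed))
  chunk <- floor(seq(0, T, length.out = nChunks + 1L))
  starts <- chunk[-length(chunk)] + 1L
  ends <- chunk[-1L]
  shuf <- numeric(nShuffles)
  for (s in seq_len(nShuffles)) {
    off <- sample(seq(minShift, T - minShift), 1)
    xs <- x[((seq_len(T) - 1L + off) %% T) + 1L]
    repeat {
      perm <- sample(nChunks)
      if (any(perm != seq_len(nChunks))) break
    }
    xp <- unlist(lapply(perm, function(k) xs[starts[k]:ends[k]]),
                 use.names = FALSE)
    m <- siMapOf(xp, bins, running, nBins)
    shuf[s] <- spatialInformation(m$lambda, m$P)
  }
  q95 <- quantile(shuf, 0.95, names = FALSE)
  list(si = si, shuffles = shuf, passes = si > q95,
       percentile = mean(si > shuf) * 100)
}

#' Classify place cells and measure their field properties
#'
#' Runs the full identification chain for every unit of an activity map:
#' eventual field, induction lap, spatial-information shuffle test on the
#' post-induction laps, and reliability (fraction of post-induction laps
#' with significant field activity).  A unit is a place cell when it
#' passes the shuffle test and its reliability exceeds
#' \code{reliabilityThreshold}.  Silent units (no significant activity in
#' any lap) are excluded.
#'
#' @param map an \code{\link{ActivityMap}} of the units.
#' @param traces the matching \code{\link{RoiTraceSet}} (or dff matrix).
#' @param behavior the matching \code{\link{BehaviorSession}}.
#' @param nShuffles shuffles per unit.
#' @param seed integer RNG seed (one stream per unit, derived).
#' @param reliabilityThreshold default 0.30.
#' @param minShift minimum shuffle shift, frames.
#' @return data.frame with one row per non-silent unit: unit, isPlaceCell,
#'   inductionLap, peakBin, peakPosition, widthCm, si, siPasses,
#'   reliability, inductionVelocity, peakShift
#' @export
classifyPlaceCells <- function(map, traces, behavior, nShuffles = 100L,
                               seed = 1L, reliabilityThreshold = 0.30,
                               minShift = 500L) {
  stopifnot(is(map, "ActivityMap"))
  dff <- if (is.matrix(traces)) traces else dffValues(traces)
  L <- map@nLaps
  nU <- dim(map@meanDff)[1]
  lap1 <- behavior@lapIndex + 1L
  binW <- map@binWidth
  belt <- behavior@beltLength

  rows <- vector("list", nU)
  for (u in seq_len(nU)) {
    sig <- map@significant[u, , ]
    if (!any(sig)) next                    # silent unit: excluded
    meanMap <- apply(map@meanDff[u, , , drop = FALSE], 3, mean, na.rm = TRUE)
    fld <- findEventualField(meanMap)
    if (is.null(fld)) next
    ind <- detectInductionLap(sig, fld$fieldBins)
    rec <- data.frame(unit = u, isPlaceCell = FALSE,
                      inductionLap = ind, peakBin = NA_integer_,
                      peakPosition = NA_real_, widthCm = NA_real_,
                      si = NA_real_, siPasses = NA,
                      reliability = NA_real_,
                      inductionVelocity = NA_real_, peakShift = NA_real_)
    if (!is.na(ind) && ind < L) {
      postLaps <- (ind + 1L):L
      postMap <- apply(map@meanDff[u, postLaps, , drop = FALSE], 3, mean,
                       na.rm = TRUE)
      postFld <- findEventualField(postMap)
      if (!is.null(postFld)) {
        rec$peakBin <- postFld$peakBin
        rec$peakPosition <- (postFld$peakBin - 0.5) * binW
        rec$widthCm <- postFld$widthCm
        rec$reliability <- mean(apply(
          sig[postLaps, postFld$fieldBins, drop = FALSE], 1, any))
        postFrames <- which(lap1 %in% postLaps)
        st <- tryCatch(
          siShuffleTest(dff[u, ], behavior, frames = postFrames,
                        nShuffles = nShuffles, seed = seed + u,
                        minShift = minShift),
          error = function(e) NULL)
        if (!is.null(st)) {
          rec$si <- st$si; rec$siPasses <- st$passes
          rec$isPlaceCell <- st$passes &&
            rec$reliability > reliabilityThreshold
        }
        runInd <- lap1 == ind & behavior@velocity > 2
        if (any(runInd))
          rec$inductionVelocity <- mean(behavior@velocity[runInd])
        indMap <- map@meanDff[u, ind, ]
        indPeak <- (which.max(indMap) - 0.5) * binW
        rec$peakShift <- circDiff(rec$peakPosition, indPeak, belt)
      }
    }
    rows[[u]] <- rec
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(unit = integer(), isPlaceCell = logical(),
                      inductionLap = integer(), peakBin = integer(),
                      peakPosition = numeric(), widthCm = numeric(),
                      si = numeric(), siPasses = logical(),
                      reliability = numeric(),
                      inductionVelocity = numeric(), peakShift = numeric())
  rownames(out) <- NULL
  out
}

#' Signed circular place-field peak shift
#'
#' Shift of the established field peak relative to the induction-lap
#' activity peak, as the minimal circular displacement in (-L/2, L/2];
#' negative values point backward (against the running direction), the
#' signature of plasticity acting on inputs active before the plateau.
#'
#' @param fieldPeakCm peak of the mean map over post-induction laps, cm.
#' @param inductionPeakCm peak activity location on the induction lap, cm.
#' @param beltLength cm.
#' @return signed shift, cm
#' @examples
#' peakShiftCm(88, 90)    # -2
#' peakShiftCm(178, 2)    # -4, wrap-aware
#' @export
peakShiftCm <- function(fieldPeakCm, inductionPeakCm, beltLength = 180) {
  circDiff(fieldPeakCm, inductionPeakCm, beltLength)
}

#' Place-field width versus induction-lap velocity
#'
#' Bins place-field widths into 5 cm/s induction-velocity bins, fits a
#' least-squares line to the bin means and reports the Pearson correlation
#' (with two-sided p value) of the bin means.
#'
#' @param records output of \code{\link{classifyPlaceCells}} (place cells
#'   with width and induction velocity are used).
#' @param velBinWidth velocity bin width, cm/s.
#' @return list(slope, intercept, R, pValue, binVelocity, binWidth, binN)
#' @export
widthVelocityRelation <- function(records, velBinWidth = 5) {
  pc <- records[records$isPlaceCell & !is.na(records$widthCm) &
                !is.na(records$inductionVelocity), ]
  if (!nrow(pc)) stop("no place cells with width and induction velocity")
  bin <- floor(pc$inductionVelocity / velBinWidth)
  bv <- tapply(pc$inductionVelocity, bin, mean)
  bw <- tapply(pc$widthCm, bin, mean)
  bn <- tapply(pc$widthCm, bin, length)
  if (length(bv) < 2) stop("fit refused: all cells fall in one velocity bin")
  fit <- lm(bw ~ bv)
  ct <- cor.test(as.numeric(bv), as.numeric(bw))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       R = unname(ct$estimate), pValue = ct$p.value,
       binVelocity = as.numeric(bv), binWidth = as.numeric(bw),
       binN = as.numeric(bn))
}

#' Population-level place-cell summaries
#'
#' Density of place-field peaks per 18-cm bin (fraction of place cells),
#' cumulative appearance curve over laps (and per session quarter), and
#' the Pearson correlation between per-18-cm-bin density and
#' peak-normalised velocity.
#'
#' @param records output of \code{\link{classifyPlaceCells}}.
#' @param velocityMap per-bin (50) mean velocity on the same alignment.
#' @param nLapsTotal session lap count.
#' @param beltLength cm.
#' @return list(density, densityBinCm, appearance, quarters,
#'   densityVelocityR, densityVelocityP)
#' @export
populationSummaries <- function(records, velocityMap = NULL,
                                nLapsTotal = NULL, beltLength = 180) {
  pc <- records[records$isPlaceCell, ]
  if (!nrow(pc)) stop("at least one place cell is required")
  wide <- positionToBin(pc$peakPosition, beltLength, 10L)
  density <- tabulate(wide, 10L) / nrow(pc)
  if (is.null(nLapsTotal)) nLapsTotal <- max(pc$inductionLap, na.rm = TRUE)
  appearance <- vapply(seq_len(nLapsTotal),
                       function(l) mean(pc$inductionLap <= l), numeric(1))
  qEdges <- ceiling(seq(0, nLapsTotal, length.out = 5L))
  quarters <- vapply(seq_len(4L), function(q)
    mean(pc$inductionLap > qEdges[q] & pc$inductionLap <= qEdges[q + 1L]),
    numeric(1))
  R <- NA_real_; p <- NA_real_
  if (!is.null(velocityMap)) {
    v10 <- vapply(seq_len(10L), function(k)
      mean(velocityMap[((k - 1L) * 5L + 1L):(k * 5L)]), numeric(1))
    ct <- cor.test(density, v10 / max(v10))
    R <- unname(ct$estimate); p <- ct$p.value
  }
  list(density = density,
       densityBinCm = (seq_len(10L) - 0.5) * beltLength / 10,
       appearance = appearance, quarters = quarters,
       densityVelocityR = R, densityVelocityP = p)
}

#' Population vector correlation between two activity maps
#'
#' For each spatial bin, the Pearson correlation of the across-unit
#' activity vectors between the two conditions (units paired by index).
#' With \code{oddEven = TRUE} and a single map, odd and even laps form the
#' two conditions (within-session reliability).
#'
#' @param mapA an \code{\link{ActivityMap}} or numeric matrix [unit, bin].
#' @param mapB second map; omitted for the odd/even variant.
#' @param oddEven split \code{mapA}'s laps by parity.
#' @return list(perBin, mean)
#' @export
populationVectorCorrelation <- function(mapA, mapB = NULL, oddEven = FALSE) {
  unitBin <- function(m, laps = NULL) {
    if (is.matrix(m)) return(m)
    x <- m@meanDff
    if (is.null(laps)) laps <- seq_len(dim(x)[2])
    t(vapply(seq_len(dim(x)[1]), function(u)
      apply(x[u, laps, , drop = FALSE], 3, mean, na.rm = TRUE),
      numeric(dim(x)[3])))
  }
  if (oddEven) {
    L <- if (is.matrix(mapA)) stop("odd/even split needs an ActivityMap")
         else mapA@nLaps
    A <- unitBin(mapA, seq(1, L, by = 2))
    B <- unitBin(mapA, seq(2, L, by = 2))
  } else {
    if (is.null(mapB)) stop("two maps (or oddEven = TRUE) are required")
    A <- unitBin(mapA); B <- unitBin(mapB)
  }
  if (nrow(A) != nrow(B)) stop("maps must share the unit set")
  if (nrow(A) < 3) stop("at least 3 shared units are required")
  perBin <- vapply(seq_len(ncol(A)), function(j) {
    if (sd(A[, j]) == 0 || sd(B[, j]) == 0) return(NA_real_)
    cor(A[, j], B[, j])
  }, numeric(1))
  list(perBin = perBin, mean = mean(perBin, na.rm = TRUE))
}

#' Session-section profiles of EC3 activity and CA1 plasticity
#'
#' Splits the session into consecutive sections (default 10 laps) and
#' reports, per section: mean EC3 dF/F in the over-representation zone,
#' the fraction of all place-cell inductions falling in the section, and
#' the Pearson correlation between the summed EC3 and summed CA1 50-bin
#' population profiles.
#'
#' @param ec3Map \code{\link{ActivityMap}} of EC3 axons.
#' @param ca1Map \code{\link{ActivityMap}} of CA1 units.
#' @param records output of \code{\link{classifyPlaceCells}}.
#' @param zone integer bin indices of the over-representation zone
#'   (default: +/- 18 cm around the aligned reward bin).
#' @param sectionLaps laps per section.
#' @return data.frame(section, ec3ZoneMean, formationFraction, ec3Ca1Corr)
#' @export
sessionSectionProfiles <- function(ec3Map, ca1Map, records, zone = NULL,
                                   sectionLaps = 10L) {
  L <- min(ec3Map@nLaps, ca1Map@nLaps)
  nSec <- L %/% sectionLaps
  if (nSec < 1) stop("session shorter than one section")
  if (is.null(zone)) {
    ctr <- (ec3Map@rewardBin - 0.5) * ec3Map@binWidth
    zone <- zoneBinsAround(ctr, 18, 180, dim(ec3Map@meanDff)[3])
  }
  if (!length(zone)) stop("over-representation zone is empty")
  nPc <- sum(records$isPlaceCell)
  out <- data.frame(section = seq_len(nSec), ec3ZoneMean = NA_real_,
                    formationFraction = NA_real_, ec3Ca1Corr = NA_real_)
  for (s in seq_len(nSec)) {
    laps <- ((s - 1L) * sectionLaps + 1L):(s * sectionLaps)
    e <- ec3Map@meanDff[, laps, , drop = FALSE]
    out$ec3ZoneMean[s] <- mean(e[, , zone], na.rm = TRUE)
    ec3Prof <- apply(e, 3, sum, na.rm = TRUE)
    ca1Prof <- apply(ca1Map@meanDff[, laps, , drop = FALSE], 3, sum,
                     na.rm = TRUE)
    if (sd(ec3Prof) > 0 && sd(ca1Prof) > 0)
      out$ec3Ca1Corr[s] <- cor(ec3Prof, ca1Prof)
    if (nPc > 0) {
      ind <- records$inductionLap[records$isPlaceCell]
      out$formationFraction[s] <- sum(ind %in% laps, na.rm = TRUE) / nPc
    }
  }
  out
}
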