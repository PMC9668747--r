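# Synthetic CA1 somatic fluorescence with ground-truth place fields.
#
# Place cells follow the plasticity phenomenology of abrupt field formation:
# silent until a single induction lap, then active on every subsequent
# traversal of the field; field width proportional to the induction-lap
# running speed; field peak displaced backward (against running) from the
# induction-lap activity peak.  The forward model is a fixture convention:
# spatial Gaussian drive convolved with a fast-indicator kernel (50 ms
# rise, 300 ms decay) on a positive baseline with additive Gaussian noise.

# rise-then-decay calcium kernel, peak-normalised
calciumKernel <- function(frameRate, rise = 0.05, decay = 0.3, lenSd = 6) {
  t <- seq(0, decay * lenSd, by = 1 / frameRate)
  k <- (1 - exp(-t / rise)) * exp(-t / decay)
  k / max(k)
}

convolveCausal <- function(x, k) {
  n <- length(x)
  y <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  y[seq_len(n)]
}

#' Generate synthetic CA1 somatic traces with known place fields
#'
#' Each unit is a silent cell (baseline + noise), a noise-only cell
#' (baseline + spatially random transients), or a place cell with a known
#' induction lap, field centre and width.  Place-cell activity starts
#' abruptly: nothing before the induction lap; on the induction lap the
#' activity is centred on the plateau position; on every later lap it is
#' centred on the true field centre, which sits backward (against the
#' running direction) of the plateau position by shiftScale x induction
#' velocity.  Field width is widthSlope x induction velocity, measured as
#' the 20\%-of-peak extent.  Lap amplitudes are jittered lognormally
#' (sigma = 0.3).
#'
#' @param behavior a \code{\link{BehaviorSession}} with >= 10 laps.
#' @param nCells number of units.
#' @param fracPlace fraction of units that are place cells (0..1); the
#'   remainder is split evenly between silent and noise-only cells.
#' @param btspParams list overriding: widthSlope (s, width = slope * v,
#'   default 2), shiftScale (s, backward shift = scale * v, default 0.5),
#'   amplitude (peak dF/F, 1.5), amplitudeJitterSd (lognormal sigma, 0.3),
#'   inductionLapRange (laps eligible for induction, default
#'   3..(nLaps - 12)).
#' @param noiseParams list overriding: sd (dF/F noise sd, 0.05), baselineF
#'   (mean baseline fluorescence, 100), baselineJitterSd (lognormal, 0.2),
#'   noiseEventRate (Hz, transient rate of noise-only cells, 0.05).
#' @param seed integer RNG seed.
#' @return list(traces = \code{\link{RoiTraceSet}} (modality "ca1_soma"),
#'   truth = data.frame with unit, cellClass, trueInductionLap,
#'   trueFieldCenter, trueFieldWidth, inductionVelocity, plateauPosition)
#' @export
generateCa1Traces <- function(behavior, nCells = 200L, fracPlace = 0.4,
                              btspParams = list(), noiseParams = list(),
                              seed = 1L) {
  stopifnot(is(behavior, "BehaviorSession"))
  if (fracPlace < 0 || fracPlace > 1) stop("fracPlace must lie in [0, 1]")
  L <- nLaps(behavior)
  if (L < 10) stop("induction laps cannot be placed: behavior has fewer than 10 laps")
  bp <- list(widthSlope = 2, shiftScale = 0.5, amplitude = 1.5,
             amplitudeJitterSd = 0.3,
             inductionLapRange = c(3L, max(3L, L - 12L)))
  bp[names(btspParams)] <- btspParams
  np <- list(sd = 0.05, baselineF = 100, baselineJitterSd = 0.2,
             noiseEventRate = 0.05)
  np[names(noiseParams)] <- noiseParams
  set.seed(as.integer(seed))

  nPlace <- round(nCells * fracPlace)
  nRest <- nCells - nPlace
  classes <- c(rep("place_cell", nPlace),
               rep("silent", ceiling(nRest / 2)),
               rep("noise_only", floor(nRest / 2)))
  classes <- sample(classes)

  fr <- behavior@frameRate
  belt <- behavior@beltLength
  n <- length(behavior)
  lap1 <- behavior@lapIndex + 1L
  running <- behavior@velocity > 2
  kern <- calciumKernel(fr)
  # spatial lag of the convolved fluorescence peak behind the drive peak,
  # per unit running speed (mode lag of the kernel-smeared profile)
  kernLagS <- 0.3

  # mean running velocity per lap (induction velocity oracle)
  lapVel <- vapply(seq_len(L), function(l) {
    v <- behavior@velocity[lap1 == l & running]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))

  F <- matrix(0, nCells, n)
  truth <- data.frame(unit = seq_len(nCells), cellClass = classes,
                      trueInductionLap = NA_integer_,
                      trueFieldCenter = NA_real_, trueFieldWidth = NA_real_,
                      inductionVelocity = NA_real_,
                      plateauPosition = NA_real_,
                      stringsAsFactors = FALSE)

  for (i in seq_len(nCells)) {
    f0 <- np$baselineF * exp(rnorm(1, 0, np$baselineJitterSd))
    sig <- numeric(n)
    if (classes[i] == "place_cell") {
      ind <- sample(seq(bp$inductionLapRange[1], bp$inductionLapRange[2]), 1)
      vInd <- lapVel[ind]
      width <- bp$widthSlope * vInd
      shift <- bp$shiftScale * vInd
      center <- runif(1, 0, belt)
      plateau <- (center + shift) %% belt   # field sits backward of plateau
      sigmaField <- width / (2 * sqrt(2 * log(5)))  # 20%-of-peak width
      truth$trueInductionLap[i] <- ind
      truth$trueFieldCenter[i] <- center
      truth$trueFieldWidth[i] <- width
      truth$inductionVelocity[i] <- vInd
      truth$plateauPosition[i] <- plateau
      for (l in ind:L) {
        fl <- which(lap1 == l)
        ctr <- if (l == ind) plateau else center
        # advance the drive centre against running by the indicator lag
        # (decay time x lap speed) so the simulated FLUORESCENCE field,
        # not the underlying drive, is centred on the ground-truth centre
        vl <- if (is.na(lapVel[l])) 18 else lapVel[l]
        ctr <- (ctr - kernLagS * vl) %% belt
        amp <- bp$amplitude * exp(rnorm(1, 0, bp$amplitudeJitterSd))
        d <- circDist(behavior@position[fl], ctr, belt)
        sig[fl] <- amp * exp(-d^2 / (2 * sigmaField^2))
      }
      sig <- convolveCausal(sig, kern)
    } else if (classes[i] == "noise_only") {
      ev <- runif(n) < np$noiseEventRate / fr
      amps <- numeric(n)
      amps[ev] <- bp$amplitude * exp(rnorm(sum(ev), 0, bp$amplitudeJitterSd))
      sig <- convolveCausal(amps, kern)
    }
    tr <- f0 * (1 + sig + rnorm(n, 0, np$sd))
    F[i, ] <- pmax(tr, f0 * 0.01)
  }
  list(traces = RoiTraceSet(F, roiSize = rep(120L, nCells),
                            frameRate = fr, modality = "ca1_soma"),
       truth = truth)
}
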