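# Synthetic EC3 axonal ROI traces driven by a chain population.
#
# Each chain plays the role of one parent axon; its binary state is mapped
# onto the behaviour frame grid lap by lap (within-lap time fraction ->
# within-lap chain step), convolved with the calcium kernel, and split into
# one or more ROI traces that share the axonal signal but carry
# independent noise -- the substrate for the noise-correlation merge.

#' Generate synthetic EC3 axonal ROI traces
#'
#' @param chains a \code{\link{ChainPopulation}} with at least as many laps
#'   as the behaviour session.
#' @param behavior a \code{\link{BehaviorSession}}.
#' @param roisPerAxon either a single integer (fixed ROI count per axon) or
#'   a probability vector over 1, 2, 3, ... ROIs (default c(0.5, 0.3, 0.2)).
#' @param kernelParams list overriding: rise (s, 0.05), decay (s, 0.3),
#'   amplitude (dF/F of the active state, 1).
#' @param noiseParams list overriding: sd (dF/F noise sd, 0.1), baselineF
#'   (100), baselineJitterSd (0.2), sizeMeanLog (log pixel count, log(30)),
#'   sizeSdLog (0.5).
#' @param seed integer RNG seed.
#' @return list(traces = \code{\link{RoiTraceSet}} (modality "ec3_axon"),
#'   truth = data.frame with roi, axonId, roiSize)
#' @export
generateEc3Rois <- function(chains, behavior, roisPerAxon = c(0.5, 0.3, 0.2),
                            kernelParams = list(), noiseParams = list(),
                            seed = 1L) {
  stopifnot(is(chains, "ChainPopulation"), is(behavior, "BehaviorSession"))
  nAxons <- nrow(chains@states)
  if (nAxons == 0) stop("empty chain population")
  cfg <- chains@config
  L <- nLaps(behavior)
  if (L > cfg@nLaps)
    stop("behavior has more laps than the chain population")
  kp <- list(rise = 0.05, decay = 0.3, amplitude = 1)
  kp[names(kernelParams)] <- kernelParams
  np <- list(sd = 0.1, baselineF = 100, baselineJitterSd = 0.2,
             sizeMeanLog = log(30), sizeSdLog = 0.5)
  np[names(noiseParams)] <- noiseParams
  set.seed(as.integer(seed))

  # within-lap time fraction -> chain step, lap by lap
  n <- length(behavior)
  lap1 <- behavior@lapIndex + 1L
  stepOf <- integer(n)
  for (l in seq_len(L)) {
    fl <- which(lap1 == l)
    frac <- (seq_along(fl) - 1) / length(fl)
    stepOf[fl] <- (l - 1L) * cfg@lapSteps + pmin(
      floor(frac * cfg@lapSteps) + 1L, cfg@lapSteps)
  }

  fr <- behavior@frameRate
  kern <- calciumKernel(fr, rise = kp$rise, decay = kp$decay)
  nRois <- if (length(roisPerAxon) == 1L)
    rep(as.integer(roisPerAxon), nAxons)
  else
    sample(seq_along(roisPerAxon), nAxons, replace = TRUE, prob = roisPerAxon)
  total <- sum(nRois)
  F <- matrix(0, total, n)
  axonId <- integer(total)
  sizes <- pmax(5L, as.integer(round(exp(
    rnorm(total, np$sizeMeanLog, np$sizeSdLog)))))
  r <- 0L
  for (a in seq_len(nAxons)) {
    sig <- kp$amplitude * convolveCausal(chains@states[a, stepOf], kern)
    for (j in seq_len(nRois[a])) {
      r <- r + 1L
      axonId[r] <- a
      f0 <- np$baselineF * exp(rnorm(1, 0, np$baselineJitterSd))
      tr <- f0 * (1 + sig + rnorm(n, 0, np$sd))
      F[r, ] <- pmax(tr, f0 * 0.01)
    }
  }
  list(traces = RoiTraceSet(F, roiSize = sizes, frameRate = fr,
                            modality = "ec3_axon"),
       truth = data.frame(roi = seq_len(total), axonId = axonId,
                          roiSize = sizes))
}
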