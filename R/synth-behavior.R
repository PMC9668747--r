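# Synthetic treadmill behaviour.  Emulates head-fixed running on a 180-cm
# circular belt: a spatial speed profile that slows in the reward zone
# (doubling dwell time there for environments A/B), lap-to-lap speed
# variability, occasional stops near the reward (so the running filter has
# frames to remove), and licking concentrated just before the reward.

#' Generate a synthetic behaviour session
#'
#' Position is integrated from a per-frame velocity built as
#' spatial profile x lap multiplier x smooth within-lap noise; velocity is
#' therefore exactly the wrap-aware forward difference of position.  For
#' environments A and B the default profile halves the speed within
#' +/- 18 cm of the reward, doubling the dwell time there relative to the
#' remainder of the track; habituation sessions have a flat profile and
#' spatially uniform licking.
#'
#' @param nLaps number of laps (>= 1).
#' @param environment "A", "B" or "habituation".
#' @param speedParams list overriding any of: baseSpeed (cm/s, 18),
#'   slowFactor (2), zoneHalfWidth (cm, 18), lapSpeedSd (lognormal sd of the
#'   per-lap multiplier, 0.2), noiseSd (within-lap AR(1) multiplicative sd,
#'   0.05), stopProb (per-lap probability of a stop near the reward, 0.3),
#'   stopDuration (s, 1), stopSpeed (cm/s during a stop, 0.5).
#' @param seed integer RNG seed.
#' @param frameRate Hz.
#' @param beltLength cm.
#' @param rewardPosition cm (default 90).
#' @param cuePosition cm; default 50 cm before the reward for environment B,
#'   NA otherwise.
#' @return a \code{\link{BehaviorSession}}
#' @examples
#' beh <- generateBehavior(20, "A", seed = 1)
#' nLaps(beh)
#' @export
generateBehavior <- function(nLaps, environment = c("A", "B", "habituation"),
                             speedParams = list(), seed = 1L,
                             frameRate = 30, beltLength = 180,
                             rewardPosition = 90, cuePosition = NULL) {
  environment <- match.arg(environment)
  if (nLaps < 1) stop("nLaps must be at least 1")
  p <- list(baseSpeed = 18, slowFactor = 2, zoneHalfWidth = 18,
            lapSpeedSd = 0.2, noiseSd = 0.05, stopProb = 0.3,
            stopDuration = 1.0, stopSpeed = 0.5)
  p[names(speedParams)] <- speedParams
  if (p$baseSpeed <= 0 || p$slowFactor < 1 || p$stopSpeed < 0)
    stop("speed profile must be strictly positive away from stop epochs")
  if (is.null(cuePosition))
    cuePosition <- if (environment == "B")
      (rewardPosition - 50) %% beltLength else NA_real_
  set.seed(as.integer(seed))
  dt <- 1 / frameRate

  profileSpeed <- function(pos) {
    v <- rep(p$baseSpeed, length(pos))
    if (environment != "habituation") {
      inZone <- circDist(pos, rewardPosition, beltLength) <= p$zoneHalfWidth
      v[inZone] <- p$baseSpeed / p$slowFactor
    }
    v
  }

  posL <- list(); velL <- list(); lapL <- list()
  for (lap in seq_len(nLaps)) {
    lapMult <- exp(rnorm(1, 0, p$lapSpeedSd))
    stopHere <- environment != "habituation" && runif(1) < p$stopProb
    stopPos <- (rewardPosition - runif(1, 0, 10)) %% beltLength
    stopLeft <- if (stopHere) round(p$stopDuration * frameRate) else 0L
    stopArmed <- stopHere
    pos <- numeric(0); vel <- numeric(0)
    x <- 0; noise <- 0
    # 1e-9 cm guard: accumulated float error must not add a spurious
    # boundary frame when the speed is commensurate with the belt length
    while (x < beltLength - 1e-9) {
      noise <- 0.9 * noise + rnorm(1, 0, p$noiseSd)
      v <- profileSpeed(x) * lapMult * exp(noise)
      if (stopArmed && stopLeft > 0 &&
          circDist(x, stopPos, beltLength) < 2) {
        v <- p$stopSpeed
        stopLeft <- stopLeft - 1L
        if (stopLeft == 0L) stopArmed <- FALSE
      }
      pos <- c(pos, x); vel <- c(vel, v)
      x <- x + v * dt
    }
    posL[[lap]] <- pos; velL[[lap]] <- vel
    lapL[[lap]] <- rep(lap - 1L, length(pos))
  }
  position <- unlist(posL); velocity <- unlist(velL)
  lapIndex <- as.integer(unlist(lapL))
  n <- length(position)
  time <- (seq_len(n) - 1) * dt

  # recompute stored velocity as the exact wrap-aware forward difference
  dpos <- (diff(position) %% beltLength) / dt
  velocity <- c(dpos, velocity[n])

  lick <- integer(n)
  if (environment == "habituation") {
    rate <- rep(1, n)
  } else {
    dBefore <- (rewardPosition - position) %% beltLength
    rate <- 0.2 + 8 * (dBefore <= 20)
  }
  lick <- as.integer(runif(n) < rate * dt)

  obj <- new("BehaviorSession",
    time = time, position = position, velocity = velocity,
    lick = lick, lapIndex = lapIndex,
    rewardPosition = rewardPosition, cuePosition = cuePosition,
    beltLength = beltLength, environment = environment,
    frameRate = frameRate)
  validObject(obj)
  obj
}

#' Per-bin dwell-time profile of a behaviour session
#'
#' Seconds spent per spatial bin per lap, optionally restricted to running
#' frames (velocity > 2 cm/s), in raw (unaligned) bin coordinates.
#'
#' @param behavior a \code{\link{BehaviorSession}}.
#' @param nBins bin count.
#' @param runningOnly restrict to running frames.
#' @return numeric per-bin mean seconds per lap
#' @export
dwellProfile <- function(behavior, nBins = 50L, runningOnly = TRUE) {
  keep <- if (runningOnly) behavior@velocity > 2 else rep(TRUE, length(behavior))
  b <- positionToBin(behavior@position[keep], behavior@beltLength, nBins)
  tabulate(b, nBins) / behavior@frameRate / nLaps(behavior)
}
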