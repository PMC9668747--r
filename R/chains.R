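# Two-state Markov-chain model of EC3 persistent activity.
#
# Each chain switches between an inactive (0) and active (1) state with
# per-step probabilities P01*dt and P10*dt.  Spatial tuning arises from a
# 1-s window at a fixed within-lap phase, recurring every lap, during which
# a chain's activation rate is stepped up to a boost value.  The mean-state
# bump of such a chain peaks at the END of its boost window (occupancy rises
# during the window and decays afterwards with time constant ~1/(P01+P10)),
# so windows are placed to end at the chain's nominal preferred step.

# frozen density constant for the env-B phase allocation: modulated-chain
# count per phase ~ 1 + ENVB_DENSITY_A * exp(-d^2 / (2 * 10cm^2)) around the
# cue, chosen once so that the cue-zone peak-fraction enrichment over the
# uniform configuration is approximately threefold
ENVB_DENSITY_A <- 25
ENVB_SIGMA_CM <- 10

stepOfPosition <- function(pos, beltLength = 180, lapSteps = 100L) {
  as.integer((floor(pos / beltLength * lapSteps) %% lapSteps) + 1L)
}

# largest-remainder apportionment of n items over weights w (deterministic)
apportion <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build a chain-population configuration
#'
#' Constructs the configuration of a two-state Markov-chain population for
#' one of three conditions: \code{"uniform"} (all chains homogeneous at the
#' baseline activation rate), \code{"A"} (cue-rich belt: 1400 chains with
#' the activation rate boosted 0.04 -> 0.20 for 1 s at within-lap phases
#' tiling the lap 14 chains per step, 600 homogeneous), or \code{"B"}
#' (single predictive cue: 1850 boosted chains, 0.04 -> 0.28, with phase
#' density concentrated around the cue position, 150 homogeneous).  With
#' \code{enhancedTuning = TRUE} the ~100 modulated chains nearest the
#' salient location (reward for A, cue for B) are further boosted (to 0.68
#' for A, to three times the env-B boost for B), emulating the enhanced
#' tuning observed around behaviourally relevant locations.
#'
#' @param environment "uniform", "A" or "B".
#' @param enhancedTuning logical, add the enhanced-tuning subpopulation.
#' @param nChains total chain count (default 2000).
#' @param p01Base baseline activation rate, 1/s (default 0.04).
#' @param p10 inactivation rate, 1/s (default 0.25, i.e. mean active period 4 s).
#' @param boostA,boostB boosted activation rates for environments A and B.
#' @param boostEnhancedA activation rate of enhanced-tuning chains in env A.
#' @param rewardPosition,cuePosition cm on the belt.
#' @param beltLength cm.
#' @param nLaps laps retained after burn-in.
#' @param lapSteps time steps per lap (dt = 0.1 s, lap = 10 s).
#' @param dt time step, s.
#' @param nHomogeneousA,nHomogeneousB homogeneous pool sizes.
#' @param nEnhanced size of the enhanced-tuning subpopulation.
#' @return a \code{\link{ChainConfig}}
#' @examples
#' cfg <- chainConfig("A")
#' sum(!is.na(cfg@boostP01))   # 1400 modulated chains
#' @export
chainConfig <- function(environment = c("uniform", "A", "B"),
                        enhancedTuning = FALSE,
                        nChains = 2000L, p01Base = 0.04, p10 = 0.25,
                        boostA = 0.20, boostB = 0.28, boostEnhancedA = 0.68,
                        rewardPosition = 90, cuePosition = 40,
                        beltLength = 180,
                        nLaps = 50L, lapSteps = 100L, dt = 0.1,
                        nHomogeneousA = 600L, nHomogeneousB = 150L,
                        nEnhanced = 100L) {
  environment <- match.arg(environment)
  nChains <- as.integer(nChains)
  boostP01 <- rep(NA_real_, nChains)
  phaseStep <- rep(NA_integer_, nChains)
  zoneCenterStep <- NA_integer_

  if (environment == "A") {
    nMod <- nChains - as.integer(nHomogeneousA)
    perPhase <- nMod / lapSteps
    if (perPhase != floor(perPhase))
      stop("modulated chain count must be a multiple of lapSteps")
    phaseStep[seq_len(nMod)] <- rep(seq_len(lapSteps), each = perPhase)
    boostP01[seq_len(nMod)] <- boostA
    zoneCenterStep <- stepOfPosition(rewardPosition, beltLength, lapSteps)
  } else if (environment == "B") {
    nMod <- nChains - as.integer(nHomogeneousB)
    zoneCenterStep <- stepOfPosition(cuePosition, beltLength, lapSteps)
    stepPos <- (seq_len(lapSteps) - 0.5) * beltLength / lapSteps
    d <- circDist(stepPos, cuePosition, beltLength)
    w <- 1 + ENVB_DENSITY_A * exp(-d^2 / (2 * ENVB_SIGMA_CM^2))
    counts <- apportion(nMod, w)
    phaseStep[seq_len(nMod)] <- rep(seq_len(lapSteps), counts)
    boostP01[seq_len(nMod)] <- boostB
  }

  if (enhancedTuning) {
    if (environment == "uniform")
      stop("enhanced tuning requires environment A or B")
    boostVal <- if (environment == "A") boostEnhancedA else 3 * boostB
    mod <- which(!is.na(phaseStep))
    d <- pmin(abs(phaseStep[mod] - zoneCenterStep),
              lapSteps - abs(phaseStep[mod] - zoneCenterStep))
    sel <- mod[order(d)][seq_len(min(nEnhanced, length(mod)))]
    boostP01[sel] <- boostVal
  }

  cfg <- new("ChainConfig",
    nChains = nChains, dt = dt, lapSteps = as.integer(lapSteps),
    nLaps = as.integer(nLaps), burnIn = as.integer(lapSteps),
    p01Base = p01Base, p10 = p10,
    boostP01 = boostP01, phaseStep = phaseStep,
    boostSteps = as.integer(round(1 / dt)),
    environment = environment, enhanced = isTRUE(enhancedTuning),
    zoneCenterStep = zoneCenterStep)
  validObject(cfg)
  cfg
}

#' Simulate a population of two-state Markov chains
#'
#' Runs the chain population forward: at each time step an inactive chain
#' activates with probability P01*dt (baseline, or the chain's boost value
#' inside its recurring within-lap boost window) and an active chain
#' inactivates with probability P10*dt.  All chains start inactive; the
#' first lap (burn-in) is discarded so the retained states start from the
#' stationary regime.
#'
#' @param config a \code{\link{ChainConfig}}.
#' @param seed integer RNG seed.
#' @return a \code{\link{ChainPopulation}}
#' @examples
#' pop <- simulateChains(chainConfig("uniform", nChains = 50L), seed = 1)
#' mean(chainStates(pop))   # ~ P01 / (P01 + P10)
#' @export
simulateChains <- function(config, seed = 1L) {
  stopifnot(is(config, "ChainConfig"))
  set.seed(as.integer(seed))
  n <- config@nChains
  lapSteps <- config@lapSteps
  totalSteps <- config@burnIn + config@nLaps * lapSteps

  # per-chain activation probability at each within-lap phase
  p01Mat <- matrix(config@p01Base * config@dt, n, lapSteps)
  mod <- which(!is.na(config@phaseStep))
  for (i in mod) {
    win <- ((config@phaseStep[i] - seq_len(config@boostSteps)) %% lapSteps) + 1L
    p01Mat[i, win] <- config@boostP01[i] * config@dt
  }
  p10Step <- config@p10 * config@dt

  states <- matrix(0L, n, config@nLaps * lapSteps)
  s <- integer(n)
  for (t in seq_len(totalSteps)) {
    ph <- ((t - 1L) %% lapSteps) + 1L
    turnOn <- s == 0L & runif(n) <= p01Mat[, ph]
    turnOff <- s == 1L & runif(n) <= p10Step
    s[turnOn] <- 1L
    s[turnOff] <- 0L
    if (t > config@burnIn)
      states[, t - config@burnIn] <- s
  }
  new("ChainPopulation", states = states, config = config)
}

#' Build a step-to-bin dwell mapping
#'
#' Converts a dwell-time profile (seconds per spatial bin per lap) into an
#' assignment of within-lap time steps to spatial bins by cumulative dwell:
#' the step whose centre time falls inside a bin's cumulative dwell interval
#' belongs to that bin, so bins holding more time receive proportionally
#' more steps.  A constant-speed profile assigns exactly
#' \code{lapSteps / nBins} steps per bin.
#'
#' @param dwell numeric, seconds per bin (non-negative; zero-dwell bins are
#'   filled by circular interpolation with a warning).  Rescaled to sum to
#'   the model lap duration \code{lapSteps * dt}.
#' @param lapSteps steps per lap.
#' @param dt step duration, s.
#' @return a \code{\link{SpaceMapping}}
#' @examples
#' sm <- spaceMapping(rep(0.2, 50))
#' table(sm@stepBin)   # 2 steps in each of the 50 bins
#' @export
spaceMapping <- function(dwell, lapSteps = 100L, dt = 0.1) {
  nBins <- length(dwell)
  if (any(!is.finite(dwell)) || any(dwell < 0))
    stop("dwell profile must be finite and non-negative")
  if (any(dwell == 0)) {
    warning("zero-dwell bins interpolated from circular neighbours")
    dwell[dwell == 0] <- NA_real_
    dwell <- fillCircularNA(dwell)
  }
  lapDur <- lapSteps * dt
  dwell <- dwell / sum(dwell) * lapDur
  centers <- (seq_len(lapSteps) - 0.5) * dt
  stepBin <- findInterval(centers, cumsum(dwell)[-nBins]) + 1L
  sm <- new("SpaceMapping", dwell = dwell, stepBin = as.integer(stepBin),
            nBins = as.integer(nBins), dt = dt)
  validObject(sm)
  sm
}

#' Map chain activity from time to space
#'
#' Averages each chain's binary state over the steps assigned to each
#' spatial bin, lap by lap, and (by default) smooths each lap with a
#' circular three-point boxcar.
#'
#' @param population a \code{\link{ChainPopulation}}.
#' @param dwell a \code{\link{SpaceMapping}} (default: constant speed).
#' @param smooth logical, apply the boxcar.
#' @return numeric array [chain, lap, bin]
#' @export
mapTimeToSpace <- function(population, dwell = NULL, smooth = TRUE) {
  cfg <- population@config
  if (is.null(dwell))
    dwell <- spaceMapping(rep(cfg@lapSteps * cfg@dt / 50, 50),
                          cfg@lapSteps, cfg@dt)
  stopifnot(is(dwell, "SpaceMapping"))
  nBins <- dwell@nBins
  # indicator matrix step -> bin, columns normalised to bin step counts
  counts <- tabulate(dwell@stepBin, nBins)
  B <- matrix(0, cfg@lapSteps, nBins)
  B[cbind(seq_len(cfg@lapSteps), dwell@stepBin)] <- 1
  B <- sweep(B, 2, counts, "/")
  maps <- array(0, c(cfg@nChains, cfg@nLaps, nBins))
  for (l in seq_len(cfg@nLaps)) {
    cols <- ((l - 1L) * cfg@lapSteps + 1L):(l * cfg@lapSteps)
    m <- population@states[, cols, drop = FALSE] %*% B
    maps[, l, ] <- if (smooth) boxcar3Rows(m) else m
  }
  maps
}

#' Per-chain spatial metrics
#'
#' Computes, for each chain (or axon), the metrics used to compare model and
#' data: activity peak location, spatial selectivity index (max/mean of the
#' across-lap mean map), odd-even lap correlation and the associated
#' well-correlated flag (odd and even peaks within 10 cm, circular),
#' correlation between the mean map and the velocity map, and the fraction
#' of laps with any activity.
#'
#' @param maps numeric array [chain, lap, bin] from \code{\link{mapTimeToSpace}}
#'   or an \code{\link{ActivityMap}}-derived tensor.
#' @param velocityMap optional numeric per-bin mean velocity.
#' @param beltLength cm.
#' @return data.frame with one row per chain; silent chains carry NA metrics.
#' @export
chainMetrics <- function(maps, velocityMap = NULL, beltLength = 180) {
  d <- dim(maps)
  if (d[2] < 4L) stop("at least 4 laps are required")
  nBins <- d[3]
  binW <- beltLength / nBins
  odd <- seq(1, d[2], by = 2)
  even <- seq(2, d[2], by = 2)
  out <- data.frame(chain = seq_len(d[1]), peakBin = NA_integer_,
                    peakPosition = NA_real_, selectivity = NA_real_,
                    oddEvenCorr = NA_real_, wellCorrelated = NA,
                    velocityCorr = NA_real_, fracLapsActive = NA_real_)
  for (i in seq_len(d[1])) {
    m <- maps[i, , , drop = TRUE]
    if (all(m == 0)) next   # silent chain: metrics flagged absent
    mm <- colMeans(m)
    out$peakBin[i] <- which.max(mm)
    out$peakPosition[i] <- (out$peakBin[i] - 0.5) * binW
    out$selectivity[i] <- max(mm) / mean(mm)
    mo <- colMeans(m[odd, , drop = FALSE])
    me <- colMeans(m[even, , drop = FALSE])
    if (sd(mo) > 0 && sd(me) > 0) {
      out$oddEvenCorr[i] <- cor(mo, me)
      po <- (which.max(mo) - 0.5) * binW
      pe <- (which.max(me) - 0.5) * binW
      out$wellCorrelated[i] <- circDist(po, pe, beltLength) <= 10
    }
    if (!is.null(velocityMap) && sd(mm) > 0 && sd(velocityMap) > 0)
      out$velocityCorr[i] <- cor(mm, velocityMap)
    out$fracLapsActive[i] <- mean(apply(m, 1, function(r) any(r > 0)))
  }
  out
}

#' Histogram of activity peak locations and zone enrichment
#'
#' Normalised per-bin histogram of chain/axon peak locations, plus the fold
#' enrichment of a zone of bins relative to the off-zone bins
#' (per-bin peak fraction inside the zone divided by per-bin fraction
#' outside it).
#'
#' @param peakBin integer peak bins (NA = silent, dropped).
#' @param nBins bin count.
#' @param zone integer bin indices of the zone (optional).
#' @return list(fraction per bin, enrichment, nUnits)
#' @export
peakHistogram <- function(peakBin, nBins = 50L, zone = NULL) {
  pk <- peakBin[!is.na(peakBin)]
  frac <- tabulate(pk, nBins) / length(pk)
  enrichment <- NA_real_
  if (!is.null(zone)) {
    zf <- sum(frac[zone]) / length(zone)
    of <- sum(frac[-zone]) / (nBins - length(zone))
    enrichment <- zf / of
  }
  list(fraction = frac, enrichment = enrichment, nUnits = length(pk))
}

#' Bins within a distance of a track position
#'
#' @param positionCm centre of the zone, cm.
#' @param halfWidth cm (default 18, i.e. a 36-cm zone).
#' @param beltLength cm.
#' @param nBins bin count.
#' @return integer bin indices whose centres lie within halfWidth of the position
#' @export
zoneBinsAround <- function(positionCm, halfWidth = 18, beltLength = 180,
                           nBins = 50L) {
  centers <- (seq_len(nBins) - 0.5) * beltLength / nBins
  which(circDist(centers, positionCm, beltLength) <= halfWidth)
}

#' Active/inactive period statistics of a chain population
#'
#' Pools completed active and inactive period durations across chains
#' (censored first/last periods excluded) and reports their means and
#' coefficients of variation.  For a two-state chain the periods are
#' geometric (exponential in the continuum limit): mean inactive period
#' = 1/P01, mean active period = 1/P10, CV ~ 1.
#'
#' @param population a \code{\link{ChainPopulation}}.
#' @return list with elements \code{active} and \code{inactive}, each a list
#'   (durations, mean, cv, n)
#' @export
dwellStatistics <- function(population) {
  dt <- population@config@dt
  act <- list(); inact <- list()
  for (i in seq_len(nrow(population@states))) {
    r <- rle(as.integer(population@states[i, ]))
    if (length(r$lengths) < 3L) next   # no interior (uncensored) period
    keep <- 2:(length(r$lengths) - 1L)
    act[[length(act) + 1L]] <- r$lengths[keep][r$values[keep] == 1L]
    inact[[length(inact) + 1L]] <- r$lengths[keep][r$values[keep] == 0L]
  }
  aDur <- unlist(act) * dt
  iDur <- unlist(inact) * dt
  if (length(aDur) + length(iDur) == 0)
    stop("no completed active/inactive periods in the population")
  if (length(aDur) + length(iDur) < 100)
    warning("fewer than 100 completed periods; statistics will be noisy")
  summarise <- function(x) list(durations = x, mean = mean(x),
                                cv = sd(x) / mean(x), n = length(x))
  list(active = summarise(aDur), inactive = summarise(iDur))
}

#' Estimate transition rates from simulated states
#'
#' Transition-count estimator: P01 = (# inactive-to-active transitions) /
#' (time spent inactive), and analogously for P10.  Used as a
#' model-consistency check.
#'
#' @param population a \code{\link{ChainPopulation}}.
#' @return list(p01, p10) in 1/s
#' @export
estimateTransitionRates <- function(population) {
  s <- population@states
  dt <- population@config@dt
  from <- s[, -ncol(s), drop = FALSE]
  to <- s[, -1L, drop = FALSE]
  n01 <- sum(from == 0L & to == 1L)
  n10 <- sum(from == 1L & to == 0L)
  t0 <- sum(from == 0L) * dt
  t1 <- sum(from == 1L) * dt
  list(p01 = n01 / t0, p10 = n10 / t1)
}
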