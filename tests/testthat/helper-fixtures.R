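# Shared small fixtures, built once per test run.

fixtureEnv <- new.env()

# small env-A session (20 laps) reused across signal/place-cell tests
smallBehavior <- function() {
  if (is.null(fixtureEnv$beh))
    fixtureEnv$beh <- generateBehavior(20, "A", seed = 42)
  fixtureEnv$beh
}

# deterministic ActivityMap built straight from arrays (bypasses traces)
makeMap <- function(meanDff, occupancy = NULL, significant = NULL,
                    environment = "A", rewardBin = 26L) {
  d <- dim(meanDff)
  if (is.null(occupancy)) occupancy <- matrix(0.2, d[2], d[3])
  if (is.null(significant)) significant <- array(meanDff > 0.1, d)
  new("ActivityMap", meanDff = meanDff, occupancy = occupancy,
      significant = significant, nLaps = d[2], rewardBin = rewardBin,
      alignShift = 0L, binWidth = 180 / d[3], environment = environment,
      excludedLaps = integer(0))
}

# chain population with states given explicitly
makePopulation <- function(states, nLaps, lapSteps = ncol(states) / nLaps,
                           p01 = 0.04, p10 = 0.25) {
  n <- nrow(states)
  cfg <- new("ChainConfig", nChains = as.integer(n), dt = 0.1,
             lapSteps = as.integer(lapSteps), nLaps = as.integer(nLaps),
             burnIn = as.integer(lapSteps), p01Base = p01, p10 = p10,
             boostP01 = rep(NA_real_, n), phaseStep = rep(NA_integer_, n),
             boostSteps = 10L, environment = "uniform", enhanced = FALSE,
             zoneCenterStep = NA_integer_)
  new("ChainPopulation", states = states, config = cfg)
}
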