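# smaller-than-default populations keep these oracle checks fast; the
# full-size configuration is exercised by the acceptance suite

test_that("identical chains with matched inhibition cancel exactly", {
  set.seed(21)
  row <- as.integer(runif(500) < 0.3)
  states <- matrix(rep(row, each = 100), 100, 500, byrow = FALSE)
  pop <- makePopulation(states, nLaps = 5)
  dr <- simulatePopulationDrive(pop, nNeurons = 50, nInputs = 10,
                                inhibitionScale = 10 / 100, seed = 1)
  expect_equal(max(abs(dr$driveMax)), 0)
  expect_equal(max(abs(dr$driveMin)), 0)
})

test_that("population-mean drive vanishes when inhibition matches sampling", {
  pop <- simulateChains(chainConfig("uniform", nChains = 200L, nLaps = 10L),
                        seed = 22)
  dr <- simulatePopulationDrive(pop, nNeurons = 400, nInputs = 10,
                                inhibitionScale = 10 / 200, seed = 2)
  # expectation oracle: E[drive] = nInputs*p - scale*nChains*p = 0,
  # checked by direct averaging of reconstructed drives
  s <- chainStates(pop)
  inh <- (10 / 200) * colSums(s)
  meanDrive <- vapply(seq_len(50), function(i)
    mean(colSums(s[dr$sampleIdx[i, ], ]) - inh), numeric(1))
  expect_lt(abs(mean(meanDrive)), 0.2)
  expect_error(simulatePopulationDrive(pop, 10, 10, inhibitionScale = 1.5),
               "\\[0, 1\\]")
  expect_error(simulatePopulationDrive(pop, 10, nInputs = 500),
               "cannot exceed")
})

test_that("drives are reproducible under a fixed seed", {
  pop <- simulateChains(chainConfig("uniform", nChains = 100L, nLaps = 10L),
                        seed = 23)
  a <- simulatePopulationDrive(pop, nNeurons = 30, nInputs = 20, seed = 3)
  b <- simulatePopulationDrive(pop, nNeurons = 30, nInputs = 20, seed = 3)
  expect_identical(a$sampleIdx, b$sampleIdx)
  expect_identical(a$driveMax, b$driveMax)
})

test_that("extreme thresholds produce empty crossing profiles", {
  pop <- simulateChains(chainConfig("uniform", nChains = 200L, nLaps = 10L),
                        seed = 24)
  dr <- simulatePopulationDrive(pop, nNeurons = 100, nInputs = 20, seed = 4)
  above <- crossingProfile(dr, max(dr$driveMax) + 1)
  expect_equal(sum(crossingProfileOf(above)), 0)
  # below the global minimum the drive never comes from below: no events,
  # though every neuron's maximum exceeds the level
  below <- crossingProfile(dr, min(dr$driveMin) - 1)
  expect_equal(sum(crossingProfileOf(below)), 0)
  expect_true(all(dr$driveMax >= min(dr$driveMin) - 1))
})

test_that("recruited fraction is monotone above the calibrated threshold", {
  pop <- simulateChains(chainConfig("uniform", nChains = 300L, nLaps = 20L),
                        seed = 25)
  dr <- simulatePopulationDrive(pop, nNeurons = 500, nInputs = 30, seed = 5)
  cal <- calibrateThreshold(dr, c(0.15, 0.30))
  expect_gte(cal$recruitedFraction, 0.15)
  expect_lte(cal$recruitedFraction, 0.30)
  rec <- function(th) mean(dr$driveMax >= th & dr$driveMin < th)
  ths <- cal$threshold + seq(0, 3, by = 0.5)
  expect_true(all(diff(vapply(ths, rec, numeric(1))) <= 0))
  allZero <- makePopulation(matrix(0L, 50, 500), nLaps = 5)
  drz <- simulatePopulationDrive(allZero, 20, 10, seed = 6)
  expect_error(calibrateThreshold(drz), "degenerate|target band")
})

test_that("crossing counts are conserved between time and space", {
  pop <- simulateChains(chainConfig("uniform", nChains = 300L, nLaps = 20L),
                        seed = 26)
  dr <- simulatePopulationDrive(pop, nNeurons = 300, nInputs = 30, seed = 7)
  cal <- calibrateThreshold(dr, c(0.15, 0.30))
  dw <- rep(0.2, 50); dw[20:29] <- 0.4
  pr <- crossingProfile(dr, cal$threshold, spaceMapping(dw))
  expect_equal(sum(crossingProfileOf(pr)),
               sum(crossingProfileOf(pr, constantSpeed = TRUE)),
               tolerance = 1e-12)
  expect_true(all(crossingProfileOf(pr) >= 0))
})

test_that("doubling a zone's dwell roughly doubles its crossing share", {
  pop <- simulateChains(chainConfig("uniform", nChains = 400L, nLaps = 30L),
                        seed = 27)
  dr <- simulatePopulationDrive(pop, nNeurons = 2000, nInputs = 40, seed = 8)
  cal <- calibrateThreshold(dr, c(0.15, 0.30))
  zone <- 20:29
  for (k in c(2, 3)) {
    dw <- rep(0.2, 50); dw[zone] <- 0.2 * k
    p <- crossingProfileOf(crossingProfile(dr, cal$threshold,
                                           spaceMapping(dw)))
    enr <- (sum(p[zone]) / length(zone)) /
           (sum(p[-zone]) / (50 - length(zone)))
    expect_gt(enr, k * 0.75)
    expect_lt(enr, k * 1.25)
  }
})

test_that("profile comparison reports correlation and zone enrichment", {
  set.seed(28)
  model <- runif(50, 0.5, 1.5)
  self <- compareProfiles(model, model, zone = 21:31)
  expect_equal(self$R, 1)
  expect_equal(self$modelEnrichment, self$observedEnrichment)
  expect_error(compareProfiles(model, rep(2, 50)), "constant profile")
  # self-consistency: binomial counts drawn from the model profile
  counts <- rpois(50, 40 * model / mean(model))
  cc <- compareProfiles(model, counts)
  expect_gt(cc$R, 0.7)
})
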