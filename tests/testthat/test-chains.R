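test_that("environment configurations have the stated composition", {
  a <- chainConfig("A")
  expect_identical(sum(!is.na(a@boostP01)), 1400L)
  expect_identical(sum(is.na(a@boostP01)), 600L)
  ph <- a@phaseStep[!is.na(a@phaseStep)]
  expect_equal(as.integer(table(ph)), rep(14L, 100))   # 14-fold phase tiling
  expect_true(all(a@boostP01[!is.na(a@boostP01)] == 0.20))

  b <- chainConfig("B")
  expect_identical(sum(is.na(b@boostP01)), 150L)
  expect_true(all(b@boostP01[!is.na(b@boostP01)] == 0.28))

  u <- chainConfig("uniform")
  expect_true(all(is.na(u@boostP01)))

  expect_error(chainConfig("uniform", p01Base = 11), "\\[0, 1\\]")
})

test_that("enhanced tuning boosts ~100 chains nearest the salient location", {
  a <- chainConfig("A", enhancedTuning = TRUE)
  enh <- which(!is.na(a@boostP01) & a@boostP01 == 0.68)
  expect_identical(length(enh), 100L)
  d <- abs(a@phaseStep[enh] - a@zoneCenterStep)
  expect_true(all(pmin(d, 100 - d) <= 5))
})

test_that("zero activation probability keeps all chains silent", {
  pop <- simulateChains(chainConfig("uniform", nChains = 20L, p01Base = 0),
                        seed = 1)
  expect_identical(sum(chainStates(pop)), 0L)
})

test_that("lap view is a pure reshape of the state matrix", {
  pop <- simulateChains(chainConfig("uniform", nChains = 5L, nLaps = 6L),
                        seed = 2)
  lv <- lapView(pop)
  flat <- matrix(0L, 5, 600)
  for (l in 1:6) flat[, ((l - 1) * 100 + 1):(l * 100)] <- lv[, l, ]
  expect_identical(flat, chainStates(pop))
})

test_that("chain laws match the two-state closed forms", {
  pop <- simulateChains(chainConfig("uniform", nChains = 400L, nLaps = 200L),
                        seed = 3)
  expect_equal(mean(chainStates(pop)), 0.04 / 0.29, tolerance = 0.02)
  est <- estimateTransitionRates(pop)
  # binomial 99% CI of the transition-count estimator
  s <- chainStates(pop)
  n0 <- sum(s[, -ncol(s)] == 0L)
  n1 <- sum(s[, -ncol(s)] == 1L)
  se01 <- sqrt(0.004 * 0.996 / n0) / 0.1
  se10 <- sqrt(0.025 * 0.975 / n1) / 0.1
  expect_lt(abs(est$p01 - 0.04), 2.58 * se01)
  expect_lt(abs(est$p10 - 0.25), 2.58 * se10)
})

test_that("homogeneous populations are stationary across laps", {
  pop <- simulateChains(chainConfig("uniform"), seed = 4)
  lv <- lapView(pop)
  perLap <- apply(lv, 2, mean)
  # no drift or lap structure: lap-to-lap variation stays at the
  # population sampling noise level (a few percent of the mean)
  expect_lt(sd(perLap) / mean(perLap), 0.05)
  expect_lt(abs(cor(perLap, seq_along(perLap))), 0.5)
})

test_that("dwell statistics recover exponential period laws", {
  pop <- simulateChains(chainConfig("uniform", nChains = 300L, nLaps = 300L),
                        seed = 5)
  ds <- dwellStatistics(pop)
  expect_equal(ds$inactive$mean, 25, tolerance = 0.05)
  expect_equal(ds$active$mean, 4, tolerance = 0.05)
  expect_gt(ds$active$n + ds$inactive$n, 1e4)
  expect_gt(ds$inactive$cv, 0.9); expect_lt(ds$inactive$cv, 1.1)
  expect_gt(ds$active$cv, 0.9); expect_lt(ds$active$cv, 1.1)
  silent <- makePopulation(matrix(0L, 3, 500), nLaps = 5)
  expect_error(dwellStatistics(silent), "no completed")
})

test_that("step-to-bin assignment follows cumulative dwell", {
  sm <- spaceMapping(rep(0.2, 50))
  expect_equal(as.integer(table(sm@stepBin)), rep(2L, 50))
  dw <- rep(0.2, 50); dw[10:19] <- 0.4
  sm2 <- spaceMapping(dw)
  counts <- tabulate(sm2@stepBin, 50)
  # doubled-dwell bins receive about twice the steps (integer rounding)
  expect_gt(mean(counts[10:19]), 1.9 * mean(counts[-(10:19)]))
  expect_identical(sum(counts), 100L)
  expect_warning(spaceMapping(c(rep(0.2, 49), 0)), "interpolated")
})

test_that("time-to-space mapping averages states into bins", {
  states <- matrix(1L, 2, 400)
  pop <- makePopulation(states, nLaps = 4)
  maps <- mapTimeToSpace(pop)
  expect_equal(max(abs(maps - 1)), 0)
  # a chain active only in steps of bin 7 peaks there (unsmoothed)
  st <- matrix(0L, 1, 400)
  st[1, rep(c(13, 14), 4) + rep(0:3 * 100, each = 2)] <- 1L
  m <- mapTimeToSpace(makePopulation(st, nLaps = 4), smooth = FALSE)
  expect_equal(as.numeric(m[1, 1, ]), c(rep(0, 6), 1, rep(0, 43)))
})

test_that("chain metrics match arithmetic oracles", {
  constMaps <- array(0.5, c(1, 6, 50))
  met <- chainMetrics(constMaps)
  expect_equal(met$selectivity, 1)
  oneBin <- array(0, c(1, 6, 50)); oneBin[1, , 7] <- 1
  met <- chainMetrics(oneBin)
  expect_equal(met$selectivity, 50)
  expect_identical(met$peakBin, 7L)
  expect_equal(met$oddEvenCorr, 1)
  expect_true(met$wellCorrelated)
  expect_equal(met$fracLapsActive, 1)
  silentMaps <- array(0, c(1, 6, 50))
  expect_true(is.na(chainMetrics(silentMaps)$selectivity))
  expect_error(chainMetrics(array(0, c(1, 3, 50))), "4 laps")
})

test_that("uniform-configuration peaks tile the track uniformly", {
  pop <- simulateChains(chainConfig("uniform"), seed = 6)
  met <- chainMetrics(mapTimeToSpace(pop))
  h <- peakHistogram(met$peakBin)
  expect_true(all(abs(h$fraction - 0.02) < 5 * sqrt(0.02 * 0.98 / h$nUnits)))
  allOne <- peakHistogram(rep(7L, 30))
  expect_equal(allOne$fraction[7], 1)
  expect_equal(sum(allOne$fraction), 1)
})
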