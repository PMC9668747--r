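test_that("dF/F of a constant trace is identically zero", {
  rts <- RoiTraceSet(matrix(100, 1, 1500), 10L, 30, "ca1_soma")
  expect_equal(max(abs(dffValues(computeDff(rts)))), 0)
})

test_that("baseline mode is found in a bimodal trace (both estimators)", {
  set.seed(1)
  f <- c(rnorm(1800, 50, 0.8), rnorm(200, 75, 0.8))[sample(2000)]
  rts <- RoiTraceSet(matrix(f, 1, 2000), 10L, 30, "ca1_soma")
  for (m in c("shorth", "histogram")) {
    dff <- dffValues(computeDff(rts, method = m))
    hi <- dff[f > 70]
    expect_equal(mean(hi), 0.5, tolerance = 0.05)
    expect_lt(abs(median(dff[f < 60])), 0.02)
  }
})

test_that("dF/F is an algebraic identity under baseline reconstruction", {
  set.seed(2)
  f <- 80 * (1 + pmax(rnorm(3000, 0, 0.05), -0.9))
  rts <- RoiTraceSet(matrix(f, 1, 3000), 10L, 30, "ca1_soma")
  dff <- dffValues(computeDff(rts))
  rts2 <- RoiTraceSet(matrix(80 * (1 + dff), 1, 3000), 10L, 30, "ca1_soma")
  dff2 <- dffValues(computeDff(rts2))
  expect_equal(dff2, dff, tolerance = 1e-6)
})

test_that("transient detection has a low false-positive rate on pure noise", {
  set.seed(3)
  dff <- matrix(rnorm(3e4, 0, 0.05), 1)
  mask <- detectTransients(dff)
  expect_lt(mean(mask), 0.01)
})

test_that("an inserted 10-sigma transient is detected at its frames", {
  set.seed(4)
  sigma <- 0.05
  dff <- matrix(rnorm(5000, 0, sigma), 1)
  dff[1, 2000:2010] <- 10 * sigma
  mask <- detectTransients(dff)
  expect_true(all(mask[1, 2000:2010]))
  runs <- rle(mask[1, ])
  expect_identical(sum(runs$values), 1L)   # exactly one excursion
})

test_that("degenerate traces are rejected by transient detection", {
  expect_error(detectTransients(matrix(0, 1, 2000)), "zero noise")
})

test_that("identical ROI traces merge into one axon with the same trace", {
  set.seed(5)
  sig <- rnorm(2000, 0, 0.2)
  F <- rbind(100 * (1 + sig), 120 * (1 + sig))
  F <- pmax(F, 1)
  rts <- computeDff(RoiTraceSet(F, c(20L, 30L), 30, "ec3_axon"))
  g <- mergeRoisByNoiseCorrelation(rts, 0.45)
  expect_identical(max(g@roiToAxon), 1L)
  expect_equal(g@mergedDff[1, ], dffValues(rts)[1, ], tolerance = 0.02)
})

test_that("independent noise ROIs stay singleton axons", {
  set.seed(6)
  F <- matrix(100 * (1 + rnorm(6000, 0, 0.05)), 3)
  rts <- computeDff(RoiTraceSet(F, rep(10L, 3), 30, "ec3_axon"))
  g <- mergeRoisByNoiseCorrelation(rts, 0.45)
  expect_identical(max(g@roiToAxon), 3L)
  for (r in 1:3)
    expect_equal(g@mergedDff[g@roiToAxon[r], ], dffValues(rts)[r, ])
})

test_that("merging is restricted to axonal data", {
  rts <- computeDff(RoiTraceSet(matrix(runif(2000, 90, 110), 1), 10L, 30,
                                "ca1_soma"))
  expect_error(mergeRoisByNoiseCorrelation(rts), "EC3 axonal")
})

test_that("a constant trace maps to a constant activity map", {
  beh <- smallBehavior()
  dff <- matrix(0.5, 1, length(beh))
  map <- buildActivityMap(dff, beh, significant = dff > 0)
  expect_equal(max(abs(mapValues(map) - 0.5)), 0, tolerance = 1e-9)
})

test_that("activity at 90 cm lands in aligned bin 26 in environment A", {
  beh <- smallBehavior()
  # smooth hump centred on raw bin 26 (centre 91.8 cm)
  d <- abs(((beh@position - 91.8 + 90) %% 180) - 90)
  dff <- matrix(exp(-d^2 / (2 * 2^2)), 1)
  map <- buildActivityMap(dff, beh, significant = dff > 0.5)
  mm <- apply(mapValues(map)[1, , , drop = FALSE], 3, mean, na.rm = TRUE)
  expect_identical(which.max(mm), 26L)
})

test_that("maxLap truncates the lap dimension", {
  beh <- smallBehavior()
  dff <- matrix(0.1, 2, length(beh))
  map <- buildActivityMap(dff, beh, maxLap = 12,
                          significant = dff > 1)
  expect_identical(dim(mapValues(map))[2], 12L)
  expect_identical(nLaps(map), 12L)
})

test_that("summed occupancy equals running time per lap", {
  beh <- smallBehavior()
  dff <- matrix(0.1, 1, length(beh))
  map <- buildActivityMap(dff, beh, significant = dff > 1)
  running <- beh@velocity > 2
  lap1 <- beh@lapIndex + 1
  for (l in c(1, 10, 20)) {
    expect_equal(sum(occupancy(map)[l, ]),
                 sum(running & lap1 == l) / beh@frameRate,
                 tolerance = 1e-6)
  }
})

test_that("reward alignment is a pure rotation of the unaligned map", {
  beh <- smallBehavior()
  set.seed(7)
  dff <- matrix(rnorm(2 * length(beh), 0.2, 0.1), 2)
  sig <- dff > 0.35
  aligned <- buildActivityMap(dff, beh, significant = sig)
  raw <- buildActivityMap(dff, beh, significant = sig, align = FALSE)
  s <- aligned@alignShift
  ord <- ((seq_len(50) - 1L - s) %% 50L) + 1L
  expect_equal(mapValues(aligned), mapValues(raw)[, , ord, drop = FALSE])
  expect_equal(occupancy(aligned), occupancy(raw)[, ord])
})

test_that("circular boxcar smoothing preserves each lap's spatial mean", {
  beh <- smallBehavior()
  set.seed(8)
  dff <- matrix(rnorm(length(beh), 0.3, 0.2), 1)
  mapRaw <- buildActivityMap(dff, beh, significant = dff > 1e9)
  # rebuild the unsmoothed binned map by hand and compare lap means
  running <- beh@velocity > 2
  lap1 <- beh@lapIndex + 1
  bins <- floor(beh@position / 3.6) + 1
  for (l in c(3, 15)) {
    sel <- running & lap1 == l
    manual <- tapply(dff[1, sel], bins[sel], mean)
    manualFull <- rep(NA_real_, 50)
    manualFull[as.integer(names(manual))] <- manual
    smoothedLap <- mapValues(mapRaw)[1, l, ]
    s <- mapRaw@alignShift
    ord <- ((seq_len(50) - 1L - s) %% 50L) + 1L
    unaligned <- smoothedLap[order(ord)]
    expect_equal(mean(unaligned), mean(manualFull, na.rm = TRUE),
                 tolerance = 0.02)
  }
})

test_that("behaviour maps report licks, velocity and the reward dip", {
  behNoLick <- generateBehavior(10, "habituation",
                                speedParams = list(lapSpeedSd = 0,
                                                   noiseSd = 0,
                                                   stopProb = 0), seed = 9)
  bm <- behaviorMaps(behNoLick)
  expect_equal(bm$velocity, rep(18, 50), tolerance = 0.01)

  beh <- generateBehavior(30, "A", seed = 10)
  bm <- behaviorMaps(beh)
  expect_lte(min(abs(which.min(bm$velocity) - bm$rewardBin)), 3)
  behQuiet <- beh
  behQuiet@lick[] <- 0L
  expect_equal(behaviorMaps(behQuiet)$lickRate, rep(0, 50))
})
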