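test_that("spherical caps follow the closed-form profile and volume", {
  cfg <- synthConfig(nrow = 101L, ncol = 101L, pitch = 10, capRadius = 400,
                     capHeight = 300, undAmplitude = 0, dropoutProb = 0,
                     noiseSd = 0)
  t <- makeCap(cfg)
  expect_equal(heights(t)[51, 51], 300)          # z = h at the apex
  expect_equal(heights(t)[1, 1], 0)              # substrate outside
  footR <- sqrt(300 * (2 * 400 - 300))
  expect_equal(sum(heights(t) > 0) * 100, pi * footR^2, tolerance = 0.02)
  fine <- makeCap(synthConfig(nrow = 421L, ncol = 421L, pitch = 2,
                              capRadius = 400, capHeight = 300,
                              undAmplitude = 0, dropoutProb = 0, noiseSd = 0))
  expect_equal(topoVolume(fine, footprintMask(fine)),
               pi * 300^2 * (3 * 400 - 300) / 3, tolerance = 0.01)
  expect_error(makeCap(synthConfig(capRadius = 100, capHeight = 300)),
               "2r")
})

test_that("irregular shapes are connected, seeded, and classify irregular", {
  cfg <- synthConfig(shape = "irregular", seed = 11L, undAmplitude = 0,
                     dropoutProb = 0, noiseSd = 0)
  t1 <- makeIrregular(cfg)
  expect_identical(heights(makeIrregular(cfg)), heights(t1))
  m <- segmentObject(t1)   # validity guarantees a single component
  expect_identical(shapeReport(t1, m)$shape_class, "irregular")
  expect_warning(
    one <- makeIrregular(synthConfig(shape = "irregular", lobes = 1L)),
    "single cap")
  expect_equal(heights(one),
               heights(makeCap(synthConfig(shape = "irregular", lobes = 1L))))
})

test_that("undulations hit their RMS target and spare the substrate", {
  t0 <- makeCap(synthConfig(undAmplitude = 0, dropoutProb = 0, noiseSd = 0))
  fp <- heights(t0) > 0
  expect_identical(heights(addUndulations(t0, 0, 100, 1)), heights(t0))
  for (s in 1:10) {
    tu <- addUndulations(t0, 100, 100, seed = s)
    dz <- heights(tu) - heights(t0)
    expect_equal(dz[!fp], rep(0, sum(!fp)))
    expect_equal(sqrt(mean(dz[fp]^2)), 50, tolerance = 0.15)
  }
  expect_identical(heights(addUndulations(t0, 100, 100, 7)),
                   heights(addUndulations(t0, 100, 100, 7)))
})

test_that("edge memory decays linearly to zero and displaces the boundary", {
  t0 <- makeCap(synthConfig(undAmplitude = 0, dropoutProb = 0, noiseSd = 0))
  # at or past tZero the scans agree exactly
  done <- applyEdgeMemory(t0, delta0 = 100, tPrep = 20, tZero = 18.8)
  expect_equal(totalEdgeVolume(done), 0)
  # uniform one-column shift constructed by hand: TEV matches the
  # brute-force pixel sum of the constructed pair exactly
  f <- matrix(0, 40, 40); f[10:30, 10:20] <- 1000
  b <- matrix(0, 40, 40); b[10:30, 11:21] <- 1000
  pair <- ScanPair(Topography(f, 30, direction = "forward"),
                   Topography(b, 30, direction = "backward"))
  expect_equal(totalEdgeVolume(pair), 30 * 30 * sum(abs(b - f)))
  # frozen field, increasing t_prep: TEV non-increasing
  tu <- addUndulations(t0, 100, 100, 3)
  tev <- sapply(c(0, 4, 8, 12, 16, 18.8),
                function(tp) totalEdgeVolume(
                  applyEdgeMemory(tu, 100, tp, 18.8, seed = 5)))
  expect_true(all(diff(tev) <= 1e-6))
  expect_equal(tev[6], 0)
  # backward footprint grows outward at t = 0
  pr <- applyEdgeMemory(t0, 150, 0, 18.8, seed = 2)
  expect_gt(sum(heights(backwardScan(pr)) > 0),
            sum(heights(forwardScan(pr)) > 0))
})

test_that("dropout injection is seeded, eligible-only and q-calibrated", {
  cfg <- synthConfig(seed = 5L, dropoutProb = 0, noiseSd = 0)
  pair <- applyEdgeMemory(makeCap(cfg), 100, 0, 18.8, seed = 6)
  none <- applyDropouts(pair, q = 0, seed = 1)
  expect_identical(heights(forwardScan(none$pair)),
                   heights(forwardScan(pair)))
  expect_equal(nrow(none$dropouts), 0L)
  rerun1 <- applyDropouts(pair, q = 0.2, seed = 9)
  rerun2 <- applyDropouts(pair, q = 0.2, seed = 9)
  expect_identical(rerun1$dropouts, rerun2$dropouts)
  expect_identical(heights(backwardScan(rerun1$pair)),
                   heights(backwardScan(rerun2$pair)))
  # dropped pixels are set to substrate level
  d <- rerun1$dropouts; d <- d[d$direction == "forward", ]
  expect_true(all(heights(forwardScan(rerun1$pair))[cbind(d$row, d$col)] == 0))
  # start-rate calibration: observed starts / eligible within 3 sigma of q
  # (maxRun = 1 so every dropped pixel is one independent start)
  q <- 0.3
  starts <- sum(sapply(1:20, function(s)
    nrow(applyDropouts(pair, q = q, maxRun = 1L, seed = s)$dropouts)))
  eligCount <- function(h) {
    slope <- matrix(0, nrow(h), ncol(h))
    slope[, 2:(ncol(h) - 1)] <- (h[, 3:ncol(h)] - h[, 1:(ncol(h) - 2)]) /
      (2 * pitchX(pair))
    sum(abs(slope) > 1 & h >= 0.65 * max(h))
  }
  elig <- eligCount(heights(forwardScan(pair))) +
    eligCount(heights(backwardScan(pair)))
  nTrials <- 20 * elig
  expect_lt(abs(starts / nTrials - q), 3 * sqrt(q * (1 - q) / nTrials))
})

test_that("z-noise is seeded with the configured scale", {
  t0 <- makeCap(synthConfig(undAmplitude = 0, dropoutProb = 0, noiseSd = 0))
  expect_identical(heights(addNoise(t0, 0, 1)), heights(t0))
  n1 <- addNoise(t0, 1, seed = 3)
  expect_identical(heights(addNoise(t0, 1, seed = 3)), heights(n1))
  resid <- heights(n1) - heights(t0)
  expect_equal(sd(resid), 1, tolerance = 0.05)
})

test_that("study simulation is reproducible and ledgers true geometry", {
  base <- synthConfig(dropoutProb = 0)
  s1 <- simulateStudy(n = 6, masterSeed = 13, base = base)
  s2 <- simulateStudy(n = 6, masterSeed = 13, base = base)
  expect_identical(s1$truth, s2$truth)
  for (i in seq_along(s1$records))
    expect_identical(heights(forwardScan(s1$records[[i]]@pair)),
                     heights(forwardScan(s2$records[[i]]@pair)))
  # serialized datasets are byte-identical for the same master seed
  withr::with_tempdir({
    writeStudy(s1, "a"); writeStudy(s2, "b")
    for (f in list.files("a"))
      expect_identical(readLines(file.path("a", f)),
                       readLines(file.path("b", f)))
  })
  # ledgered closed-form V and SA agree with the measured metrics on the
  # noiseless grid (generator-analyzer loop closure)
  sph <- s1$truth[s1$truth$shape == "spherical_cap", ]
  expect_gt(nrow(sph), 0)
  for (i in seq_len(nrow(sph))) {
    cfg <- synthConfig(shape = "spherical_cap",
                       capRadius = sph$capRadius[i],
                       capHeight = sph$capHeight[i],
                       undAmplitude = 0, dropoutProb = 0, noiseSd = 0)
    ideal <- makeCap(cfg)
    m <- footprintMask(ideal)
    expect_equal(topoVolume(ideal, m), sph$trueVolume[i], tolerance = 0.02)
    expect_equal(surfaceArea(ideal, m), sph$trueSurfaceArea[i],
                 tolerance = 0.03)
  }
})

test_that("without edge memory TEV reduces to the folded-Gaussian floor", {
  base <- synthConfig(dropoutProb = 0)
  n <- base@nrow * base@ncol
  tevs <- sapply(1:5, function(s) {
    sim <- simulateRecord(synthConfig(dropoutProb = 0, delta0 = 0,
                                      seed = s * 101L))
    totalEdgeVolume(sim$record@pair)
  })
  floorOracle <- base@pitch^2 * n * 2 * base@noiseSd / sqrt(pi)
  expect_equal(mean(tevs), floorOracle, tolerance = 0.02)
})
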