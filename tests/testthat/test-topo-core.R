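test_that("topography and pair validity invariants are enforced", {
  expect_error(Topography(matrix(1, 2, 2), pitchX = 0), "positive")
  expect_error(Topography(matrix(Inf, 2, 2), pitchX = 1), "finite")
  expect_silent(Topography(matrix(c(1, NA, 2, 3), 2), pitchX = 1))
  fwd <- Topography(matrix(0, 4, 4), 10, direction = "forward")
  bwd <- Topography(matrix(0, 4, 4), 10, direction = "backward")
  expect_s4_class(ScanPair(fwd, bwd), "ScanPair")
  expect_error(ScanPair(fwd, Topography(matrix(0, 4, 5), 10,
                                        direction = "backward")),
               "dimensions")
  expect_error(ScanPair(fwd, fwd), "directions")
  expect_error(MeasurementRecord("a", ScanPair(fwd, bwd), tPrep = -1),
               "non-negative")
})

test_that("object masks must be single connected components", {
  m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE
  expect_s4_class(ObjectMask(m), "ObjectMask")
  m2 <- m; m2[5, 5] <- TRUE
  expect_error(ObjectMask(m2), "single connected")
  # diagonal touch is connected under 8- but not 4-connectivity
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_s4_class(ObjectMask(d, connectivity = 8L), "ObjectMask")
  expect_error(ObjectMask(d, connectivity = 4L), "single connected")
})

test_that("ascii_matrix round trip is bit-for-bit and keeps metadata", {
  withr::with_tempdir({
    t <- Topography(matrix(c(1.5, 2.5, 3.5, 4.5), 2), pitchX = 10)
    writeTopography(t, "tiny.txt")
    back <- readTopography("tiny.txt")
    expect_identical(dim(heights(back)), c(2L, 2L))
    expect_equal(pitchX(back), 10)
    set.seed(42)
    big <- Topography(matrix(rnorm(64 * 64) * 1000, 64), pitchX = 17.5,
                      pitchY = 12.25, direction = "backward")
    writeTopography(big, "rand.txt")
    rt <- readTopography("rand.txt")
    expect_identical(heights(rt), heights(big))
    expect_identical(pitchY(rt), 12.25)
    expect_identical(scanDirection(rt), "backward")
  })
})

test_that("missing pixels and metadata errors are handled per dialect", {
  withr::with_tempdir({
    h <- matrix(rnorm(25, 100, 10), 5); h[2, 3] <- NA
    t <- Topography(h, pitchX = 5)
    for (d in c("ascii_matrix", "csv", "float_tiff")) {
      f <- paste0("m_", d, switch(d, ascii_matrix = ".txt", csv = ".csv",
                                  float_tiff = ".tif"))
      writeTopography(t, f, d)
      back <- readTopography(f, d)
      expect_true(is.na(heights(back)[2, 3]))
      tol <- if (d == "float_tiff") 1e-4 else 1e-12
      expect_equal(heights(back), heights(t), tolerance = tol)
    }
    # pitch absent from file and not supplied -> metadata error
    writeLines(c("# direction: forward", "1 2", "3 4"), "nopitch.txt")
    expect_error(readTopography("nopitch.txt"), "metadata")
    expect_s4_class(readTopography("nopitch.txt", pitchX = 10),
                    "Topography")
    writeLines(c("# pitch_x_nm: 10", "1 x", "3 4"), "bad.txt")
    expect_error(readTopography("bad.txt"), "parse")
  })
})

test_that("manifest loading survives missing files", {
  withr::with_tempdir({
    study <- simulateStudy(n = 2, masterSeed = 9,
                           base = synthConfig(nrow = 32L, ncol = 32L,
                                              pitch = 120))
    mf <- writeStudy(study, ".")
    manifest <- readManifest(mf)
    recs <- loadMeasurements(manifest, ".")
    expect_length(Filter(Negate(is.null), recs), 2L)
    expect_equal(heights(forwardScan(recs[[1]]@pair)),
                 heights(forwardScan(study$records[[1]]@pair)))
    manifest2 <- rbind(manifest, manifest[1, ])
    manifest2$id[3] <- "ghost"; manifest2$forward[3] <- "missing.txt"
    recs2 <- loadMeasurements(manifest2, ".")
    expect_null(recs2[["ghost"]])
    expect_match(attr(recs2, "failures"), "ghost")
  })
})

test_that("row-median alignment zeroes every row median and keeps shape", {
  t <- randomTopo(12, 9, seed = 3)
  out <- alignRowsMedian(t)
  expect_equal(apply(heights(out), 1, median), rep(0, 12))
  # per-row shifts only: within-row differences unchanged
  expect_equal(t(apply(heights(out), 1, diff)),
               t(apply(heights(t), 1, diff)))
  # flat grid with per-row offsets collapses to zero
  off <- matrix(c(5, -3, 11), 3, 4)
  expect_equal(heights(alignRowsMedian(Topography(off, 1))),
               matrix(0, 3, 4))
  # adding a global constant commutes
  t2 <- t; t2@heights <- t2@heights + 123.4
  expect_equal(heights(alignRowsMedian(t2)), heights(out))
})

test_that("median-of-differences alignment removes a row staircase", {
  g <- sin(seq(0, 3, length.out = 8)) * 40          # within-row shape
  stair <- outer(1:6 * 13, rep(1, 8)) + outer(rep(1, 6), g)
  out <- alignRowsMedianDiff(Topography(stair, 5))
  # all rows identical after correction, anchored at zero minimum
  expect_equal(heights(out), outer(rep(1, 6), g - min(g)))
  d <- heights(out)
  expect_equal(apply(d[-1, ] - d[-6, ], 1, median), rep(0, 5))
  expect_error(alignRowsMedianDiff(Topography(matrix(1, 1, 5), 1)), "rows")
  const <- Topography(matrix(7, 4, 4), 1)
  expect_equal(heights(alignRowsMedianDiff(const)), matrix(0, 4, 4))
})

test_that("mean-plane subtraction leaves a zero best-fit plane", {
  nr <- 20; nc <- 25; pitch <- 10
  x <- (seq_len(nc) - 0.5) * pitch; y <- (seq_len(nr) - 0.5) * pitch
  plane <- outer(y * 0.3, rep(1, nc)) + outer(rep(1, nr), x * -0.2) + 40
  expect_equal(heights(subtractMeanPlane(Topography(plane, pitch))),
               matrix(0, nr, nc), tolerance = 1e-10)
  dome <- outer(exp(-(y - 100)^2 / 2000), exp(-(x - 125)^2 / 2000)) * 500
  out <- heights(subtractMeanPlane(Topography(plane + dome, pitch)))
  # refit a plane on the output: coefficients must vanish
  X <- rep(x, each = nr); Y <- rep(y, nc)
  beta <- coef(lm(as.vector(out) ~ X + Y))
  expect_equal(unname(beta[2:3]), c(0, 0), tolerance = 1e-10)
  expect_error(subtractMeanPlane(Topography(matrix(1, 1, 5), 1)),
               "degenerate")
})

test_that("zero floor and preprocessing stability", {
  t <- randomTopo(10, 10, seed = 7)
  z <- zeroFloor(t)
  expect_equal(min(heights(z)), 0)
  expect_equal(heights(z) - heights(t),
               matrix(-min(heights(t)), 10, 10))
  expect_equal(heights(zeroFloor(z)), heights(z))
  # each correction is an exact projection (idempotent on its own)
  a <- alignRowsMedian(t)
  expect_equal(heights(alignRowsMedian(a)), heights(a), tolerance = 1e-12)
  p <- subtractMeanPlane(t)
  expect_equal(heights(subtractMeanPlane(p)), heights(p),
               tolerance = 1e-12)
  # the composed chain is contractive: a second pass changes the result
  # by far less than the first pass changed the input (the row-median and
  # plane projections do not commute, so one-step equality cannot hold)
  chain <- function(t) preprocessTopography(
    t, c("align_rows_median", "subtract_mean_plane", "zero_floor"))
  nr <- 40; nc <- 40; pitch <- 10
  x <- (1:nc - 0.5) * pitch; y <- (1:nr - 0.5) * pitch
  dome <- outer(exp(-(y - 200)^2 / 8000), exp(-(x - 200)^2 / 8000)) * 800
  plane <- outer(y * 0.2, rep(1, nc)) + outer(rep(1, nr), x * -0.1) + 30
  set.seed(7)
  raw <- Topography(dome + plane + matrix(rnorm(nr, 0, 20), nr, nc), pitch)
  once <- chain(raw); twice <- chain(once)
  firstPass <- max(abs(heights(once) - heights(raw)))
  secondPass <- max(abs(heights(twice) - heights(once)))
  expect_lt(secondPass, 0.05 * firstPass)
  expect_lt(secondPass, 0.02 * diff(range(heights(once))))
  expect_identical(dim(heights(once)), dim(heights(raw)))
  expect_identical(pitchX(once), pitchX(raw))
})

test_that("segmentation keeps the largest component and fills holes", {
  t <- plateauTopo(32, 32, 5:24, 5:24)
  m <- segmentObject(t, 0.1)
  expect_equal(sum(maskMatrix(m)), 400)
  two <- plateauTopo(40, 40, 3:22, 3:22)        # 400 px
  two@heights[30:34, 30:39] <- 1000             # 50 px
  expect_equal(sum(maskMatrix(segmentObject(two))), 400)
  donut <- plateauTopo(32, 32, 5:24, 5:24)
  donut@heights[12:16, 12:16] <- 0
  expect_equal(sum(maskMatrix(segmentObject(donut))), 400)  # hole filled
  expect_error(segmentObject(Topography(matrix(0, 8, 8), 1)),
               "segmentation error")
  tiny <- plateauTopo(16, 16, 8:9, 8:9)
  expect_error(segmentObject(tiny, minPixels = 16), "segmentation error")
})
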