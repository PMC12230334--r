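# Fixtures are built in code; nothing is stored on disk.

# Ideal discretized hemisphere (cap with h = r), frame padded to `half` nm.
hemisphereTopo <- function(r = 500, pitch = 5, half = 1.1 * r) {
  n <- 2L * ceiling(half / pitch) + 1L
  makeCap(synthConfig(nrow = n, ncol = n, pitch = pitch,
                      capRadius = r, capHeight = r,
                      undAmplitude = 0, dropoutProb = 0, noiseSd = 0))
}

footprintMask <- function(t) ObjectMask(heights(t) > 0)

# Rectangular plateau of the given height (nm) on a zero substrate.
plateauTopo <- function(nrow = 32, ncol = 32, rows, cols, height = 1000,
                        pitch = 20) {
  h <- matrix(0, nrow, ncol)
  h[rows, cols] <- height
  Topography(h, pitchX = pitch, pitchY = pitch)
}

randomTopo <- function(nrow = 16, ncol = 16, pitch = 10, seed = 1) {
  set.seed(seed)
  Topography(matrix(rnorm(nrow * ncol, 50, 20), nrow), pitchX = pitch)
}

# Dropout detection harness: pixel-level precision/recall of the
# intermittency summary against the generator's ground truth.
dropoutScores <- function(seeds, q = 0.15) {
  flaggedKeys <- character(0); truthKeys <- character(0)
  hits <- 0L
  key <- function(d) paste(d$direction, d$row, d$col)
  for (s in seeds) {
    sim <- simulateRecord(synthConfig(seed = s, dropoutProb = q))
    pre <- ScanPair(
      preprocessTopography(forwardScan(sim$record@pair),
                           c("subtract_mean_plane", "zero_floor")),
      preprocessTopography(backwardScan(sim$record@pair),
                           c("subtract_mean_plane", "zero_floor")))
    mask <- segmentObject(forwardScan(pre))
    im <- intermittencySummary(pre, mask)
    flag <- do.call(rbind, c(list(
      data.frame(direction = character(0), row = integer(0),
                 col = integer(0))),
      lapply(seq_len(nrow(im$events)), function(i) {
        e <- im$events[i, ]
        data.frame(direction = e$direction, row = e$row,
                   col = e$start_col:e$end_col)
      })))
    flaggedKeys <- c(flaggedKeys, paste(s, key(flag)))
    truthKeys <- c(truthKeys, paste(s, key(sim$truth$dropouts)))
  }
  list(precision = mean(flaggedKeys %in% truthKeys),
       recall = mean(truthKeys %in% flaggedKeys),
       nTruth = length(truthKeys), nFlagged = length(flaggedKeys))
}

# TEV-vs-time recovery: simulate a study, derive groups from the measured
# equivalent-sphere diameter, fit the trend.
recoverTrend <- function(masterSeed, n = 30, base = synthConfig()) {
  study <- simulateStudy(n = n, masterSeed = masterSeed, base = base)
  pts <- lapply(study$records, function(rec) {
    fwd <- forwardScan(rec@pair)
    mask <- segmentObject(fwd)
    d <- sizeDescriptors(fwd, mask)$d_sphere_equiv
    data.frame(id = rec@id, t_prep_h = rec@tPrep,
               tev_nm3 = totalEdgeVolume(rec@pair),
               group = splitByEquivalentDiameter(d),
               complete = rec@complete)
  })
  tevTrend(do.call(rbind, pts))
}
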