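#' Ideal cap-shaped object on a flat substrate
#'
#' Builds the noiseless height field of a spherical or ellipsoidal cap
#' centered in the frame: \eqn{z(\rho) = \sqrt{r^2 - \rho^2} - (r - h)}
#' inside the footprint \eqn{\rho \le \sqrt{h(2r - h)}}, 0 outside. The
#' ellipsoidal variant scales the x semi-axis by the configured
#' ellipticity. This is the shape family of isolated, substrate-immobilized
#' mitochondria as seen from above.
#'
#' @param config a [SynthConfig].
#' @return a forward-direction [Topography] of the ideal shape.
#' @examples
#' heights(makeCap(synthConfig(nrow = 64, ncol = 64, pitch = 40)))[32, 32]
#' @export
makeCap <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  r <- config@capRadius; h <- config@capHeight
  if (h > 2 * r) stop("cap height must not exceed 2r")
  ex <- if (config@shape == "ellipsoidal_cap") config@ellipticity else 1
  nr <- config@nrow; nc <- config@ncol; pitch <- config@pitch
  x <- pixelCenters(nc, pitch); y <- pixelCenters(nr, pitch)
  cx <- mean(x); cy <- mean(y)
  rho2 <- outer((y - cy)^2, ((x - cx) / ex)^2, "+")
  z <- sqrt(pmax(r^2 - rho2, 0)) - (r - h)
  z[rho2 > h * (2 * r - h)] <- 0
  z[z < 0] <- 0
  Topography(z, pitchX = pitch, pitchY = pitch, direction = "forward")
}

#' Ideal irregular multi-lobed object
#'
#' Pixelwise maximum of a central cap and several displaced caps with
#' randomized radii, heights and lobe directions; deterministic for a given
#' seed. The central cap keeps the union connected; strongly displaced
#' lobes produce outlines whose roundness exceeds the 15% classification
#' tolerance.
#'
#' @param config a [SynthConfig] with `lobes >= 2`; a request for one lobe
#'   falls back to [makeCap()] with a warning.
#' @return a forward-direction [Topography].
#' @export
makeIrregular <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  if (config@lobes < 2L) {
    warning("lobes < 2: falling back to a single cap")
    return(makeCap(config))
  }
  r <- config@capRadius; h <- config@capHeight
  nr <- config@nrow; nc <- config@ncol; pitch <- config@pitch
  x <- pixelCenters(nc, pitch); y <- pixelCenters(nr, pitch)
  cx <- mean(x); cy <- mean(y)
  withSeed(config@seed, {
    k <- config@lobes
    ang <- c(0, 2 * pi * (seq_len(k) - 1) / k + stats::runif(k, -0.3, 0.3))
    disp <- c(0, config@lobeAmplitude * r * stats::runif(k, 0.7, 1))
    rl <- c(0.6 * r, r * stats::runif(k, 0.45, 0.7))
    hl <- pmin(c(0.8 * h, h * stats::runif(k, 0.5, 0.9)), 2 * rl)
    k <- k + 1L   # central lobe glues the union into one component
    z <- matrix(0, nr, nc)
    for (i in seq_len(k)) {
      lx <- cx + disp[i] * cos(ang[i]); ly <- cy + disp[i] * sin(ang[i])
      rho2 <- outer((y - ly)^2, (x - lx)^2, "+")
      zi <- sqrt(pmax(rl[i]^2 - rho2, 0)) - (rl[i] - hl[i])
      zi[rho2 > hl[i] * (2 * rl[i] - hl[i])] <- 0
      zi[zi < 0] <- 0
      z <- pmax(z, zi)
    }
    Topography(z, pitchX = pitch, pitchY = pitch, direction = "forward")
  })
}

#' Add shallow membrane undulations to an ideal shape
#'
#' Superimposes a band-limited Gaussian random field (correlation length
#' `corrLength`) on the object only, scaled so its RMS inside the footprint
#' equals `amplitude / 2` (the configured amplitude is read as
#' peak-to-peak). The field is tapered with `tanh(z/amplitude)` towards the
#' footprint boundary so the rim is not pushed below the substrate, then
#' rescaled to hit the RMS target after tapering. Substrate pixels are
#' untouched. Deterministic per seed.
#'
#' @param t ideal [Topography] (substrate exactly 0).
#' @param amplitude peak-to-peak undulation amplitude, nm.
#' @param corrLength lateral correlation length, nm.
#' @param seed integer seed.
#' @return the undulated [Topography].
#' @export
addUndulations <- function(t, amplitude, corrLength, seed) {
  stopifnot(is(t, "Topography"), amplitude >= 0)
  if (amplitude == 0) return(t)
  h <- t@heights
  fp <- h > 0
  if (!any(fp)) return(t)
  withSeed(seed, {
    field <- gaussSmooth(matrix(stats::rnorm(length(h)), nrow(h)),
                         sigmaPx = corrLength / t@pitchX)
    field <- field * tanh(h / amplitude)
    rms <- sqrt(mean(field[fp]^2))
    field <- field * (amplitude / 2) / rms
    h[fp] <- pmax(h[fp] + field[fp], 0)
    t@heights <- h
    t
  })
}

.edgeMemoryDelta <- function(delta0, tPrep, tZero)
  delta0 * max(0, 1 - tPrep / tZero)

#' Apply the edge memory effect to an ideal object
#'
#' Produces a scan pair in which the backward scan sees the object's
#' footprint boundary displaced laterally relative to the forward scan, the
#' phenomenological signature of a specimen responding morphodynamically to
#' the probe's previous pass. The displacement magnitude decays linearly
#' with time since preparation, \eqn{\delta(t_P) = \delta_0 \max(0,
#' 1 - t_P/t_{zero})}, and is modulated asymmetrically around the object
#' (one side displaced more), plus a smooth seeded per-angle perturbation.
#' Implementation: per-angle radial rescale of the ideal field about the
#' footprint centroid, moving the boundary outward by \eqn{\delta(\theta)}.
#'
#' @param ideal an ideal (optionally undulated) [Topography].
#' @param delta0 displacement magnitude at `tPrep = 0`, nm.
#' @param tPrep time since preparation, h.
#' @param tZero decay time at which the displacement reaches zero, h.
#' @param anisotropy relative amplitude of the one-sided modulation (0..1).
#' @param phase angle (rad) of the most-displaced side.
#' @param seed integer seed for the per-angle perturbation.
#' @return a [ScanPair] (forward = the ideal field).
#' @export
applyEdgeMemory <- function(ideal, delta0, tPrep, tZero, anisotropy = 0.5,
                            phase = 0, seed = 1L) {
  stopifnot(is(ideal, "Topography"), delta0 >= 0, tZero > 0)
  fwd <- ideal; fwd@direction <- "forward"
  deltaT <- .edgeMemoryDelta(delta0, tPrep, tZero)
  bwd <- ideal; bwd@direction <- "backward"
  if (deltaT > 0) {
    h <- ideal@heights
    fp <- h > 0
    nr <- nrow(h); nc <- ncol(h)
    x <- pixelCenters(nc, ideal@pitchX); y <- pixelCenters(nr, ideal@pitchY)
    cx <- sum(colSums(fp) * x) / sum(fp)
    cy <- sum(rowSums(fp) * y) / sum(fp)
    rRef <- sqrt(sum(fp) * ideal@pitchX * ideal@pitchY / pi)
    X <- matrix(x, nr, nc, byrow = TRUE) - cx
    Y <- matrix(y, nr, nc) - cy
    theta <- atan2(Y, X)
    pert <- withSeed(seed, {
      a <- stats::runif(3, 0, 0.15); ph <- stats::runif(3, 0, 2 * pi)
      a[1] * cos(2 * theta + ph[1]) + a[2] * cos(3 * theta + ph[2]) +
        a[3] * cos(4 * theta + ph[3])
    })
    delta <- pmax(deltaT * (1 + anisotropy * cos(theta - phase) + pert), 0)
    s <- rRef / (rRef + delta)
    ri <- (cy + Y * s) / ideal@pitchY + 0.5
    ci <- (cx + X * s) / ideal@pitchX + 0.5
    bwd@heights <- matrix(interpBilinear(h, as.vector(ri), as.vector(ci)),
                          nr, nc)
  }
  ScanPair(fwd, bwd)
}

#' Inject stochastic height dropouts at steep edges
#'
#' Pixels on the steep upper shoulder of the object (fast-axis slope
#' magnitude above `slopeThreshold` and height at least 65% of the scan
#' maximum) start a dropout run with probability `q`; the run continues
#' along the fast axis over further eligible pixels up to `maxRun` pixels.
#' Dropped pixels are set to the substrate level (0); both scan directions
#' are processed independently. The true dropped-pixel list is returned for
#' benchmarking detectors.
#'
#' @param pair a [ScanPair].
#' @param q per-eligible-pixel dropout probability, in \[0, 1\].
#' @param slopeThreshold fast-axis slope magnitude (nm/nm) for eligibility.
#' @param maxRun maximum run length, pixels.
#' @param seed integer seed.
#' @return list with `pair` (the modified [ScanPair]) and `dropouts`
#'   (data.frame `direction`, `row`, `col` of every dropped pixel).
#' @export
applyDropouts <- function(pair, q, slopeThreshold = 1, maxRun = 3L,
                          seed = 1L) {
  stopifnot(is(pair, "ScanPair"), q >= 0, q <= 1)
  truth <- list()
  withSeed(seed, {
    for (dir in c("forward", "backward")) {
      t <- slot(pair, dir)
      h <- t@heights
      if (q > 0) {
        nr <- nrow(h); nc <- ncol(h)
        slope <- matrix(0, nr, nc)
        slope[, 2:(nc - 1)] <-
          (h[, 3:nc] - h[, 1:(nc - 2)]) / (2 * t@pitchX)
        zmax <- max(h, na.rm = TRUE)
        eligible <- abs(slope) > slopeThreshold & h >= 0.65 * zmax
        for (r in seq_len(nr)) {
          cols <- which(eligible[r, ])
          cc <- 1L
          while (cc <= length(cols)) {
            if (stats::runif(1) < q) {
              len <- sample.int(maxRun, 1L)
              run <- cols[cc]
              while (length(run) < len) {
                nxt <- run[length(run)] + 1L
                if (nxt > nc || !eligible[r, nxt]) break
                run <- c(run, nxt)
              }
              h[r, run] <- 0
              truth[[length(truth) + 1L]] <-
                data.frame(direction = dir, row = r, col = run)
              cc <- cc + sum(cols >= run[1] & cols <= run[length(run)])
            } else cc <- cc + 1L
          }
        }
        t@heights <- h
        slot(pair, dir) <- t
      }
    }
  })
  dropouts <- if (length(truth)) do.call(rbind, truth) else
    data.frame(direction = character(0), row = integer(0), col = integer(0))
  list(pair = pair, dropouts = dropouts)
}

#' Add Gaussian z-noise
#'
#' Independent Gaussian noise per pixel, emulating the about 1 nm
#' z-resolution of the instrument. Deterministic per seed.
#'
#' @param t a [Topography].
#' @param sd noise standard deviation, nm.
#' @param seed integer seed.
#' @return the noisy [Topography].
#' @export
addNoise <- function(t, sd = 1, seed = 1L) {
  stopifnot(is(t, "Topography"), sd >= 0)
  if (sd == 0) return(t)
  withSeed(seed, {
    t@heights <- t@heights + matrix(stats::rnorm(length(t@heights), 0, sd),
                                    nrow(t@heights))
    t
  })
}

#' Generate one synthetic measurement record with ground truth
#'
#' Composes the ideal shape, undulations, edge memory, dropouts and
#' z-noise for one [SynthConfig]. All randomness derives from
#' `config@seed`.
#'
#' @param config a [SynthConfig].
#' @param id record label.
#' @param specimen specimen label stored in the record.
#' @param complete completeness flag stored in the record.
#' @return list with `record` (a [MeasurementRecord]) and `truth` (list:
#'   the config, the realized edge displacement `delta`, the dropout pixel
#'   table, and for spherical caps the closed-form `volume`
#'   \eqn{\pi h^2 (3r - h)/3} and lateral `surfaceArea` \eqn{2\pi r h} of
#'   the ideal shape).
#' @export
simulateRecord <- function(config, id = "synth", specimen = "synthetic",
                           complete = TRUE) {
  stopifnot(is(config, "SynthConfig"))
  s <- config@seed
  ideal <- if (config@shape == "irregular") makeIrregular(config)
           else makeCap(config)
  und <- addUndulations(ideal, config@undAmplitude, config@undLength,
                        seed = s + 1L)
  pair <- applyEdgeMemory(und, config@delta0, config@tPrep, config@tZero,
                          config@anisotropy, config@anisotropyPhase,
                          seed = s + 2L)
  dp <- applyDropouts(pair, config@dropoutProb, config@slopeThreshold,
                      config@maxRun, seed = s + 3L)
  pair <- dp$pair
  pair@forward <- addNoise(pair@forward, config@noiseSd, seed = s + 4L)
  pair@backward <- addNoise(pair@backward, config@noiseSd, seed = s + 5L)
  r <- config@capRadius; h <- config@capHeight
  truth <- list(
    config = config,
    delta = .edgeMemoryDelta(config@delta0, config@tPrep, config@tZero),
    dropouts = dp$dropouts,
    volume = if (config@shape == "spherical_cap")
      pi * h^2 * (3 * r - h) / 3 else NA_real_,
    surfaceArea = if (config@shape == "spherical_cap")
      2 * pi * r * h else NA_real_)
  list(record = MeasurementRecord(id, pair, tPrep = config@tPrep,
                                  specimen = specimen, complete = complete),
       truth = truth)
}

#' Simulate a full measurement study
#'
#' Generates `n` measurement records whose marginals mirror the measured
#' study conditions: object sizes drawn from a two-component mixture
#' (submitochondrial particles a few hundred nm across, mitochondria above
#' about 1.5 um), a fraction of irregular multi-lobed shapes, undulations,
#' a linearly decaying edge-memory displacement with 10% record-to-record
#' magnitude jitter, stochastic edge dropouts and 1 nm z-noise. The
#' `"fixed"` preset switches the edge memory off (fixed specimens show no
#' morphodynamic response). All randomness flows from `masterSeed`;
#' regeneration is bit-reproducible.
#'
#' @param n number of records.
#' @param masterSeed integer master seed.
#' @param preset `"active"` (default) or `"fixed"`.
#' @param base a [SynthConfig] providing grid, undulation, dropout, noise
#'   and edge-memory defaults.
#' @param tPrepRange range (h) from which preparation times are drawn.
#' @param submitoFraction fraction of small-mode objects.
#' @param irregularFraction fraction of irregular shapes.
#' @param relDeltaNoise relative sd of the per-record edge-memory magnitude.
#' @param partialFraction fraction of records flagged as partial captures.
#' @return list with `records` (list of [MeasurementRecord]), `truth`
#'   (data.frame of every true parameter per record) and `dropouts`
#'   (combined dropout pixel table with record ids).
#' @examples
#' study <- simulateStudy(n = 4, masterSeed = 7,
#'                        base = synthConfig(nrow = 48, ncol = 48,
#'                                           pitch = 60, dropoutProb = 0))
#' tevPoints(study$records)
#' @export
simulateStudy <- function(n = 30, masterSeed = 1L,
                          preset = c("active", "fixed"),
                          base = synthConfig(),
                          tPrepRange = c(0.5, 17.5),
                          submitoFraction = 0.2,
                          irregularFraction = 0.3,
                          relDeltaNoise = 0.1,
                          partialFraction = 0.1) {
  preset <- match.arg(preset)
  if (n < 1L) stop("n must be >= 1")
  if (length(tPrepRange) != 2L || any(!is.finite(tPrepRange)) ||
      tPrepRange[1] < 0 || diff(tPrepRange) < 0)
    stop("invalid t_prep schedule")
  specimen <- if (preset == "fixed") "fixed_mito" else "active_mito"
  delta0 <- if (preset == "fixed") 0 else base@delta0
  draws <- withSeed(masterSeed, {
    list(seeds = sample.int(2^28, n),
         tPrep = stats::runif(n, tPrepRange[1], tPrepRange[2]),
         small = stats::runif(n) < submitoFraction,
         irr = stats::runif(n) < irregularFraction,
         ell = stats::runif(n) < 0.5,
         rJitter = stats::rnorm(n, 0, 1),
         hJitter = stats::runif(n, 0.8, 1.1),
         dJitter = stats::rnorm(n, 0, relDeltaNoise),
         partial = stats::runif(n) < partialFraction,
         phase = stats::runif(n, 0, 2 * pi))
  })
  records <- vector("list", n)
  truthRows <- vector("list", n)
  dropouts <- list()
  for (i in seq_len(n)) {
    r <- if (draws$small[i]) 290 + 40 * draws$rJitter[i]
         else 1030 + 80 * draws$rJitter[i]
    r <- max(r, 120)
    h <- min(max(r * draws$hJitter[i], 100), 2 * r)
    shape <- if (draws$irr[i]) "irregular"
             else if (draws$ell[i]) "ellipsoidal_cap" else "spherical_cap"
    cfg <- synthConfig(
      nrow = base@nrow, ncol = base@ncol, pitch = base@pitch,
      shape = shape, capRadius = r, capHeight = h,
      ellipticity = base@ellipticity, lobes = base@lobes,
      lobeAmplitude = base@lobeAmplitude,
      undAmplitude = base@undAmplitude, undLength = base@undLength,
      # submitochondrial particles show no edge memory: their TEV is
      # instrumental and time-independent
      delta0 = if (draws$small[i]) 0 else
        max(0, delta0 * (1 + draws$dJitter[i])),
      tZero = base@tZero, anisotropy = base@anisotropy,
      anisotropyPhase = draws$phase[i],
      dropoutProb = base@dropoutProb,
      slopeThreshold = base@slopeThreshold, maxRun = base@maxRun,
      noiseSd = base@noiseSd, tPrep = draws$tPrep[i],
      seed = draws$seeds[i])
    id <- sprintf("%s-%03d", preset, i)
    sim <- simulateRecord(cfg, id = id, specimen = specimen,
                          complete = !draws$partial[i])
    records[[i]] <- sim$record
    if (nrow(sim$truth$dropouts))
      dropouts[[length(dropouts) + 1L]] <-
        cbind(id = id, sim$truth$dropouts)
    truthRows[[i]] <- data.frame(
      id = id, seed = cfg@seed, shape = shape, capRadius = r,
      capHeight = h, tPrep = cfg@tPrep, delta0 = cfg@delta0,
      delta = sim$truth$delta, specimen = specimen,
      complete = !draws$partial[i],
      trueVolume = sim$truth$volume,
      trueSurfaceArea = sim$truth$surfaceArea,
      stringsAsFactors = FALSE)
  }
  names(records) <- vapply(records, function(r) r@id, character(1))
  list(records = records,
       truth = do.call(rbind, truthRows),
       dropouts = if (length(dropouts)) do.call(rbind, dropouts) else
         data.frame(id = character(0), direction = character(0),
                    row = integer(0), col = integer(0)))
}

#' Write a simulated study to disk
#'
#' Writes every scan pair in the chosen height-map dialect, a loader
#' manifest CSV and the ground-truth ledger (JSON) — a self-contained
#' fixture set for the whole pipeline.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @param dialect height-map dialect, see [writeTopography()].
#' @return the manifest path, invisibly.
#' @export
writeStudy <- function(study, dir, dialect = "ascii_matrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(dialect, ascii_matrix = ".txt", float_tiff = ".tif",
                csv = ".csv")
  rows <- lapply(study$records, function(rec) {
    fwd <- paste0(rec@id, "_fwd", ext); bwd <- paste0(rec@id, "_bwd", ext)
    meta <- list(id = rec@id, t_prep_h = rec@tPrep,
                 specimen = rec@specimen, isolation = rec@isolation,
                 complete = rec@complete)
    writeTopography(rec@pair@forward, file.path(dir, fwd), dialect, meta)
    writeTopography(rec@pair@backward, file.path(dir, bwd), dialect, meta)
    data.frame(id = rec@id, forward = fwd, backward = bwd,
               dialect = dialect, t_prep_h = rec@tPrep,
               specimen = rec@specimen, isolation = rec@isolation,
               complete = rec@complete, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mfPath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mfPath, row.names = FALSE)
  truth <- study$truth
  jsonlite::write_json(
    list(truth = truth, dropouts = study$dropouts),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(mfPath)
}
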