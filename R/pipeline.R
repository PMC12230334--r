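#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch–Satterthwaite degrees of freedom, the
#' comparison used for group means throughout the analysis. Exact p-values
#' are reported; no multiple-testing correction is applied and no
#' significance stars are printed.
#'
#' @param a,b numeric samples (each n >= 2 with positive variance).
#' @return list with `statistic`, `df`, `p.value` (two-sided).
#' @examples
#' welchT(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welchT <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 values")
  if (stats::var(a) <= 0 && stats::var(b) <= 0)
    stop("degenerate samples: zero variance")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

.CONFIG_KEYS <- c("input", "preprocess", "segmentation", "classification",
                  "tev", "intermittency", "outDir", "seed")

#' Default study configuration
#'
#' @return a named list with all pipeline settings at their defaults; see
#'   [runPipeline()] for the meaning of each block.
#' @export
defaultStudyConfig <- function() {
  list(
    input = list(simulate = list(preset = "active", n = 12)),
    # row alignment is opt-in: on frames where the object spans most of a
    # scanline the row median sits on the object and the correction
    # corrupts the image
    preprocess = list(steps = c("subtract_mean_plane", "zero_floor")),
    segmentation = list(relThreshold = 0.10, minPixels = 16,
                        connectivity = 8),
    classification = list(tol = 0.15, level = 0.10),
    tev = list(excludePartial = TRUE, excludeSubmito = TRUE,
               cutoffNm = 1000),
    intermittency = list(marginNm = 500, fLow = 0.2, fHigh = 0.5),
    outDir = NULL,
    seed = 1L)
}

#' Read and validate a study configuration file
#'
#' YAML file with the blocks of [defaultStudyConfig()]; unknown top-level
#' keys are rejected, missing blocks take their defaults.
#'
#' @param path YAML config path.
#' @return validated config list.
#' @export
readStudyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  def <- defaultStudyConfig()
  for (k in names(cfg)) {
    def[[k]] <- if (is.list(cfg[[k]]) && is.list(def[[k]]))
      utils::modifyList(def[[k]], cfg[[k]]) else cfg[[k]]
  }
  def
}

#' Run the full analysis pipeline on a study
#'
#' Loads or simulates a set of measurements, preprocesses both scan
#' directions, segments the object of each forward scan, computes the
#' shape report, TEV, dropout summary, the TEV-vs-time trend with zero
#' crossing, group comparisons (Welch) and, when objects were measured
#' repeatedly, the one-sided MCI* decrease test. Any per-record failure is
#' logged with its id and stage and the remaining records are processed.
#'
#' @param config a config list (see [defaultStudyConfig()]) or the path of
#'   a YAML config file.
#' @return (invisibly) a list with `reports` (shape-report data.frame),
#'   `tev` (TEV table), `trend` ([TrendFit] or `NULL`), `comparisons`
#'   (Welch table), `mciTest`, `intermittency` (event table), `failures`
#'   and `log`. When `outDir` is set, the tables are also written as CSV /
#'   JSON files there.
#' @examples
#' bundle <- runPipeline(list(
#'   input = list(simulate = list(preset = "active", n = 5)),
#'   seed = 42))
#' bundle$trend
#' @export
runPipeline <- function(config = defaultStudyConfig()) {
  if (is.character(config)) config <- readStudyConfig(config)
  def <- defaultStudyConfig()
  for (k in names(config)) {
    def[[k]] <- if (is.list(config[[k]]) && is.list(def[[k]]))
      utils::modifyList(def[[k]], config[[k]]) else config[[k]]
  }
  cfg <- def
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  log <- character(0)
  note <- function(...) log[[length(log) + 1L]] <<- sprintf(...)

  # ---- input -------------------------------------------------------------
  if (!is.null(cfg$input$manifest)) {
    note("loading manifest %s", cfg$input$manifest)
    records <- loadMeasurements(cfg$input$manifest)
    loadFailures <- attr(records, "failures")
    records <- Filter(Negate(is.null), records)
  } else {
    sim <- cfg$input$simulate
    if (is.null(sim)) stop("config$input needs 'manifest' or 'simulate'")
    simArgs <- sim
    simArgs$preset <- sim$preset %||% "active"
    simArgs$masterSeed <- sim$masterSeed %||% cfg$seed
    if (!is.null(sim$base) && !is(sim$base, "SynthConfig"))
      simArgs$base <- do.call(synthConfig, sim$base)
    note("simulating %d records (preset %s, seed %d)",
         simArgs$n %||% 30, simArgs$preset, as.integer(simArgs$masterSeed))
    study <- do.call(simulateStudy, simArgs)
    records <- study$records
    loadFailures <- character(0)
  }
  if (!length(records)) stop("no records to process")

  # ---- per-record metrics ------------------------------------------------
  failures <- data.frame(id = character(0), stage = character(0),
                         message = character(0))
  fail <- function(id, stage, e) {
    failures <<- rbind(failures, data.frame(
      id = id, stage = stage, message = conditionMessage(e)))
    note("FAIL %s [%s]: %s", id, stage, conditionMessage(e))
  }
  reports <- list(); tevRows <- list(); events <- list()
  keep <- character(0)
  for (rec in records) {
    id <- rec@id
    pre <- tryCatch({
      fwd <- preprocessTopography(rec@pair@forward, cfg$preprocess$steps)
      bwd <- preprocessTopography(rec@pair@backward, cfg$preprocess$steps)
      ScanPair(fwd, bwd)
    }, error = function(e) { fail(id, "preprocess", e); NULL })
    if (is.null(pre)) next
    mask <- tryCatch(
      segmentObject(pre@forward, cfg$segmentation$relThreshold,
                    cfg$segmentation$minPixels,
                    cfg$segmentation$connectivity),
      error = function(e) { fail(id, "segment", e); NULL })
    if (is.null(mask)) next
    rep <- tryCatch(
      cbind(id = id,
            shapeReport(pre@forward, mask, cfg$classification$level,
                        cfg$classification$tol),
            stringsAsFactors = FALSE),
      error = function(e) { fail(id, "shape_report", e); NULL })
    if (is.null(rep)) next
    tev <- tryCatch(totalEdgeVolume(pre),
                    error = function(e) { fail(id, "tev", e); NULL })
    if (is.null(tev)) next
    im <- tryCatch(
      intermittencySummary(pre, mask, cfg$intermittency$marginNm,
                           cfg$intermittency$fLow, cfg$intermittency$fHigh),
      error = function(e) { fail(id, "intermittency", e); NULL })
    reports[[id]] <- rep
    tevRows[[id]] <- data.frame(
      id = id, t_prep_h = rec@tPrep, tev_nm3 = tev,
      group = splitByEquivalentDiameter(rep$d_sphere_equiv_nm,
                                        cfg$tev$cutoffNm),
      complete = rec@complete, specimen = rec@specimen,
      stringsAsFactors = FALSE)
    if (!is.null(im) && nrow(im$events))
      events[[id]] <- cbind(id = id, im$events, row.names = NULL)
    keep <- c(keep, id)
  }
  if (!length(keep)) stop("all records failed; see failures")
  reports <- do.call(rbind, c(reports, list(make.row.names = FALSE)))
  tevTab <- do.call(rbind, c(tevRows, list(make.row.names = FALSE)))
  eventTab <- if (length(events))
    do.call(rbind, c(events, list(make.row.names = FALSE))) else
    data.frame(id = character(0), direction = character(0),
               row = integer(0), start_col = integer(0),
               end_col = integer(0), min_z_nm = numeric(0),
               flank_z_nm = numeric(0), depth_fraction = numeric(0))

  # ---- study-level statistics -------------------------------------------
  trend <- tryCatch(
    tevTrend(tevTab, cfg$tev$excludePartial, cfg$tev$excludeSubmito),
    error = function(e) { note("trend fit skipped: %s",
                               conditionMessage(e)); NULL })
  comparisons <- .groupComparisons(reports, tevTab, note)
  mciTest <- .repeatedMciTest(reports, tevTab, note)

  bundle <- list(reports = reports, tev = tevTab, trend = trend,
                 comparisons = comparisons, mciTest = mciTest,
                 intermittency = eventTab,
                 failures = failures, loadFailures = loadFailures,
                 log = log)
  if (!is.null(cfg$outDir)) .writeBundle(bundle, cfg$outDir)
  invisible(bundle)
}

.groupComparisons <- function(reports, tevTab, note) {
  out <- list()
  cls <- reports$shape_class
  for (v in c("h_max_nm", "d_slow_nm", "volume_V_nm3")) {
    a <- reports[[v]][cls == "spherical_ellipsoidal"]
    b <- reports[[v]][cls == "irregular"]
    if (length(a) >= 2L && length(b) >= 2L) {
      w <- tryCatch(welchT(a, b), error = function(e) NULL)
      if (!is.null(w))
        out[[length(out) + 1L]] <- data.frame(
          comparison = "spherical_vs_irregular", variable = v,
          mean_a = mean(a), mean_b = mean(b), t = w$statistic,
          df = w$df, p_value = w$p.value)
    }
  }
  act <- tevTab$specimen == "active_mito"
  fix <- tevTab$specimen == "fixed_mito"
  if (sum(act) >= 2L && sum(fix) >= 2L) {
    va <- reports$volume_V_nm3[match(tevTab$id[act], reports$id)]
    vf <- reports$volume_V_nm3[match(tevTab$id[fix], reports$id)]
    w <- tryCatch(welchT(va, vf), error = function(e) NULL)
    if (!is.null(w))
      out[[length(out) + 1L]] <- data.frame(
        comparison = "active_vs_fixed", variable = "volume_V_nm3",
        mean_a = mean(va), mean_b = mean(vf), t = w$statistic,
        df = w$df, p_value = w$p.value)
    wt <- tryCatch(welchT(tevTab$tev_nm3[act], tevTab$tev_nm3[fix]),
                   error = function(e) NULL)
    if (!is.null(wt))
      out[[length(out) + 1L]] <- data.frame(
        comparison = "active_vs_fixed", variable = "tev_nm3",
        mean_a = mean(tevTab$tev_nm3[act]),
        mean_b = mean(tevTab$tev_nm3[fix]), t = wt$statistic,
        df = wt$df, p_value = wt$p.value)
  }
  if (!length(out)) {
    note("group comparisons skipped: insufficient group sizes")
    return(data.frame(comparison = character(0), variable = character(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      t = numeric(0), df = numeric(0),
                      p_value = numeric(0)))
  }
  do.call(rbind, out)
}

# Repeated measurements are recognized by an object tag before the last
# "#" of the id (e.g. "m3#1", "m3#2"); first/last ranked by t_prep.
.repeatedMciTest <- function(reports, tevTab, note) {
  obj <- sub("#[^#]*$", "", reports$id)
  tp <- tevTab$t_prep_h[match(reports$id, tevTab$id)]
  reps <- split(seq_len(nrow(reports)), obj)
  reps <- reps[lengths(reps) >= 2L]
  if (length(reps) < 2L) {
    note("MCI* decrease test skipped: fewer than 2 repeatedly measured objects")
    return(NULL)
  }
  first <- vapply(reps, function(i) reports$mci_star[i[which.min(tp[i])]],
                  numeric(1))
  last <- vapply(reps, function(i) reports$mci_star[i[which.max(tp[i])]],
                 numeric(1))
  mciDecreaseTest(first, last)
}

.writeBundle <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$reports, file.path(outDir, "shape_reports.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$tev, file.path(outDir, "tev.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$intermittency,
                   file.path(outDir, "intermittency_events.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$comparisons,
                   file.path(outDir, "comparisons.csv"), row.names = FALSE)
  if (!is.null(bundle$trend))
    jsonlite::write_json(
      list(slope_nm3_per_h = bundle$trend@slope,
           intercept_nm3 = bundle$trend@intercept,
           t_zero_h = bundle$trend@tZero,
           r_squared = bundle$trend@rSquared,
           n_points = bundle$trend@nPoints),
      file.path(outDir, "trend.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$mciTest))
    jsonlite::write_json(bundle$mciTest,
                         file.path(outDir, "mci_decrease_test.json"),
                         auto_unbox = TRUE, digits = NA)
  if (nrow(bundle$failures))
    utils::write.csv(bundle$failures, file.path(outDir, "failures.csv"),
                     row.names = FALSE)
  writeLines(bundle$log, file.path(outDir, "pipeline.log"))
  invisible(outDir)
}
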