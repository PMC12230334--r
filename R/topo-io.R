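#' Read and write SICM height maps
#'
#' Three plain interchange dialects are supported. All heights are in nm.
#'
#' * `ascii_matrix`: `#`-prefixed `key: value` header lines followed by
#'   whitespace-separated rows (compatible with common SPM text exports).
#'   Heights are printed with 17 significant digits, so a write/read cycle
#'   reproduces the doubles bit-for-bit. Missing pixels are written as `NA`.
#' * `csv`: a bare numeric matrix, one grid row per line; metadata lives in
#'   a JSON sidecar `<name>.json`.
#' * `float_tiff`: one 32-bit float grey image per file. Because float TIFF
#'   samples are stored in \[0, 1\], heights are min-max normalized on write
#'   and the scale (`z_min_nm`, `z_max_nm`) recorded in the JSON sidecar;
#'   missing pixels are recorded as a sidecar index list.
#'
#' Sidecar / header keys: `pitch_x_nm`, `pitch_y_nm`, `direction`, and
#' optionally `t_prep_h`, `specimen`, `isolation`, `complete`, `id`.
#' Explicit arguments override file metadata. Pitch and direction must be
#' available from one of the two sources.
#'
#' @param path file to read or write.
#' @param dialect `"ascii_matrix"`, `"float_tiff"` or `"csv"`.
#' @param pitchX,pitchY pixel pitch in nm (override/supply metadata).
#' @param direction `"forward"` or `"backward"` (override/supply metadata).
#' @return `readTopography()` a [Topography]; `writeTopography()` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeTopography(Topography(matrix(1:4, 2), pitchX = 10), f)
#' readTopography(f)
#' @export
readTopography <- function(path,
                           dialect = c("ascii_matrix", "float_tiff", "csv"),
                           pitchX = NULL, pitchY = NULL, direction = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- list()
  if (dialect == "ascii_matrix") {
    lines <- readLines(path, warn = FALSE)
    hdr <- grepl("^#", lines)
    meta <- .parseHeader(sub("^#\\s*", "", lines[hdr]))
    body <- lines[!hdr & nzchar(trimws(lines))]
    if (!length(body)) stop("parse error: no data rows in ", path)
    rows <- lapply(strsplit(trimws(body), "\\s+"), function(v) {
      x <- suppressWarnings(as.numeric(v))
      if (any(is.na(x) & toupper(v) != "NA"))
        stop("parse error: non-numeric cell in ", path)
      x
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("parse error: ragged rows in ", path)
    h <- do.call(rbind, rows)
  } else {
    sc <- .sidecarPath(path)
    if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (dialect == "csv") {
      h <- tryCatch(
        as.matrix(utils::read.csv(path, header = FALSE,
                                  colClasses = "numeric")),
        warning = function(w) stop("parse error: non-numeric cell in ", path),
        error = function(e) stop("parse error: non-numeric cell in ", path))
      dimnames(h) <- NULL
    } else {
      v <- tiff::readTIFF(path)
      if (is.null(meta$z_min_nm) || is.null(meta$z_max_nm))
        stop("metadata error: float_tiff sidecar must carry z_min_nm/z_max_nm")
      h <- meta$z_min_nm + v * (meta$z_max_nm - meta$z_min_nm)
      if (length(meta$missing_idx)) h[unlist(meta$missing_idx)] <- NA_real_
    }
  }
  px <- pitchX %||% meta$pitch_x_nm
  py <- pitchY %||% meta$pitch_y_nm %||% px
  dr <- direction %||% meta$direction
  if (is.null(px)) stop("metadata error: pixel pitch not in file metadata ",
                        "and not supplied")
  if (is.null(dr)) dr <- "forward"
  Topography(h, pitchX = as.numeric(px), pitchY = as.numeric(py),
             direction = dr)
}

#' @param t a [Topography] to write.
#' @param meta named list of extra metadata stored in the header/sidecar
#'   (e.g. `id`, `t_prep_h`, `specimen`, `isolation`, `complete`).
#' @rdname readTopography
#' @export
writeTopography <- function(t, path,
                            dialect = c("ascii_matrix", "float_tiff", "csv"),
                            meta = list()) {
  dialect <- match.arg(dialect)
  stopifnot(is(t, "Topography"))
  meta <- c(list(pitch_x_nm = t@pitchX, pitch_y_nm = t@pitchY,
                 direction = t@direction), meta)
  h <- t@heights
  if (dialect == "ascii_matrix") {
    hdr <- sprintf("# %s: %s", names(meta),
                   vapply(meta, .fmtMeta, character(1)))
    body <- apply(h, 1L, function(r)
      paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = " "))
    writeLines(c(hdr, body), path)
  } else if (dialect == "csv") {
    utils::write.table(h, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                         digits = NA)
  } else {
    zmin <- min(h, na.rm = TRUE); zmax <- max(h, na.rm = TRUE)
    v <- if (zmax > zmin) (h - zmin) / (zmax - zmin) else h * 0
    miss <- which(is.na(h))
    v[miss] <- 0
    tiff::writeTIFF(v, path, bits.per.sample = 32L)
    meta$z_min_nm <- zmin; meta$z_max_nm <- zmax
    meta$missing_idx <- if (length(miss)) miss else NULL
    jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

.sidecarPath <- function(path) paste0(sub("\\.[^./]*$", "", path), ".json")

.parseHeader <- function(lines) {
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  meta <- list()
  for (m in kv) {
    if (length(m) != 3L) next
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

.fmtMeta <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a measurement manifest and load its scan pairs
#'
#' The manifest is a CSV with one row per measurement and columns `id`,
#' `forward`, `backward` (file paths relative to the manifest), `dialect`,
#' `t_prep_h`, `specimen`, `isolation`, `complete`.
#'
#' @param path manifest CSV path.
#' @return `readManifest()` the manifest data.frame; `loadMeasurements()` a
#'   list of [MeasurementRecord]. Records whose files fail to load are
#'   returned as `NULL` with the error message in the `"failures"`
#'   attribute, so one bad file does not abort a study.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "forward", "backward", "dialect", "t_prep_h",
            "specimen", "isolation", "complete")
  missing <- setdiff(need, names(mf))
  if (length(missing))
    stop("metadata error: manifest lacks columns: ",
         paste(missing, collapse = ", "))
  mf
}

#' @param manifest a manifest data.frame from [readManifest()], or a path.
#' @param dir directory that relative file paths are resolved against.
#' @rdname readManifest
#' @export
loadMeasurements <- function(manifest, dir = ".") {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- readManifest(manifest)
  }
  failures <- character(0)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    tryCatch({
      fwd <- readTopography(file.path(dir, row$forward), row$dialect,
                            direction = "forward")
      bwd <- readTopography(file.path(dir, row$backward), row$dialect,
                            direction = "backward")
      MeasurementRecord(row$id, ScanPair(fwd, bwd), tPrep = row$t_prep_h,
                        specimen = row$specimen, isolation = row$isolation,
                        complete = as.logical(row$complete))
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        sprintf("%s: %s", row$id, conditionMessage(e))
      NULL
    })
  })
  names(recs) <- manifest$id
  attr(recs, "failures") <- failures
  recs
}
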