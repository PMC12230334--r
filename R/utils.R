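# Internal numerical helpers shared across modules.

# Evaluate expr with a locally seeded RNG; the caller's RNG state is
# untouched, so generator determinism never leaks into user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Pixel-center coordinates in nm: pixel k spans [(k-1)*pitch, k*pitch].
pixelCenters <- function(n, pitch) (seq_len(n) - 0.5) * pitch

# Connected-component labeling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, diagonally touching labels are merged with a union-find
# pass over the two diagonal shifts.
.labelComponents <- function(m, connectivity = 8L) {
  stopifnot(is.logical(m))
  lab <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m)))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    parent <- seq_len(nlab)
    findRoot <- function(i) {
      while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
      i
    }
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        a <- findRoot(pairs[k, 1]); b <- findRoot(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(nlab), findRoot, integer(1))
      remap <- match(roots, sort(unique(roots)))
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  lab
}

# Bilinear interpolation of matrix z (rows = y, cols = x) at fractional
# pixel-index coordinates; points outside the grid return `outside`.
interpBilinear <- function(z, ri, ci, outside = 0) {
  nr <- nrow(z); nc <- ncol(z)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  r0 <- pmin(pmax(r0, 1L), nr - 1L)
  c0 <- pmin(pmax(c0, 1L), nc - 1L)
  idx <- function(r, c) z[cbind(r, c)]
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) +
       (1 - fr) * fc       * idx(r0, c0 + 1) +
       fr       * (1 - fc) * idx(r0 + 1, c0) +
       fr       * fc       * idx(r0 + 1, c0 + 1)
  out <- ri < 1 | ri > nr | ci < 1 | ci > nc
  v[out] <- outside
  v
}

# Separable Gaussian smoothing by exact banded-kernel matrix products with
# boundary renormalization; robust for kernels wider than small grids.
gaussSmooth <- function(m, sigmaPx) {
  if (sigmaPx <= 0) return(m)
  kernelMat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * sigmaPx^2))
    k / rowSums(k)
  }
  kernelMat(nrow(m)) %*% m %*% t(kernelMat(ncol(m)))
}

# Maximal runs of TRUE in a logical vector -> matrix of (start, end).
trueRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
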