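# Internal helpers shared across modules. Nothing here is exported.

SEASONS <- c("spring", "summer", "fall", "winter")

LANDUSE_CLASSES <- c("governmental", "commercial", "residential",
                     "industrial", "open_space", "other")

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user code.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stream index,
# kept strictly below 2^31 - 1.
subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Smooth standardized Gaussian random field on an nr x nc grid.
# White noise convolved with a Gaussian kernel of length-scale `range`
# (in cells) on the torus via FFT, then standardized to mean 0, sd 1.
# Opposite-edge wraparound correlation is an accepted property of the
# toy geography.
smoothField <- function(nr, nc, range) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range > 0) {
    dy <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
    dx <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
    k <- exp(-0.5 * outer(dy^2, dx^2, "+") / range^2)
    k <- k / sum(k)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  }
  s <- stats::sd(z)
  if (s == 0) return(z * 0)
  (z - mean(z)) / s
}

# Cell-center coordinate helpers. Cell (row, col) covers
# x in [(col-1)*cs, col*cs), y in [(row-1)*cs, row*cs); row 1 is the top row.
cellCenterX <- function(col, cellSize) (col - 0.5) * cellSize
cellCenterY <- function(row, cellSize) (row - 0.5) * cellSize
colOfX <- function(x, cellSize) floor(x / cellSize) + 1L
rowOfY <- function(y, cellSize) floor(y / cellSize) + 1L

# Integer (dy, dx) cell offsets whose center-to-center distance from the
# origin cell is <= radius. Shared membership rule for site extraction at
# cell centers and for focal convolution kernels.
discOffsets <- function(radius, cellSize) {
  m <- floor(radius / cellSize)
  dy <- rep(-m:m, times = 2L * m + 1L)
  dx <- rep(-m:m, each = 2L * m + 1L)
  keep <- (dy * dy + dx * dx) * cellSize^2 <= radius^2
  list(dy = dy[keep], dx = dx[keep])
}

# Linear indices of cells whose centers lie within the closed disc of
# `radius` around the arbitrary planar point (x, y). Returns integer(0)
# when no cell center falls inside.
discCellIndex <- function(x, y, radius, nr, nc, cellSize) {
  c0 <- colOfX(x, cellSize); r0 <- rowOfY(y, cellSize)
  m <- ceiling(radius / cellSize) + 1L
  rows <- max(1L, r0 - m):min(nr, r0 + m)
  cols <- max(1L, c0 - m):min(nc, c0 + m)
  cy <- cellCenterY(rows, cellSize)
  cx <- cellCenterX(cols, cellSize)
  d2 <- outer((cy - y)^2, (cx - x)^2, "+")
  keep <- d2 <= radius^2
  if (!any(keep)) return(integer(0))
  ri <- rows[row(d2)[keep]]
  ci <- cols[col(d2)[keep]]
  (ci - 1L) * nr + ri
}

# Number of cells of the (unbounded) grid whose centers lie within the
# closed disc around (x, y): the nominal disc cell count, independent of
# the raster window. Used as the denominator of density extractions.
discNominalCount <- function(x, y, radius, cellSize) {
  c0 <- colOfX(x, cellSize); r0 <- rowOfY(y, cellSize)
  m <- ceiling(radius / cellSize) + 1L
  cy <- cellCenterY((r0 - m):(r0 + m), cellSize)
  cx <- cellCenterX((c0 - m):(c0 + m), cellSize)
  sum(outer((cy - y)^2, (cx - x)^2, "+") <= radius^2)
}

# Segments (x1,y1,x2,y2 matrix) from a list of polylines.
polylineSegments <- function(lines) {
  if (length(lines) == 0L) {
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  }
  segs <- lapply(lines, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 2L) return(NULL)
    cbind(x1 = p[-nrow(p), 1], y1 = p[-nrow(p), 2],
          x2 = p[-1, 1], y2 = p[-1, 2])
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) {
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  }
  do.call(rbind, segs)
}

# Minimum Euclidean distance from point (x, y) to a set of segments.
pointSegmentDistance <- function(x, y, segs) {
  dx <- segs[, "x2"] - segs[, "x1"]
  dy <- segs[, "y2"] - segs[, "y1"]
  len2 <- dx * dx + dy * dy
  px <- x - segs[, "x1"]
  py <- y - segs[, "y1"]
  t <- ifelse(len2 > 0, pmin(1, pmax(0, (px * dx + py * dy) / len2)), 0)
  qx <- segs[, "x1"] + t * dx - x
  qy <- segs[, "y1"] + t * dy - y
  min(sqrt(qx * qx + qy * qy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
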