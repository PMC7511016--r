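#' Georeferenced single-band raster grid
#'
#' A minimal planar raster container: a numeric matrix of cell values plus a
#' lower-left origin and a square cell size in metres. Rows run south to
#' north (row 1 is the southernmost band), columns west to east. `NA` marks
#' nodata. All denscape rasters (terrain, covariates, masks, RSF, intensity,
#' risk) use this class; a single projected planar CRS in metres is assumed
#' throughout.
#'
#' Cells are half-open: cell (i, j) covers
#' `[xmin + (j-1)*cs, xmin + j*cs) x [ymin + (i-1)*cs, ymin + i*cs)`,
#' so a point on a shared edge belongs to the cell to its east/north-side
#' lower neighbour exactly once and point-to-cell lookup is invertible.
#'
#' @param values numeric matrix (rows = y bands south to north).
#' @param xmin,ymin coordinates of the lower-left corner (m).
#' @param cellsize cell edge length (m), > 0.
#' @return An object of class `"grid"`.
#' @export
make_grid <- function(values, xmin = 0, ymin = 0, cellsize = 5) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "grid"
  )
}

#' @export
print.grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<grid> %d x %d cells @ %g m, origin (%g, %g)\n  range: [%g, %g], nodata: %d cells\n",
    nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin,
    suppressWarnings(min(v, na.rm = TRUE)), suppressWarnings(max(v, na.rm = TRUE)),
    sum(is.na(v))
  ))
  invisible(x)
}

#' @export
dim.grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "grid")

#' Check that two grids share shape, origin and cell size
#' @param a,b grids.
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b) {
  is_grid(a) && is_grid(b) &&
    identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize), c(b$xmin, b$ymin, b$cellsize)))
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) stop(what, " are not aligned (shape/origin/cell size differ)")
  invisible(TRUE)
}

#' Build a grid like another, with new values
#' @param template a grid supplying geometry.
#' @param values replacement matrix (same shape).
#' @return a grid.
#' @export
grid_like <- function(template, values) {
  stopifnot(identical(dim(values), dim(template$values)))
  make_grid(values, template$xmin, template$ymin, template$cellsize)
}

#' Cell-centre coordinates of every cell
#' @param g a grid.
#' @return list with matrices `x` and `y` of cell-centre coordinates.
#' @export
grid_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values); cs <- g$cellsize
  xs <- g$xmin + (seq_len(nc) - 0.5) * cs
  ys <- g$ymin + (seq_len(nr) - 0.5) * cs
  list(
    x = matrix(xs, nr, nc, byrow = TRUE),
    y = matrix(ys, nr, nc)
  )
}

#' Map point coordinates to cell row/column indices
#'
#' Half-open cell convention: the west and south edges of a cell belong to
#' it. Points outside the extent get `NA` indices.
#'
#' @param g a grid.
#' @param x,y point coordinates (m).
#' @return data.frame with integer columns `row`, `col`.
#' @export
xy_to_cell <- function(g, x, y) {
  cs <- g$cellsize
  col <- floor((x - g$xmin) / cs) + 1L
  row <- floor((y - g$ymin) / cs) + 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values) |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Grid values at point locations (nearest-cell lookup)
#' @param g a grid.
#' @param x,y point coordinates.
#' @return numeric vector of cell values (`NA` outside the extent / nodata).
#' @export
grid_lookup <- function(g, x, y) {
  rc <- xy_to_cell(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Area represented by non-zero, non-NA cells
#' @param mask a grid of 0/1 (or logical) values.
#' @return area in km^2.
#' @export
mask_area_km2 <- function(mask) {
  sum(mask$values > 0, na.rm = TRUE) * mask$cellsize^2 / 1e6
}

# --- moving-window machinery ------------------------------------------------

# Sum of matrix values over a circular window of `r` cells (centre included),
# together with the count of in-grid cells per window. Edge windows use the
# available cells only. Implemented as, for each row offset dy, a row shift
# followed by a horizontal running sum of half-width floor(sqrt(r^2-dy^2))
# via cumulative sums, which is exact (no FFT roundoff).
disc_window_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr, nc)
  Cn <- matrix(0, nr, nc)
  for (dy in -r:r) {
    wx <- floor(sqrt(r^2 - dy^2))
    # rows of m shifted by dy (row i of `sh` holds m[i + dy, ])
    src <- seq_len(nr) + dy
    ok <- src >= 1L & src <= nr
    sh <- matrix(0, nr, nc)
    ones <- matrix(0, nr, nc)
    sh[ok, ] <- m[src[ok], ]
    ones[ok, ] <- 1
    # horizontal running sum of half-width wx via padded row cumsums
    cs <- t(apply(cbind(0, sh), 1, cumsum))
    co <- t(apply(cbind(0, ones), 1, cumsum))
    hi <- pmin(seq_len(nc) + wx, nc) + 1L
    lo <- pmax(seq_len(nc) - wx, 1L)
    S <- S + cs[, hi, drop = FALSE] - cs[, lo, drop = FALSE]
    Cn <- Cn + co[, hi, drop = FALSE] - co[, lo, drop = FALSE]
  }
  list(sum = S, count = Cn)
}

# 3x3 (or (2k+1)^2) square-window sum with edge truncation; k in cells.
square_window_sum <- function(m, k = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr, nc)
  Cn <- matrix(0, nr, nc)
  for (dy in -k:k) for (dx in -k:k) {
    ri <- seq_len(nr) + dy
    ci <- seq_len(nc) + dx
    rok <- ri >= 1L & ri <= nr
    cok <- ci >= 1L & ci <= nc
    S[rok, cok] <- S[rok, cok] + m[ri[rok], ci[cok]]
    Cn[rok, cok] <- Cn[rok, cok] + 1
  }
  list(sum = S, count = Cn)
}
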