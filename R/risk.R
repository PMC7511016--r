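# --- simple planar polygon helpers -----------------------------------------

# normalize polygon input to a list of closed rings (matrices with x, y cols)
as_rings <- function(permits) {
  if (is.matrix(permits) || is.data.frame(permits)) permits <- list(permits)
  lapply(permits, function(p) {
    p <- as.matrix(p)[, 1:2, drop = FALSE]
    # repair: drop duplicate consecutive vertices, close the ring
    keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
    p <- p[keep, , drop = FALSE]
    if (nrow(p) < 3) stop("invalid polygon: fewer than 3 distinct vertices")
    if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
    if (abs(polygon_area(p)) < .Machine$double.eps)
      stop("invalid polygon: zero area after repair")
    p
  })
}

#' Planar polygon area (shoelace formula)
#' @param ring two-column matrix of vertices (closed or open ring).
#' @return signed area (m^2); positive for counter-clockwise rings.
#' @export
polygon_area <- function(ring) {
  ring <- as.matrix(ring)[, 1:2, drop = FALSE]
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# TRUE for points inside any of the rings
points_in_polygons <- function(x, y, rings) {
  inside <- rep(FALSE, length(x))
  pts <- cbind(x, y)
  for (r in rings) inside <- inside | mgcv::in.out(r, pts)
  inside
}

# minimum distance from points to the edges of a set of rings
dist_to_ring_edges <- function(x, y, rings) {
  d <- rep(Inf, length(x))
  for (r in rings) d <- pmin(d, dist_to_polyline(x, y, r))
  d
}

# --- kernel density with LSCV bandwidth -------------------------------------

# least-squares cross-validation score for a product Gaussian kernel with
# per-axis bandwidths (hx, hy), from pairwise coordinate differences
lscv_score <- function(dx, dy, n, hx, hy) {
  # integral of fhat^2: pairwise convolution kernel with bandwidth h*sqrt(2)
  s2 <- sqrt(2)
  int_f2 <- sum(stats::dnorm(dx / (hx * s2)) / (hx * s2) *
                stats::dnorm(dy / (hy * s2)) / (hy * s2)) / n^2
  # sum over i of leave-one-out density at x_i: off-diagonal pair terms
  offdiag <- sum(stats::dnorm(dx / hx) * stats::dnorm(dy / hy)) -
    n * stats::dnorm(0)^2
  loo <- offdiag / ((n - 1) * hx * hy)
  int_f2 - 2 * loo / n
}

#' Helicopter-activity kernel density with LSCV bandwidth
#'
#' Bivariate Gaussian product-kernel density of flight-track fixes evaluated
#' on the template grid. A single bandwidth multiplier on the per-axis
#' standard deviations is chosen to minimize the least-squares
#' cross-validation score `LSCV(h) = int(fhat^2) - (2/n) sum_i fhat_{-i}(x_i)`
#' (coarse log-spaced search refined by golden-section). Bandwidths are
#' floored at one cell size (duplicate-heavy data can drive LSCV towards
#' h = 0); a warning reports the floor.
#'
#' @param fixes data.frame with `x`, `y` (>= 10 rows).
#' @param grid_template grid supplying the evaluation geometry.
#' @param h_range search range for the bandwidth multiplier, expressed
#'   relative to the Scott reference `sd * n^(-1/6)` per axis; default
#'   `c(0.05, 4)`.
#' @param max_pairs_n fixes are subsampled to this many points for the
#'   pairwise LSCV score (the density itself uses all fixes).
#' @param seed seed for the subsample when `nrow(fixes) > max_pairs_n`.
#' @return object of class `"intensity_surface"`: `kde` (density grid,
#'   integrating to ~1 over a covering extent), `bandwidth` c(hx, hy) in m,
#'   `quantile_classes` (a 5-class [equal_area_classify()] result).
#' @export
kde_lscv <- function(fixes, grid_template, h_range = c(0.05, 4),
                     max_pairs_n = 2000L, seed = 1L) {
  n_all <- nrow(fixes)
  if (n_all < 10) stop("need at least 10 fixes")
  x <- fixes$x; y <- fixes$y
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("degenerate fixes: zero coordinate variance")
  sub <- if (n_all > max_pairs_n) {
    with_seed(seed, sample.int(n_all, max_pairs_n))
  } else seq_len(n_all)
  xs <- x[sub]; ys <- y[sub]
  n <- length(sub)
  dx <- outer(xs, xs, `-`); dy <- outer(ys, ys, `-`)
  scott <- n_all^(-1 / 6)
  obj <- function(m) lscv_score(dx, dy, n, m * scott * sx, m * scott * sy)
  grid_m <- exp(seq(log(h_range[1]), log(h_range[2]), length.out = 25))
  sc <- vapply(grid_m, obj, numeric(1))
  i0 <- which.min(sc)
  lo <- grid_m[max(1, i0 - 1)]; hi <- grid_m[min(length(grid_m), i0 + 1)]
  opt <- stats::optimize(obj, interval = c(lo, hi))
  m <- opt$minimum
  hx <- m * scott * sx; hy <- m * scott * sy
  cs <- grid_template$cellsize
  if (hx < cs || hy < cs) {
    warning("LSCV bandwidth below one cell size; flooring at ", cs, " m")
    hx <- max(hx, cs); hy <- max(hy, cs)
  }
  nr <- nrow(grid_template$values); nc <- ncol(grid_template$values)
  gx <- grid_template$xmin + (seq_len(nc) - 0.5) * cs
  gy <- grid_template$ymin + (seq_len(nr) - 0.5) * cs
  # MASS::kde2d divides h by 4 internally; pass 4*h so the kernel sd is h
  kd <- MASS::kde2d(x, y, h = 4 * c(hx, hy), n = c(nc, nr),
                    lims = c(range(gx), range(gy)))
  dens <- t(kd$z)  # -> rows = y (south to north), cols = x
  kde_grid <- grid_like(grid_template, dens)
  structure(list(
    kde = kde_grid,
    bandwidth = c(hx = hx, hy = hy),
    lscv_multiplier = m,
    quantile_classes = equal_area_classify(kde_grid, 5)
  ), class = "intensity_surface")
}

#' @export
print.intensity_surface <- function(x, ...) {
  cat(sprintf("<intensity_surface> bandwidth (%.1f, %.1f) m; mass %.4f\n",
              x$bandwidth[1], x$bandwidth[2],
              sum(x$kde$values, na.rm = TRUE) * x$kde$cellsize^2))
  invisible(x)
}

#' Classify a surface into five quantile intensity bins
#'
#' Same equal-pixel-count machinery as the habitat classification, applied
#' to a (kernel-density) intensity surface.
#'
#' @param intensity grid (or `intensity_surface`).
#' @param n number of classes (default 5).
#' @return a `classified_surface`.
#' @export
quantile_classify <- function(intensity, n = 5) {
  g <- if (inherits(intensity, "intensity_surface")) intensity$kde else intensity
  equal_area_classify(g, n)
}

#' Disturbance-risk surface: intensity times selection
#'
#' Cellwise product of the raw helicopter-intensity surface and the raw RSF
#' surface, classified into five quantile bins. The top class marks where
#' prime denning habitat coincides with intense helicopter use. Class-grid
#' multiplication (`use_classes = TRUE`) is offered as a categorical
#' alternative; the default multiplies the raw surfaces.
#'
#' @param intensity `intensity_surface` or grid.
#' @param rsf RSF score grid.
#' @param use_classes multiply the 1-5 class grids instead of raw surfaces.
#' @return object of class `"risk_surface"`: `risk` grid and `classes`
#'   (a 5-class `classified_surface`).
#' @export
risk_product <- function(intensity, rsf, use_classes = FALSE) {
  ig <- if (inherits(intensity, "intensity_surface")) intensity$kde else intensity
  stop_if_misaligned(ig, rsf)
  if (use_classes) {
    a <- equal_area_classify(ig, 5)$classes$values
    b <- equal_area_classify(rsf, 5)$classes$values
    risk <- grid_like(rsf, a * b)
  } else {
    risk <- grid_like(rsf, ig$values * rsf$values)
  }
  structure(list(
    risk = risk,
    classes = equal_area_classify(risk, 5)
  ), class = "risk_surface")
}

#' Overlap of prime denning habitat, permit areas, dens and risk classes
#'
#' Summarizes: km^2 of prime habitat inside and outside the permitted
#' heli-ski polygons (with whole-percent overlap), den counts inside/outside
#' the permits, the share of in-bounds dens that sit in prime habitat, den
#' counts per risk class (with the share in the two highest classes), and
#' the distance from each in-bounds den to the nearest permit boundary.
#' All percentages are computed from raw counts, then rounded.
#'
#' @param prime 0/1 prime-habitat grid (see [prime_habitat_mask()]).
#' @param permits polygon, or list of polygons (two-column vertex matrices).
#' @param dens data.frame with `x`, `y`.
#' @param risk_classes optional `classified_surface` (or integer class grid)
#'   of disturbance risk.
#' @return list of overlap statistics.
#' @export
overlap_summary <- function(prime, permits, dens, risk_classes = NULL) {
  rings <- as_rings(permits)
  ctr <- grid_centers(prime)
  in_permit <- matrix(
    points_in_polygons(as.vector(ctr$x), as.vector(ctr$y), rings),
    nrow(prime$values), ncol(prime$values))
  pr <- prime$values > 0 & !is.na(prime$values)
  cell_km2 <- prime$cellsize^2 / 1e6
  prime_km2 <- sum(pr) * cell_km2
  overlap_km2 <- sum(pr & in_permit) * cell_km2
  den_in <- points_in_polygons(dens$x, dens$y, rings)
  n_dens <- nrow(dens)
  den_prime <- grid_lookup(prime, dens$x, dens$y) > 0
  out <- list(
    prime_km2 = prime_km2,
    overlap_km2 = overlap_km2,
    overlap_pct = round(100 * overlap_km2 / prime_km2),
    n_dens = n_dens,
    dens_inside = sum(den_in),
    dens_outside = sum(!den_in),
    dens_inside_pct = round(100 * sum(den_in) / n_dens),
    dens_outside_pct = round(100 * sum(!den_in) / n_dens),
    inside_dens_in_prime_pct = if (any(den_in))
      round(100 * sum(den_prime[den_in], na.rm = TRUE) / sum(den_in))
    else NA_real_,
    boundary_dist_m = dist_to_ring_edges(dens$x[den_in], dens$y[den_in], rings)
  )
  if (!is.null(risk_classes)) {
    cg <- if (inherits(risk_classes, "classified_surface"))
      risk_classes$classes else risk_classes
    rc <- grid_lookup(cg, dens$x, dens$y)
    counts <- tabulate(rc[!is.na(rc)], nbins = 5)
    out$dens_by_risk_class <- counts
    out$dens_top2_risk <- sum(counts[4:5])
    out$dens_top2_risk_pct <- round(100 * sum(counts[4:5]) / n_dens)
  }
  out
}
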