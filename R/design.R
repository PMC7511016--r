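# minimum distance from points to a polyline, vectorized over points
dist_to_polyline <- function(x, y, line) {
  n <- nrow(line)
  d2 <- rep(Inf, length(x))
  for (k in seq_len(n - 1)) {
    x1 <- line[k, 1]; y1 <- line[k, 2]
    x2 <- line[k + 1, 1]; y2 <- line[k + 1, 2]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(pmax(((x - x1) * vx + (y - y1) * vy) / L2, 0), 1) else 0
    dx <- x - (x1 + t * vx); dy <- y - (y1 + t * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

#' Build the study-area mask
#'
#' A cell is in the study area when it lies within `buffer_m` of the survey
#' route, at or above the minimum elevation, is not forest (VHI at most the
#' forest threshold) and is not glacier. Mirrors the open-terrain survey
#' frame of an aerial den survey: a 1,500-m route buffer excluding forest,
#' terrain below 300 m, and glaciers.
#'
#' @param dtm terrain grid.
#' @param vhi_grid vegetation-height grid from [vhi()].
#' @param glacier_mask 0/1 glacier grid.
#' @param route two-column matrix of route vertices (m).
#' @param buffer_m route buffer distance (m), measured from cell centres.
#' @param min_elev minimum elevation retained (m).
#' @param forest_vhi VHI above which a cell is forest and excluded (m).
#' @return 0/1 grid; attribute `area_km2` holds the masked-in area.
#' @export
build_study_mask <- function(dtm, vhi_grid, glacier_mask, route,
                             buffer_m = 1500, min_elev = 300, forest_vhi = 5) {
  stop_if_misaligned(dtm, vhi_grid)
  stop_if_misaligned(dtm, glacier_mask)
  ctr <- grid_centers(dtm)
  d <- dist_to_polyline(as.vector(ctr$x), as.vector(ctr$y), route)
  # cell-intersection semantics: expand by half a cell diagonal so cells the
  # route crosses are kept even when their centre sits just off the line
  slop <- dtm$cellsize * sqrt(2) / 2
  inbuf <- matrix(d <= buffer_m + slop, nrow(dtm$values), ncol(dtm$values))
  m <- inbuf & dtm$values >= min_elev & vhi_grid$values <= forest_vhi &
    !(glacier_mask$values > 0)
  m[is.na(m)] <- FALSE
  if (!any(m)) stop("study-area mask is empty")
  out <- grid_like(dtm, m * 1)
  attr(out, "area_km2") <- mask_area_km2(out)
  out
}

#' Draw random available locations over the study area
#'
#' Points are uniform over the continuous unmasked area (a uniformly chosen
#' unmasked cell plus a uniform within-cell offset), at a mean density of
#' `density_per_km2` locations per km^2 — the availability sample of a
#' second-order, Design II used-available study.
#'
#' @param mask study-area 0/1 grid.
#' @param density_per_km2 mean point density (default 500).
#' @param seed integer seed.
#' @param n optional explicit point count overriding the density.
#' @return data.frame with `x`, `y`, `label = "available"`.
#' @export
draw_available <- function(mask, density_per_km2 = 500, seed, n = NULL) {
  cells <- which(mask$values > 0)
  if (length(cells) == 0) stop("mask is empty")
  area <- mask_area_km2(mask)
  if (is.null(n)) n <- round(density_per_km2 * area)
  if (n < 1) stop("requested zero available points; increase density or area")
  nr <- nrow(mask$values)
  cs <- mask$cellsize
  with_seed(seed, {
    pick <- sample(cells, n, replace = TRUE)
    row <- (pick - 1L) %% nr + 1L
    col <- (pick - 1L) %/% nr + 1L
    data.frame(
      x = mask$xmin + (col - 1L) * cs + stats::runif(n) * cs,
      y = mask$ymin + (row - 1L) * cs + stats::runif(n) * cs,
      label = "available"
    )
  })
}

#' Extract covariate values at point locations
#'
#' Nearest-cell (containing-cell) lookup of every model covariate in the
#' stack; rows that hit nodata in any covariate are dropped with a message.
#' Extraction is deterministic and preserves row order.
#'
#' @param points data.frame with `x`, `y` (and optionally `label`).
#' @param stack a [build_covariates()] stack (standardized or not).
#' @param strict if `TRUE`, error when more than 10% of rows are dropped
#'   (otherwise just a message).
#' @return `points` with one column per covariate, nodata rows removed.
#' @export
extract_covariates <- function(points, stack, strict = FALSE) {
  stopifnot(inherits(stack, "covariate_stack"))
  covs <- intersect(COVARIATE_NAMES, names(stack$grids))
  out <- points
  for (cv in covs) out[[cv]] <- grid_lookup(stack$grids[[cv]], points$x, points$y)
  keep <- stats::complete.cases(out[covs])
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " of ", nrow(out), " points dropped (nodata covariates)")
    if (strict && dropped > 0.1 * nrow(out))
      stop("more than 10% of rows dropped in strict mode")
  }
  out[keep, , drop = FALSE]
}

#' Assemble the used-available design table
#'
#' Binds den (used) and available points and extracts standardized
#' covariates for both. The stack must already be standardized so used and
#' available rows share one scale.
#'
#' @param dens,available data.frames with `x`, `y` (labels are reset to
#'   `"used"` / `"available"`).
#' @param stack standardized covariate stack.
#' @param strict passed to [extract_covariates()].
#' @return design data.frame with `x`, `y`, `label`, covariate columns.
#' @export
make_design <- function(dens, available, stack, strict = FALSE) {
  if (!isTRUE(stack$standardized))
    stop("stack must be standardized before building the design table")
  dens$label <- "used"
  available$label <- "available"
  pts <- rbind(dens[c("x", "y", "label")], available[c("x", "y", "label")])
  extract_covariates(pts, stack, strict = strict)
}

#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlations and per-covariate variance inflation
#' factors (`VIF = 1 / (1 - R^2)` from regressing each covariate on the
#' others). Violations of the thresholds are reported, not auto-dropped:
#' the candidate model set is fixed a priori, so removal is an analyst
#' decision.
#'
#' @param data design table (or any data.frame of covariate columns).
#' @param covariates covariate column names (default: the model covariates
#'   present).
#' @param r_max pairwise |r| threshold (default 0.7).
#' @param vif_max VIF threshold (default 2).
#' @return list with `r` (correlation matrix), `vif` (named vector),
#'   `flagged_pairs` (data.frame), `flagged_vif` (named vector), `ok` flag.
#' @export
collinearity_screen <- function(data, covariates = NULL, r_max = 0.7, vif_max = 2) {
  if (is.null(covariates))
    covariates <- intersect(COVARIATE_NAMES, names(data))
  if (length(covariates) < 2) stop("need at least two covariates to screen")
  X <- as.data.frame(data[covariates])
  r <- stats::cor(X)
  pr <- which(abs(r) >= r_max & upper.tri(r), arr.ind = TRUE)
  flagged_pairs <- data.frame(
    a = rownames(r)[pr[, 1]], b = colnames(r)[pr[, 2]],
    r = r[pr]
  )
  vif <- vapply(covariates, function(cv) {
    fml <- stats::reformulate(setdiff(covariates, cv), response = cv)
    r2 <- suppressWarnings(summary(stats::lm(fml, data = X))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  list(
    r = r,
    vif = vif,
    flagged_pairs = flagged_pairs,
    flagged_vif = vif[vif >= vif_max],
    ok = nrow(flagged_pairs) == 0 && all(vif < vif_max)
  )
}
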