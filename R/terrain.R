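#' Slope and aspect from a terrain model (Horn's method)
#'
#' Third-order finite differences over the 3x3 neighbourhood (Horn 1981),
#' the convention used by mainstream GIS slope tools. Slope is returned in
#' degrees; aspect is the downslope bearing in degrees clockwise from north.
#' Edge cells and flat cells (zero gradient) get `NA` aspect; edge cells get
#' `NA` slope.
#'
#' @param dtm terrain grid (>= 3x3 cells).
#' @return list with grids `slope` (degrees, `[0, 90)`) and `aspect`
#'   (degrees from north).
#' @export
slope_aspect <- function(dtm) {
  z <- dtm$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("dtm must have at least 3 x 3 cells")
  cs <- dtm$cellsize
  # shifted copies; sh(dy, dx) holds z[i + dy, j + dx]
  sh <- function(dy, dx) {
    out <- matrix(NA_real_, nr, nc)
    ri <- seq_len(nr) + dy; ci <- seq_len(nc) + dx
    rok <- ri >= 1L & ri <= nr; cok <- ci >= 1L & ci <= nc
    out[rok, cok] <- z[ri[rok], ci[cok]]
    out
  }
  # rows run south->north: dy = +1 is the northern neighbour
  zN <- sh(1, 0); zS <- sh(-1, 0); zE <- sh(0, 1); zW <- sh(0, -1)
  zNE <- sh(1, 1); zNW <- sh(1, -1); zSE <- sh(-1, 1); zSW <- sh(-1, -1)
  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cs)
  gy <- ((zNE + 2 * zN + zNW) - (zSE + 2 * zS + zSW)) / (8 * cs)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  # downslope bearing: direction of -grad, clockwise from north
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[is.finite(gx) & is.finite(gy) & gx == 0 & gy == 0] <- NA_real_
  list(slope = grid_like(dtm, slope), aspect = grid_like(dtm, aspect))
}

#' Topographic position index
#'
#' Difference between each cell's elevation and the mean elevation of the
#' surrounding cells within a circular window (centre cell excluded).
#' Positive values indicate convex terrain (ridges, knobs), negative values
#' concave terrain (gullies, valley bottoms). Windows truncated by the grid
#' edge use the available neighbours.
#'
#' @param dtm terrain grid.
#' @param radius_m window radius in metres (default 140, i.e. 28 cells at
#'   5-m resolution).
#' @return TPI grid (m).
#' @export
tpi <- function(dtm, radius_m = 140) {
  cs <- dtm$cellsize
  if (radius_m < cs) stop("radius must be at least one cell size")
  r <- floor(radius_m / cs)
  ws <- disc_window_sum(dtm$values, r)
  nbr_mean <- (ws$sum - dtm$values) / (ws$count - 1)
  grid_like(dtm, dtm$values - nbr_mean)
}

#' Vector ruggedness measure
#'
#' Sappington's VRM: unit surface-normal vectors
#' `n = (sin s sin a, sin s cos a, cos s)` are summed over a square window
#' and the ruggedness is one minus the normalized resultant length,
#' `VRM = 1 - |sum(n)| / N`. 0 on smooth terrain (parallel normals),
#' approaching 1 in maximally irregular terrain. Flat cells (undefined
#' aspect) contribute a vertical normal; cells with `NA` slope (grid edge)
#' are excluded from the window count.
#'
#' @param slope,aspect aligned grids from [slope_aspect()] (degrees).
#' @param window_m square window edge length in metres (default 15 = 3x3
#'   cells at 5-m resolution).
#' @return VRM grid in `[0, 1]`.
#' @export
vrm <- function(slope, aspect, window_m = 15) {
  stop_if_misaligned(slope, aspect)
  cs <- slope$cellsize
  k <- floor(window_m / (2 * cs))
  if (window_m < cs) stop("window smaller than one cell")
  k <- max(k, 1L)
  s <- slope$values * pi / 180
  a <- aspect$values * pi / 180
  flat <- is.finite(s) & !is.finite(a)
  a[flat] <- 0  # sin(s)=0 there anyway once slope is 0; guard NA arithmetic
  valid <- is.finite(s)
  nx <- ifelse(valid, sin(s) * sin(a), 0)
  ny <- ifelse(valid, sin(s) * cos(a), 0)
  nz <- ifelse(valid, cos(s), 0)
  Sx <- square_window_sum(nx, k)$sum
  Sy <- square_window_sum(ny, k)$sum
  Sz <- square_window_sum(nz, k)
  Nn <- square_window_sum(valid * 1, k)$sum
  R <- sqrt(Sx^2 + Sy^2 + Sz$sum^2)
  v <- 1 - R / Nn
  v[Nn == 0] <- NA_real_
  v[!valid] <- NA_real_
  v <- pmin(pmax(v, 0), 1)
  grid_like(slope, v)
}

# Planchon-Darboux style pit filling: water level W starts at the DEM on the
# border and +Inf inside, then is iteratively lowered to
# max(z, min(neighbour W) + eps) until stable.
fill_pits <- function(z, eps = 1e-4, max_iter = 5000L) {
  nr <- nrow(z); nc <- ncol(z)
  W <- matrix(Inf, nr, nc)
  W[c(1, nr), ] <- z[c(1, nr), ]
  W[, c(1, nc)] <- z[, c(1, nc)]
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (iter in seq_len(max_iter)) {
    nbmin <- matrix(Inf, nr, nc)
    for (o in seq_len(nrow(offs))) {
      dy <- offs$dy[o]; dx <- offs$dx[o]
      ri <- seq_len(nr) + dy; ci <- seq_len(nc) + dx
      rok <- ri >= 1L & ri <= nr; cok <- ci >= 1L & ci <= nc
      cur <- nbmin[rok, cok]
      nbmin[rok, cok] <- pmin(cur, W[ri[rok], ci[cok]] + eps)
    }
    Wnew <- pmax(z, pmin(W, nbmin))
    Wnew[c(1, nr), ] <- z[c(1, nr), ]
    Wnew[, c(1, nc)] <- z[, c(1, nc)]
    if (all(Wnew == W)) break
    W <- Wnew
  }
  W
}

# Freeman multiple-flow-direction (MD8) accumulation on a pit-filled DEM.
# Each cell passes its accumulated area to all lower neighbours with weights
# proportional to (drop/distance)^p, p = 1.1. Returns the accumulated cell
# count (>= 1, the cell itself).
flow_accumulation_md8 <- function(zf, cellsize, p = 1.1, d8 = FALSE) {
  nr <- nrow(zf); nc <- ncol(zf)
  n <- nr * nc
  offs <- cbind(
    dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
    dx = c(-1, 0, 1, -1, 1, -1, 0, 1)
  )
  dist <- sqrt(offs[, 1]^2 + offs[, 2]^2) * cellsize
  idx <- seq_len(n)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  # neighbour linear indices (NA off-grid) and drop-based weights, vectorized
  nb <- matrix(NA_integer_, n, 8)
  wt <- matrix(0, n, 8)
  for (o in 1:8) {
    ri <- row + offs[o, 1]; ci <- col + offs[o, 2]
    ok <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
    nbi <- ifelse(ok, (ci - 1L) * nr + ri, NA_integer_)
    nb[, o] <- nbi
    drop <- rep(NA_real_, n)
    drop[ok] <- zf[idx[ok]] - zf[nbi[ok]]
    w <- pmax(drop, 0) / dist[o]
    w[!ok | is.na(w)] <- 0
    wt[, o] <- w
  }
  if (d8) {
    # all flow to the single steepest-descent neighbour
    best <- max.col(wt, ties.method = "first")
    sel <- matrix(0, n, 8)
    sel[cbind(seq_len(n), best)] <- 1
    wt <- sel * (wt > 0)
  } else {
    wt <- wt^p
  }
  wsum <- rowSums(wt)
  acc <- rep(1, n)
  for (i in order(zf, decreasing = TRUE)) {
    if (wsum[i] <= 0) next
    share <- acc[i] * wt[i, ] / wsum[i]
    tgt <- nb[i, ]
    pos <- which(share > 0)
    if (length(pos)) acc[tgt[pos]] <- acc[tgt[pos]] + share[pos]
  }
  matrix(acc, nr, nc)
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan(beta))` where `a` is the specific catchment area
#' (MD8 multiple-flow-direction accumulation times cell area, divided by the
#' cell-size contour width) computed on a pit-filled copy of the terrain,
#' and `beta` is the local slope, floored at `tan(0.1 deg)` so flat cells do
#' not blow up. High values mark wet, poorly drained positions.
#'
#' @param dtm terrain grid.
#' @param routing `"md8"` (Freeman multiple flow direction, default) or
#'   `"d8"` (single steepest-descent direction).
#' @return TWI grid.
#' @export
twi <- function(dtm, routing = c("md8", "d8")) {
  routing <- match.arg(routing)
  cs <- dtm$cellsize
  zf <- fill_pits(dtm$values)
  acc <- flow_accumulation_md8(zf, cs, d8 = routing == "d8")
  sca <- acc * cs^2 / cs  # specific catchment area, m
  sl <- slope_aspect(make_grid(zf, dtm$xmin, dtm$ymin, cs))$slope$values
  tanb <- pmax(tan(sl * pi / 180), tan(0.1 * pi / 180))
  # edge cells have NA Horn slope; fall back to the floor so TWI stays defined
  tanb[is.na(tanb)] <- tan(0.1 * pi / 180)
  grid_like(dtm, log(sca / tanb))
}

#' Daily clear-sky solar radiation on sloped terrain
#'
#' Direct-beam plus isotropic diffuse irradiance integrated over the
#' daylight period in fixed time steps. Solar position follows the standard
#' declination/hour-angle formulas; the beam incidence on each cell is
#' `cos(theta) = cos(s) cos(Z) + sin(s) sin(Z) cos(A_sun - aspect)` and is
#' zeroed where the sun is below the local terrain plane (self-shading only,
#' no cast shadows). Atmospheric attenuation uses a fixed clear-sky beam
#' transmittance per unit air mass.
#'
#' @param dtm terrain grid (geometry template; values unused).
#' @param slope,aspect grids from [slope_aspect()] (degrees).
#' @param latitude_deg site latitude (degrees, `|lat| < 66.5`).
#' @param day_of_year day of year (default 91 = 1 April, the pre-emergence
#'   reference date for denning conditions).
#' @param transmittance clear-sky beam transmittance (default 0.7).
#' @param diffuse_fraction diffuse proportionality coefficient (default 0.3).
#' @param step_min integration time step, minutes (<= 15 recommended).
#' @return grid of daily insolation (Wh m^-2 day^-1).
#' @export
solar_radiation <- function(dtm, slope, aspect, latitude_deg = 59.3,
                            day_of_year = 91, transmittance = 0.7,
                            diffuse_fraction = 0.3, step_min = 15) {
  if (abs(latitude_deg) >= 66.5)
    stop("polar latitudes are not supported (day-length formula breaks)")
  stop_if_misaligned(slope, aspect)
  s <- slope$values * pi / 180
  a <- aspect$values * pi / 180
  a[is.na(a) & is.finite(s)] <- 0  # flat cells: aspect irrelevant (sin s = 0)
  phi <- latitude_deg * pi / 180
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  S0 <- 1361
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))  # sunset hour angle
  n_steps <- max(1L, ceiling(2 * ws * 12 / pi * 60 / step_min))
  dt_h <- (2 * ws * 12 / pi) / n_steps  # hours per step
  total <- matrix(0, nrow(s), ncol(s))
  for (k in seq_len(n_steps)) {
    w <- -ws + (k - 0.5) * (2 * ws / n_steps)  # midpoint hour angle
    cosZ <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(w)
    if (cosZ <= 0) next
    sinZ <- sqrt(1 - cosZ^2)
    # solar azimuth from north, clockwise; morning east, afternoon west
    cosA <- (sin(decl) - cosZ * sin(phi)) / (sinZ * cos(phi))
    A <- acos(pmin(pmax(cosA, -1), 1))
    if (w > 0) A <- 2 * pi - A
    m <- 1 / cosZ  # plane-parallel air mass
    Ib <- S0 * transmittance^m
    cost <- cos(s) * cosZ + sin(s) * sinZ * cos(A - a)
    direct <- Ib * pmax(cost, 0)
    diffuse <- diffuse_fraction * S0 * (1 - transmittance^m) * cosZ *
      (1 + cos(s)) / 2
    total <- total + (direct + diffuse) * dt_h
  }
  total[!is.finite(s)] <- NA_real_
  grid_like(slope, total)
}

#' Snow-load index
#'
#' Product of (i) elevation scaled 0-1 across the full available range and
#' (ii) a leeward-exposure term `(1 + cos(aspect - leeward)) / 2` that is
#' maximal on the aspect opposite the prevailing storm wind (135 deg wind ->
#' 315 deg leeward) and zero on the windward aspect. Flat cells (undefined
#' aspect) get exposure 0.5 (no prevailing-wind information). The index is
#' in `[0, 1]` before standardization.
#'
#' @param dtm terrain grid.
#' @param aspect aspect grid (degrees from north).
#' @param prevailing_bearing prevailing wind bearing (degrees, default 135).
#' @return snow-load grid in `[0, 1]`.
#' @export
snow_load <- function(dtm, aspect, prevailing_bearing = 135) {
  stop_if_misaligned(dtm, aspect)
  z <- dtm$values
  zr <- range(z, na.rm = TRUE)
  if (zr[1] == zr[2]) stop("elevation range is zero; snow-load index undefined")
  E <- (z - zr[1]) / (zr[2] - zr[1])
  leeward <- (prevailing_bearing + 180) %% 360
  W <- (1 + cos((aspect$values - leeward) * pi / 180)) / 2
  W[is.na(aspect$values)] <- 0.5
  grid_like(dtm, E * W)
}

#' Vegetation height index
#'
#' Canopy height as surface model minus terrain model (m). Values above 5 m
#' are treated as forest by the study-area mask; slightly negative values
#' from sensor noise are preserved as-is.
#'
#' @param dsm,dtm aligned surface and terrain grids.
#' @return VHI grid (m).
#' @export
vhi <- function(dsm, dtm) {
  stop_if_misaligned(dsm, dtm)
  grid_like(dtm, dsm$values - dtm$values)
}

# names of the model covariates carried by a stack (aspect is auxiliary)
COVARIATE_NAMES <- c("dtm", "slope", "tpi", "vrm", "vhi",
                     "snow.load", "solrad", "twi")

#' Build the covariate stack from terrain and surface models
#'
#' Computes the eight den-selection covariates (elevation, slope, TPI, VRM,
#' VHI, snow load, solar radiation, TWI) plus aspect, all aligned on the
#' DTM geometry. The returned stack is unstandardized; standardize it
#' against a reference (availability) sample with [standardize_stack()].
#'
#' @param dtm,dsm aligned terrain and surface grids.
#' @param latitude_deg site latitude for the solar model.
#' @param prevailing_bearing prevailing wind bearing for the snow-load index.
#' @param tpi_radius_m TPI window radius (m).
#' @param vrm_window_m VRM window edge (m).
#' @return list of class `"covariate_stack"` with elements `grids` (named
#'   list of grids), `standardization` (NULL until standardized),
#'   `standardized` (flag).
#' @export
build_covariates <- function(dtm, dsm, latitude_deg = 59.3,
                             prevailing_bearing = 135,
                             tpi_radius_m = 140, vrm_window_m = 15) {
  stop_if_misaligned(dtm, dsm)
  sa <- slope_aspect(dtm)
  grids <- list(
    dtm = dtm,
    slope = sa$slope,
    aspect = sa$aspect,
    tpi = tpi(dtm, tpi_radius_m),
    vrm = vrm(sa$slope, sa$aspect, vrm_window_m),
    vhi = vhi(dsm, dtm),
    snow.load = snow_load(dtm, sa$aspect, prevailing_bearing),
    solrad = solar_radiation(dtm, sa$slope, sa$aspect, latitude_deg),
    twi = twi(dtm)
  )
  structure(list(grids = grids, standardization = NULL, standardized = FALSE),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %s; standardized: %s\n",
              paste(names(x$grids), collapse = ", "),
              if (isTRUE(x$standardized)) "yes" else "no"))
  invisible(x)
}

#' Standardize a covariate stack against a reference sample
#'
#' Each model covariate is transformed to `(x - mean) / sd` using the mean
#' and sd of the reference sample — by convention the availability sample,
#' which defines the scale against which selection is measured. The
#' parameters are stored so the transform is invertible with
#' [unstandardize_stack()].
#'
#' @param stack a [build_covariates()] stack.
#' @param reference data.frame of raw covariate values at the reference
#'   points (one column per model covariate).
#' @return the stack with standardized covariate grids and a
#'   `standardization` table of `(name, mean, sd)`.
#' @export
standardize_stack <- function(stack, reference) {
  stopifnot(inherits(stack, "covariate_stack"))
  if (isTRUE(stack$standardized)) stop("stack is already standardized")
  if (!is.data.frame(reference) || nrow(reference) == 0)
    stop("reference sample must be a nonempty data.frame")
  covs <- intersect(COVARIATE_NAMES, names(stack$grids))
  missing <- setdiff(covs, names(reference))
  if (length(missing))
    stop("reference sample lacks covariates: ", paste(missing, collapse = ", "))
  pars <- data.frame(name = covs, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(covs)) {
    v <- reference[[covs[i]]]
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s <= 0)
      stop("zero or undefined sd for covariate '", covs[i], "'")
    pars$mean[i] <- m
    pars$sd[i] <- s
    g <- stack$grids[[covs[i]]]
    stack$grids[[covs[i]]] <- grid_like(g, (g$values - m) / s)
  }
  stack$standardization <- pars
  stack$standardized <- TRUE
  stack
}

#' Invert the standardization of a covariate stack
#' @param stack a standardized stack.
#' @return the stack on the original covariate scales.
#' @export
unstandardize_stack <- function(stack) {
  stopifnot(inherits(stack, "covariate_stack"), isTRUE(stack$standardized))
  pars <- stack$standardization
  for (i in seq_len(nrow(pars))) {
    g <- stack$grids[[pars$name[i]]]
    stack$grids[[pars$name[i]]] <-
      grid_like(g, g$values * pars$sd[i] + pars$mean[i])
  }
  stack$standardization <- NULL
  stack$standardized <- FALSE
  stack
}
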