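#' Synthetic alpine landscape configuration
#'
#' Bundles the parameters of the synthetic study system: a rugged coastal
#' alpine landscape with elevations spanning roughly 300-2,050 m, a noisy
#' forest line centred near 480 m (sd 168 m), glaciers capping the highest
#' terrain, and a prevailing winter storm wind from 135 degrees. These
#' defaults emulate the northern Southeast Alaska setting the den-selection
#' model was developed for.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param nx,ny grid extent in cells (>= 32 each).
#' @param cellsize cell size in metres.
#' @param relief numeric length-2, min/max elevation (m).
#' @param forest_line_mean,forest_line_sd forest-line elevation (m): the
#'   upper limit of continuous canopy, spatially smoothed noise.
#' @param glacier_fraction fraction of the (highest) cells mapped as glacier,
#'   in `[0, 1)`.
#' @param heliport_count number of heliports placed along the survey route.
#' @param prevailing_wind_bearing prevailing storm wind bearing (degrees
#'   clockwise from north); snow loading is maximal on the opposite (leeward)
#'   aspect.
#' @param spectral_exponent power-law exponent of the spectral DEM synthesis;
#'   larger values give smoother terrain.
#' @return A list of class `"landscape_config"`.
#' @export
landscape_config <- function(seed = 1L,
                             nx = 128L, ny = 128L,
                             cellsize = 5,
                             relief = c(300, 2048),
                             forest_line_mean = 480,
                             forest_line_sd = 168,
                             glacier_fraction = 0.15,
                             heliport_count = 3L,
                             prevailing_wind_bearing = 135,
                             spectral_exponent = 1.8) {
  stopifnot(
    cellsize > 0,
    length(relief) == 2L, relief[1] < relief[2],
    forest_line_mean >= relief[1], forest_line_mean <= relief[2],
    glacier_fraction >= 0, glacier_fraction < 1,
    heliport_count >= 1L
  )
  structure(
    list(
      seed = as.integer(seed), nx = as.integer(nx), ny = as.integer(ny),
      cellsize = cellsize, relief = relief,
      forest_line_mean = forest_line_mean, forest_line_sd = forest_line_sd,
      glacier_fraction = glacier_fraction,
      heliport_count = as.integer(heliport_count),
      prevailing_wind_bearing = prevailing_wind_bearing,
      spectral_exponent = spectral_exponent
    ),
    class = "landscape_config"
  )
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Fractal random field by Fourier spectral synthesis: white complex noise
# filtered by f^(-exponent), inverse transformed, returned as an ny x nx
# matrix with zero mean and unit sd.
spectral_field <- function(nx, ny, exponent, seed) {
  with_seed(seed, {
    re <- matrix(stats::rnorm(nx * ny), ny, nx)
    im <- matrix(stats::rnorm(nx * ny), ny, nx)
    noise <- complex(real = re, imaginary = im)
    fy <- c(0, seq_len(ny - 1)) / ny
    fy <- pmin(fy, 1 - fy)
    fx <- c(0, seq_len(nx - 1)) / nx
    fx <- pmin(fx, 1 - fx)
    f <- sqrt(outer(fy^2, fx^2, `+`))
    amp <- ifelse(f > 0, f^(-exponent), 0)  # kill the DC term
    z <- Re(stats::fft(matrix(noise, ny, nx) * amp, inverse = TRUE))
    (z - mean(z)) / stats::sd(z)
  })
}

#' Generate a synthetic digital terrain model
#'
#' Spectral-synthesis (power-law filtered Gaussian noise) surface rescaled
#' exactly to the configured relief range. Deterministic for a fixed
#' config/seed; no nodata cells.
#'
#' @param cfg a [landscape_config()].
#' @return A [make_grid()] raster of elevations (m).
#' @export
generate_dtm <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  if (cfg$nx < 32L || cfg$ny < 32L)
    stop("extent must be at least 32 x 32 cells for moving-window terrain metrics")
  z <- spectral_field(cfg$nx, cfg$ny, cfg$spectral_exponent, cfg$seed)
  z <- (z - min(z)) / (max(z) - min(z))
  z <- cfg$relief[1] + z * (cfg$relief[2] - cfg$relief[1])
  make_grid(z, xmin = 0, ymin = 0, cellsize = cfg$cellsize)
}

#' Generate a synthetic digital surface model (terrain + canopy)
#'
#' Adds a canopy-height field to the DTM: 15-30 m canopy well below a
#' spatially noisy forest line, tapering through a krummholz transition to
#' under 1 m in the alpine. The DSM is never below the DTM.
#'
#' @param dtm terrain grid from [generate_dtm()].
#' @param cfg the matching [landscape_config()].
#' @return A grid of surface elevations (m).
#' @export
generate_dsm <- function(dtm, cfg) {
  stopifnot(is_grid(dtm), inherits(cfg, "landscape_config"))
  z <- dtm$values
  fl <- cfg$forest_line_mean +
    cfg$forest_line_sd * spectral_field(cfg$nx, cfg$ny, 3, cfg$seed + 1L)
  # taper: full canopy below the local forest line, krummholz within ~50 m
  taper <- stats::plogis((fl - z) / 35)
  u <- spectral_field(cfg$nx, cfg$ny, 2, cfg$seed + 2L)
  u <- (u - min(u)) / (max(u) - min(u))
  canopy <- (15 + 15 * u) * taper
  canopy[canopy < 0] <- 0
  grid_like(dtm, z + canopy)
}

#' Generate the aerial survey route and glacier mask
#'
#' The route is a smooth west-east polyline tracking the mid-elevation band
#' (the open terrain an aerial den survey would follow); glaciers occupy the
#' configured fraction of the highest cells.
#'
#' @param dtm terrain grid.
#' @param cfg the matching [landscape_config()].
#' @return list with `route` (two-column matrix of vertex x/y, m) and
#'   `glaciers` (0/1 grid).
#' @export
generate_route_and_glaciers <- function(dtm, cfg) {
  stopifnot(is_grid(dtm), inherits(cfg, "landscape_config"))
  z <- dtm$values
  # glaciers: exactly the top glacier_fraction of cells by elevation
  if (cfg$glacier_fraction > 0) {
    thr <- stats::quantile(z, 1 - cfg$glacier_fraction, names = FALSE)
    gl <- (z >= thr) * 1
  } else {
    gl <- matrix(0, nrow(z), ncol(z))
  }
  # route: per column, the row whose elevation is closest to the mid band,
  # smoothed so the polyline is flyable
  zmid <- stats::quantile(z, 0.45, names = FALSE)
  best_row <- apply(abs(z - zmid), 2, which.min)
  j <- seq_len(ncol(z))
  sm <- stats::smooth.spline(j, best_row, df = min(8, length(j) - 1))
  ys <- pmin(pmax(stats::predict(sm, j)$y, 1), nrow(z))
  cs <- dtm$cellsize
  route <- cbind(
    x = dtm$xmin + (j - 0.5) * cs,
    y = dtm$ymin + (ys - 0.5) * cs
  )
  list(route = route, glaciers = grid_like(dtm, gl))
}

#' Place heliports along the survey route
#'
#' Heliports sit on the route at evenly spaced stations, emulating staging
#' areas from which helicopter activity radiates.
#'
#' @param route two-column matrix of route vertices.
#' @param n number of heliports.
#' @return data.frame with columns `x`, `y`.
#' @export
place_heliports <- function(route, n) {
  stopifnot(n >= 1, nrow(route) >= n)
  idx <- round(seq(1, nrow(route), length.out = n + 2L))[seq_len(n) + 1L]
  data.frame(x = route[idx, 1], y = route[idx, 2])
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper running [generate_dtm()], [generate_dsm()],
#' [generate_route_and_glaciers()] and [place_heliports()] for one
#' configuration.
#'
#' @param cfg a [landscape_config()].
#' @return list with `cfg`, `dtm`, `dsm`, `glaciers`, `route`, `heliports`.
#' @export
simulate_landscape <- function(cfg) {
  dtm <- generate_dtm(cfg)
  dsm <- generate_dsm(dtm, cfg)
  rg <- generate_route_and_glaciers(dtm, cfg)
  heliports <- place_heliports(rg$route, cfg$heliport_count)
  list(cfg = cfg, dtm = dtm, dsm = dsm, glaciers = rg$glaciers,
       route = rg$route, heliports = heliports)
}

#' Define a true selection function for den simulation
#'
#' The exponential selection function `w(x) = exp(b1 x1 + ... + bn xn)` on
#' standardized covariates, used to place synthetic dens with known
#' preferences so downstream model fitting can be checked for parameter
#' recovery.
#'
#' @param beta named numeric vector of coefficients; names are covariate
#'   terms (`"dtm"`, `"slope"`, ...) with `"_sq"` marking quadratics
#'   (`"dtm_sq"` is elevation squared).
#' @param n_dens number of dens to simulate (>= 1).
#' @return list of class `"true_selection"`.
#' @export
true_selection <- function(beta, n_dens) {
  stopifnot(is.numeric(beta), length(beta) >= 1, !is.null(names(beta)),
            all(nzchar(names(beta))), n_dens >= 1)
  structure(list(beta = beta, n_dens = as.integer(n_dens)),
            class = "true_selection")
}

# split "dtm_sq" -> list(cov = "dtm", power = 2)
parse_term <- function(term) {
  if (grepl("_sq$", term)) list(cov = sub("_sq$", "", term), power = 2L)
  else list(cov = term, power = 1L)
}

# linear predictor over all cells of a standardized stack for named betas
stack_linear_predictor <- function(stack, beta) {
  lp <- 0
  for (term in names(beta)) {
    pt <- parse_term(term)
    g <- stack$grids[[pt$cov]]
    if (is.null(g)) stop("covariate '", pt$cov, "' not in stack")
    lp <- lp + beta[[term]] * g$values^pt$power
  }
  lp
}

#' Simulate den locations from a known selection function
#'
#' Exact importance sampling at the cell level: `n_dens` cells are drawn
#' without replacement from the unmasked cells with probability proportional
#' to `exp(sum(beta * x))` on the standardized covariates, then each den is
#' jittered uniformly within its cell (west/south corner + uniform offset,
#' so point-to-cell lookup recovers the sampled cell exactly).
#'
#' @param stack a standardized [covariate_stack].
#' @param truth a [true_selection()].
#' @param mask 0/1 grid of eligible cells.
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`, `label = "used"`.
#' @export
simulate_dens <- function(stack, truth, mask, seed) {
  stopifnot(inherits(truth, "true_selection"), is_grid(mask))
  if (!isTRUE(stack$standardized))
    stop("stack must be standardized before simulating dens")
  lp <- stack_linear_predictor(stack, truth$beta)
  eligible <- which(mask$values > 0 & is.finite(lp))
  if (length(eligible) == 0) stop("mask is empty")
  if (truth$n_dens > length(eligible))
    stop("n_dens exceeds the number of unmasked cells")
  w <- exp(lp[eligible] - max(lp[eligible]))
  cells <- with_seed(seed, {
    picked <- sample(eligible, truth$n_dens, replace = FALSE, prob = w)
    jx <- stats::runif(truth$n_dens)
    jy <- stats::runif(truth$n_dens)
    list(picked = picked, jx = jx, jy = jy)
  })
  nr <- nrow(mask$values)
  row <- (cells$picked - 1L) %% nr + 1L
  col <- (cells$picked - 1L) %/% nr + 1L
  cs <- mask$cellsize
  data.frame(
    x = mask$xmin + (col - 1L) * cs + cells$jx * cs,
    y = mask$ymin + (row - 1L) * cs + cells$jy * cs,
    label = "used"
  )
}

#' Simulate helicopter flight-track fixes
#'
#' Fixes are drawn from an equal-weight mixture of bivariate Gaussians
#' centred on the heliports; optionally a fraction of fixes is blurred along
#' the survey route to mimic transit flight. Deterministic per seed.
#'
#' @param heliports data.frame with `x`, `y` (>= 1 row).
#' @param n_fixes number of fixes to draw.
#' @param spread Gaussian sd around each heliport (m).
#' @param seed integer seed.
#' @param route optional route polyline for along-route blur.
#' @param route_prop fraction of fixes placed along the route (default 0).
#' @return data.frame with columns `x`, `y`, `label = "fix"`.
#' @export
simulate_flight_tracks <- function(heliports, n_fixes, spread, seed,
                                   route = NULL, route_prop = 0) {
  stopifnot(nrow(heliports) >= 1, n_fixes >= 1, spread >= 0,
            route_prop >= 0, route_prop <= 1)
  if (is.null(route)) route_prop <- 0
  with_seed(seed, {
    n_route <- round(n_fixes * route_prop)
    n_heli <- n_fixes - n_route
    comp <- sample.int(nrow(heliports), n_heli, replace = TRUE)
    x <- heliports$x[comp] + stats::rnorm(n_heli, sd = spread)
    y <- heliports$y[comp] + stats::rnorm(n_heli, sd = spread)
    if (n_route > 0) {
      v <- sample.int(nrow(route), n_route, replace = TRUE)
      x <- c(x, route[v, 1] + stats::rnorm(n_route, sd = spread / 2))
      y <- c(y, route[v, 2] + stats::rnorm(n_route, sd = spread / 2))
    }
    data.frame(x = x, y = y, label = "fix")
  })
}
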