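# Shared fixtures built in code. The small study is cached per session so
# several test files can reuse one simulated landscape.

tiny_cfg <- function(seed = 101L, nx = 64L, ny = 64L, ...) {
  landscape_config(seed = seed, nx = nx, ny = ny, ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_den_study(
      101L, cfg = tiny_cfg(), n_dens = 150, n_available = 2000)
  }
  .fixture_env$study
}

# an inclined-plane DTM: z = gx * x + gy * y + z0 (coordinates in metres)
plane_dtm <- function(n = 21, cellsize = 5, gx = 0, gy = 0, z0 = 1000) {
  xs <- (seq_len(n) - 0.5) * cellsize
  z <- outer(xs, xs, function(y, x) z0 + gx * x + gy * y)
  make_grid(z, cellsize = cellsize)
}

# hand-rolled covariate stack for tests that bypass build_covariates()
manual_stack <- function(grids, standardized = TRUE) {
  structure(list(grids = grids, standardization = NULL,
                 standardized = standardized),
            class = "covariate_stack")
}

# brute-force TPI oracle: double loop over a circular window, centre excluded
tpi_oracle <- function(z, r_cells) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; cnt <- 0
    for (di in -r_cells:r_cells) for (dj in -r_cells:r_cells) {
      if (di == 0 && dj == 0) next
      if (di * di + dj * dj > r_cells * r_cells) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      acc <- acc + z[ii, jj]; cnt <- cnt + 1
    }
    out[i, j] <- z[i, j] - acc / cnt
  }
  out
}

# brute-force VRM oracle: explicit normal sums over a (2k+1)^2 window
vrm_oracle <- function(slope_deg, aspect_deg, k = 1) {
  nr <- nrow(slope_deg); nc <- ncol(slope_deg)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(slope_deg[i, j])) next
    sx <- sy <- sz <- 0; cnt <- 0
    for (di in -k:k) for (dj in -k:k) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      s <- slope_deg[ii, jj]
      if (is.na(s)) next
      a <- aspect_deg[ii, jj]
      if (is.na(a)) a <- 0
      s <- s * pi / 180; a <- a * pi / 180
      sx <- sx + sin(s) * sin(a); sy <- sy + sin(s) * cos(a); sz <- sz + cos(s)
      cnt <- cnt + 1
    }
    out[i, j] <- 1 - sqrt(sx^2 + sy^2 + sz^2) / cnt
  }
  out
}

# recursive MD8 accumulation oracle (memoized upstream recursion)
accumulation_oracle <- function(zf, cellsize, p = 1.1) {
  nr <- nrow(zf); nc <- ncol(zf)
  acc <- matrix(NA_real_, nr, nc)
  offs <- cbind(dy = c(-1,-1,-1,0,0,1,1,1), dx = c(-1,0,1,-1,1,-1,0,1))
  dist <- sqrt(offs[,1]^2 + offs[,2]^2) * cellsize
  # weight of flow from (i2,j2) into (i,j)
  inflow_weight <- function(i2, j2, i, j) {
    drops <- numeric(0)
    for (o in 1:8) {
      ii <- i2 + offs[o,1]; jj <- j2 + offs[o,2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      d <- (zf[i2,j2] - zf[ii,jj]) / dist[o]
      if (d > 0) drops <- c(drops, stats::setNames(d^p, paste(ii, jj)))
    }
    if (!length(drops)) return(0)
    w <- drops[paste(i, j)]
    if (is.na(w)) 0 else unname(w / sum(drops))
  }
  visit <- function(i, j) {
    if (!is.na(acc[i, j])) return(acc[i, j])
    acc[i, j] <<- 1
    a <- 1
    for (o in 1:8) {
      ii <- i + offs[o,1]; jj <- j + offs[o,2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (zf[ii, jj] > zf[i, j]) {
        w <- inflow_weight(ii, jj, i, j)
        if (w > 0) a <- a + w * visit(ii, jj)
      }
    }
    acc[i, j] <<- a
    a
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) visit(i, j)
  acc
}

# scalar fine-step clear-sky integration for one horizontal cell
flat_solar_oracle <- function(latitude_deg, day_of_year = 91,
                              transmittance = 0.7, diffuse_fraction = 0.3,
                              step_min = 1) {
  phi <- latitude_deg * pi / 180
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  S0 <- 1361
  ws <- acos(min(max(-tan(phi) * tan(decl), -1), 1))
  n_steps <- ceiling(2 * ws * 12 / pi * 60 / step_min)
  dt_h <- (2 * ws * 12 / pi) / n_steps
  tot <- 0
  for (k in seq_len(n_steps)) {
    w <- -ws + (k - 0.5) * (2 * ws / n_steps)
    cosZ <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(w)
    if (cosZ <= 0) next
    m <- 1 / cosZ
    direct <- S0 * transmittance^m * cosZ
    diffuse <- diffuse_fraction * S0 * (1 - transmittance^m) * cosZ
    tot <- tot + (direct + diffuse) * dt_h
  }
  tot
}
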