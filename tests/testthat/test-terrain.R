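test_that("slope and aspect match the analytic plane", {
  # z rises eastward at 0.1 m/m: slope atan(0.1) = 5.71 deg, downslope west
  g <- plane_dtm(n = 11, gx = 0.1)
  sa <- slope_aspect(g)
  inner <- sa$slope$values[2:10, 2:10]
  expect_equal(inner, matrix(atan(0.1) * 180 / pi, 9, 9), tolerance = 1e-10)
  expect_equal(sa$aspect$values[2:10, 2:10], matrix(270, 9, 9), tolerance = 1e-10)
  expect_true(all(is.na(sa$slope$values[1, ])))  # edge cells are nodata
  # horizontal plane: slope 0, aspect undefined
  flat <- slope_aspect(plane_dtm(n = 5))
  expect_equal(flat$slope$values[2:4, 2:4], matrix(0, 3, 3))
  expect_true(all(is.na(flat$aspect$values[2:4, 2:4])))
  # north-rising plane drains south
  gs <- slope_aspect(plane_dtm(n = 7, gy = 0.2))
  expect_equal(gs$aspect$values[3, 3], 180)
})

test_that("TPI is zero on planes, signs peaks, and matches brute force", {
  pl <- plane_dtm(n = 15, gx = 0.3, gy = -0.1)
  p <- tpi(pl, radius_m = 15)
  expect_lt(max(abs(p$values[4:12, 4:12])), 1e-9 * diff(range(pl$values)))
  z <- matrix(0, 9, 9); z[5, 5] <- 10
  pk <- tpi(make_grid(z, cellsize = 5), radius_m = 10)
  expect_gt(pk$values[5, 5], 0)
  expect_lt(pk$values[5, 4], 0)
  set.seed(42)
  zr <- matrix(rnorm(21 * 21, 1000, 50), 21, 21)
  got <- tpi(make_grid(zr, cellsize = 5), radius_m = 15)  # radius 3 cells
  expect_equal(got$values, tpi_oracle(zr, 3), tolerance = 1e-12)
})

test_that("VRM is zero on smooth terrain, bounded, and matches hand sums", {
  sa <- slope_aspect(plane_dtm(n = 9, gx = 0.2, gy = 0.1))
  v <- vrm(sa$slope, sa$aspect)
  expect_equal(max(abs(v$values[3:7, 3:7])), 0, tolerance = 1e-12)
  # hand-built normals: centre window mixes axis-aligned directions
  s <- matrix(c(90, 90, 0, 90, 90, 0, 0, 0, 0), 3, 3)
  a <- matrix(c(0, 90, NA, 180, 270, NA, NA, NA, NA), 3, 3)
  sg <- make_grid(s, cellsize = 5); ag <- make_grid(a, cellsize = 5)
  got <- vrm(sg, ag, window_m = 15)
  expect_equal(got$values, vrm_oracle(s, a, 1), tolerance = 1e-12)
  # four horizontal normals cancel pairwise; five vertical remain: R = 5
  expect_equal(got$values[2, 2], 1 - 5 / 9, tolerance = 1e-12)
  # bounded on rugged synthetic terrain
  st <- small_study()
  sa2 <- slope_aspect(st$landscape$dtm)
  v2 <- vrm(sa2$slope, sa2$aspect)$values
  expect_true(all(v2 >= 0 & v2 <= 1, na.rm = TRUE))
})

test_that("TPI and VRM equal their brute-force oracles on random grids", {
  for (s in 1:8) {
    set.seed(s)
    z <- matrix(rnorm(25 * 25, 800, 120), 25, 25)
    g <- make_grid(z, cellsize = 5)
    expect_equal(tpi(g, radius_m = 15)$values, tpi_oracle(z, 3),
                 tolerance = 1e-12)
    sa <- slope_aspect(g)
    expect_equal(vrm(sa$slope, sa$aspect)$values,
                 vrm_oracle(sa$slope$values, sa$aspect$values, 1),
                 tolerance = 1e-12)
  }
})

test_that("terrain metrics are translation-invariant and rotation-consistent", {
  set.seed(13)
  z <- matrix(rnorm(20 * 20, 900, 80), 20, 20)
  g <- make_grid(z, cellsize = 5)
  gc <- make_grid(z + 250, cellsize = 5)
  expect_equal(tpi(g, 20)$values, tpi(gc, 20)$values, tolerance = 1e-9)
  sa <- slope_aspect(g); sac <- slope_aspect(gc)
  expect_equal(sa$slope$values, sac$slope$values)
  expect_equal(vrm(sa$slope, sa$aspect)$values,
               vrm(sac$slope, sac$aspect)$values)
  # rotating the DEM rotates slope and shifts aspect by a constant 90 deg
  rot <- function(m) t(m[nrow(m):1, ])
  gr <- make_grid(rot(z), cellsize = 5)
  sar <- slope_aspect(gr)
  expect_equal(sar$slope$values, rot(sa$slope$values))
  expect_equal(rot(tpi(g, 20)$values), tpi(gr, 20)$values, tolerance = 1e-9)
  d <- (sar$aspect$values - rot(sa$aspect$values)) %% 360
  expect_true(all(abs(d[!is.na(d)] - 90) < 1e-9 |
                    abs(d[!is.na(d)] - 270) < 1e-9))
  expect_equal(length(unique(round(d[!is.na(d)]))), 1L)
})

test_that("TWI increases downslope and matches the recursive oracle", {
  # inclined plane: accumulation grows linearly downslope (southward drain)
  g <- plane_dtm(n = 12, gy = 0.2)
  tw <- twi(g)
  mid <- tw$values[, 6]
  expect_true(all(diff(mid[2:11]) < 0))  # decreasing row = downslope = larger
  # tilted V-valley: upstream crest cells drain, downstream valley collects
  zv <- outer(1:10, 1:10, function(i, j) 500 + 20 * abs(j - 5.5) - 2 * i)
  gv <- make_grid(zv, cellsize = 5)
  tv <- twi(gv)
  expect_gt(tv$values[9, 5], tv$values[2, 5])  # down-valley beats up-valley
  expect_gt(tv$values[5, 5], tv$values[5, 3])  # valley floor beats mid-flank
  # oracle equivalence on the V-valley
  zf <- denscape:::fill_pits(zv)
  acc <- denscape:::flow_accumulation_md8(zf, 5)
  expect_equal(acc, accumulation_oracle(zf, 5), tolerance = 1e-6)
})

test_that("solar radiation orders aspects correctly and matches fine integration", {
  s30 <- make_grid(matrix(30, 3, 3), cellsize = 5)
  south <- make_grid(matrix(180, 3, 3), cellsize = 5)
  north <- make_grid(matrix(0, 3, 3), cellsize = 5)
  dummy <- make_grid(matrix(0, 3, 3), cellsize = 5)
  rs <- solar_radiation(dummy, s30, south)$values[2, 2]
  rn <- solar_radiation(dummy, s30, north)$values[2, 2]
  expect_gt(rs, rn)
  # flat cell vs 1-minute-step integration of the same irradiance model
  flat_s <- make_grid(matrix(0, 3, 3), cellsize = 5)
  flat_a <- make_grid(matrix(NA_real_, 3, 3), cellsize = 5)
  got <- solar_radiation(dummy, flat_s, flat_a, latitude_deg = 59.3)$values[2, 2]
  want <- flat_solar_oracle(59.3)
  expect_lt(abs(got - want) / want, 0.01)
  # with zero beam transmittance the output is linear in the diffuse term
  d1 <- solar_radiation(dummy, s30, south, transmittance = 0,
                        diffuse_fraction = 0.3)$values[2, 2]
  d2 <- solar_radiation(dummy, s30, south, transmittance = 0,
                        diffuse_fraction = 0.6)$values[2, 2]
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_error(solar_radiation(dummy, s30, south, latitude_deg = 70), "polar")
})

test_that("snow load hits its boundary values and stays within [0, 1]", {
  z <- make_grid(matrix(c(300, 1174, 2048, 1174), 2, 2), cellsize = 5)
  asp <- function(vals) make_grid(matrix(vals, 2, 2), cellsize = 5)
  # leeward aspect at the top of the relief: maximal loading
  expect_equal(snow_load(z, asp(315))$values[1, 2], 1.0)
  # windward aspect: zero regardless of elevation
  expect_equal(max(abs(snow_load(z, asp(135))$values)), 0, tolerance = 1e-12)
  # cross-wind aspect at mid elevation: 0.5 * 0.5
  expect_equal(snow_load(z, asp(225))$values[2, 1], 0.25, tolerance = 1e-12)
  expect_equal(snow_load(z, asp(45))$values[2, 1], 0.25, tolerance = 1e-12)
  # flat cells get exposure 0.5
  expect_equal(snow_load(z, asp(NA_real_))$values[1, 1], 0)
  expect_equal(snow_load(z, asp(NA_real_))$values[1, 2], 0.5)
  expect_error(snow_load(make_grid(matrix(500, 2, 2)), asp(0)), "range")
  st <- small_study()
  sl <- snow_load(st$landscape$dtm,
                  slope_aspect(st$landscape$dtm)$aspect)$values
  expect_true(all(sl >= 0 & sl <= 1, na.rm = TRUE))
})

test_that("VHI is the DSM-DTM difference with shape checking", {
  d <- plane_dtm(n = 5, gx = 0.1)
  expect_equal(vhi(d, d)$values, matrix(0, 5, 5))
  d7 <- grid_like(d, d$values + 7)
  expect_equal(vhi(d7, d)$values, matrix(7, 5, 5))
  expect_true(all(vhi(d7, d)$values > 5))  # forest-maskable
  expect_error(vhi(plane_dtm(n = 4), d), "aligned")
})

test_that("standardization is exact, invertible, and guards zero variance", {
  g <- make_grid(matrix(seq(0, 30, length.out = 16), 4, 4), cellsize = 5)
  grids <- list(dtm = g, slope = grid_like(g, g$values * 2))
  stack <- manual_stack(grids, standardized = FALSE)
  ref <- data.frame(dtm = c(1, 2, 3), slope = c(10, 20, 30),
                    tpi = 0, vrm = 0, vhi = 0, snow.load = 0, solrad = 0,
                    twi = 0)
  # only covariates present in the stack are standardized
  std <- standardize_stack(manual_stack(grids["dtm"], FALSE), ref["dtm"])
  expect_equal(std$grids$dtm$values, (g$values - 2) / 1)
  expect_equal((c(1, 2, 3) - 2) / sd(c(1, 2, 3)), c(-1, 0, 1))
  back <- unstandardize_stack(std)
  expect_equal(back$grids$dtm$values, g$values, tolerance = 1e-10)
  expect_error(
    standardize_stack(manual_stack(grids["dtm"], FALSE),
                      data.frame(dtm = rep(5, 4))),
    "dtm")
})

test_that("standardized availability sample has mean zero and unit sd", {
  st <- small_study()
  av <- st$design[st$design$label == "available", ]
  raw_av <- suppressMessages(
    extract_covariates(st$available, unstandardize_stack(st$stack)))
  pars <- st$stack$standardization
  for (cv in pars$name) {
    z <- (raw_av[[cv]] - pars$mean[pars$name == cv]) / pars$sd[pars$name == cv]
    expect_lt(abs(mean(z, na.rm = TRUE)), 1e-6)
    expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-6)
  }
})
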