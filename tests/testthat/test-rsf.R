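# a small two-covariate design with known structure
toy_design <- function(n_used = 60, n_avail = 600, seed = 5) {
  set.seed(seed)
  avail <- data.frame(x = 0, y = 0, label = "available",
                      dtm = rnorm(n_avail), slope = rnorm(n_avail))
  used <- data.frame(x = 0, y = 0, label = "used",
                     dtm = rnorm(n_used, 0.8), slope = rnorm(n_used, 0.4))
  rbind(used, avail)
}

test_that("the candidate set has 18 models with the documented structure", {
  cs <- candidate_set()
  expect_length(cs, 18L)
  expect_identical(vapply(cs, function(m) m$id, integer(1)), 1:18)
  k <- vapply(cs, function(m) length(m$terms), integer(1))
  expect_identical(k[c(1, 13, 14, 18)], c(5L, 9L, 8L, 16L))
  expect_setequal(cs[[14]]$terms,
                  c("dtm", "dtm_sq", "slope", "slope_sq", "snow.load",
                    "twi", "vhi", "vrm"))
  # every quadratic term is accompanied by its linear term
  for (m in cs) {
    quads <- grep("_sq$", m$terms, value = TRUE)
    expect_true(all(sub("_sq$", "", quads) %in% m$terms))
  }
})

test_that("swapping used and available labels exactly flips coefficients", {
  d <- toy_design()
  spec <- ms_spec <- candidate_set()[[1]]
  spec <- structure(list(id = 99L, name = "toy", terms = c("dtm", "slope")),
                    class = "model_spec")
  f1 <- fit_rsf(d, spec)
  d2 <- d
  d2$label <- ifelse(d$label == "used", "available", "used")
  f2 <- fit_rsf(d2, spec)
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-8)
})

test_that("a two-level covariate reproduces the closed-form log odds ratio", {
  d <- data.frame(
    label = c(rep("used", 40), rep("available", 100)),
    x = c(rep(1, 30), rep(0, 10), rep(1, 50), rep(0, 50))
  )
  spec <- structure(list(id = 1L, name = "t", terms = "x"), class = "model_spec")
  f <- fit_rsf(d, spec)
  expect_equal(unname(f$beta[["x"]]), log(3), tolerance = 1e-8)
})

test_that("reported log-likelihood matches a direct Bernoulli evaluation", {
  d <- toy_design()
  spec <- structure(list(id = 2L, name = "t", terms = c("dtm", "dtm_sq")),
                    class = "model_spec")
  f <- fit_rsf(d, spec)
  eta <- f$beta[["(Intercept)"]] + f$beta[["dtm"]] * d$dtm +
    f$beta[["dtm_sq"]] * d$dtm^2
  p <- plogis(eta)
  y <- as.integer(d$label == "used")
  expect_equal(f$loglik, sum(y * log(p) + (1 - y) * log(1 - p)),
               tolerance = 1e-8)
  # row order invariance
  f_shuf <- fit_rsf(d[sample(nrow(d)), ], spec)
  expect_equal(f_shuf$beta, f$beta, tolerance = 1e-8)
})

test_that("degenerate fits fail loudly", {
  spec <- structure(list(id = 3L, name = "t", terms = "x"), class = "model_spec")
  sep <- data.frame(label = c(rep("used", 20), rep("available", 20)),
                    x = c(rnorm(20, 10), rnorm(20, -10)))
  expect_error(fit_rsf(sep, spec), "separation")
  spec2 <- structure(list(id = 4L, name = "t", terms = c("x", "z")),
                     class = "model_spec")
  ali <- data.frame(label = c(rep("used", 30), rep("available", 30)),
                    x = rnorm(60))
  ali$z <- ali$x  # aliased copy
  expect_error(fit_rsf(ali, spec2), "aliased|singular")
})

test_that("AICc follows its formula, limits and monotonicity", {
  expect_equal(aicc(-100, 3, 1000), 206 + 24 / 996, tolerance = 1e-12)
  expect_equal(aicc(-100, 3, 1e9), -2 * (-100) + 2 * 3, tolerance = 1e-6)
  expect_gt(aicc(-100, 5, 200), aicc(-100, 4, 200))
  expect_error(aicc(-10, 5, 6), "n must exceed")
})

test_that("model ranking computes deltas and Akaike weights correctly", {
  aw <- akaike_weights(c(2.898, 0) + 1000)
  expect_equal(aw$delta, c(2.898, 0))
  expect_equal(aw$weight, c(0.1899, 0.8101), tolerance = 1e-3)
  expect_equal(sum(aw$weight), 1, tolerance = 1e-12)
  d <- toy_design()
  specs <- list(
    structure(list(id = 1L, name = "a", terms = "dtm"), class = "model_spec"),
    structure(list(id = 2L, name = "b", terms = c("dtm", "slope")),
              class = "model_spec"),
    structure(list(id = 3L, name = "c", terms = c("dtm", "dtm_sq", "slope")),
              class = "model_spec")
  )
  fits <- lapply(specs, function(s) fit_rsf(d, s))
  tab <- rank_models(fits)
  expect_equal(tab$delta[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(tab$aicc))
  # differing n is refused
  fits2 <- fits
  fits2[[2]] <- fit_rsf(toy_design(n_used = 50), specs[[2]])
  expect_error(rank_models(fits2), "differing")
})

test_that("RSF surfaces drop the intercept and are log-linear in covariates", {
  g <- make_grid(matrix(rnorm(64), 8, 8), cellsize = 5)
  stack <- manual_stack(list(dtm = g))
  fake_fit <- function(b0, b1) {
    structure(list(
      spec = structure(list(id = 1L, name = "t", terms = "dtm"),
                       class = "model_spec"),
      beta = c("(Intercept)" = b0, dtm = b1)), class = "rsf_fit")
  }
  w <- predict_surface(stack, fake_fit(0.3, 0.7))
  expect_equal(log(w$values), 0.7 * g$values, tolerance = 1e-12)
  # intercept is irrelevant to the surface
  w2 <- predict_surface(stack, fake_fit(-5, 0.7))
  expect_equal(w$values, w2$values)
  # all-zero coefficients give w = 1 everywhere
  w0 <- predict_surface(stack, fake_fit(2, 0))
  expect_equal(w0$values, matrix(1, 8, 8))
})

test_that("effect curves expose the quadratic optimum", {
  fake <- structure(list(
    spec = structure(list(id = 1L, name = "t", terms = c("slope", "slope_sq")),
                     class = "model_spec"),
    beta = c("(Intercept)" = 0, slope = 0.64, slope_sq = -0.17)),
    class = "rsf_fit")
  ec <- effect_curve(fake, "slope", range = c(-3, 5), n = 4001)
  expect_equal(attr(ec, "optimum"), 0.64 / (2 * 0.17), tolerance = 1e-12)
  expect_equal(ec$x[which.max(ec$w)], attr(ec, "optimum"), tolerance = 2e-3)
  # negative quadratic: unimodal (single sign change of the derivative)
  expect_equal(sum(diff(sign(diff(ec$w))) != 0), 1L)
  # zero coefficients: flat curve at 1
  fake0 <- fake; fake0$beta[] <- 0
  expect_equal(unique(effect_curve(fake0, "slope")$w), 1)
  expect_error(effect_curve(fake, "twi"), "not in the fitted model")
})

test_that("duplicated available rows equal weight-2 rows exactly", {
  d <- toy_design(n_used = 40, n_avail = 200)
  spec <- structure(list(id = 5L, name = "t", terms = "dtm"), class = "model_spec")
  f_dup <- fit_rsf(rbind(d, d[d$label == "available", ]), spec)
  w <- ifelse(d$label == "available", 2, 1)
  f_wt <- suppressWarnings(stats::glm(
    I(label == "used") ~ dtm, data = d, family = binomial(), weights = w,
    control = glm.control(epsilon = 1e-10)))
  expect_equal(unname(f_dup$beta), unname(coef(f_wt)), tolerance = 1e-8)
})
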