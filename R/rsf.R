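ms <- function(id, name, terms) {
  structure(list(id = id, name = name, terms = terms), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %d> %s: %s\n", x$id, x$name,
              paste(x$terms, collapse = " + ")))
  invisible(x)
}

#' The a priori candidate model set
#'
#' The 18 candidate used-available logistic models of den-site selection:
#' terrain-only, terrain+vegetation, terrain-complexity, climate (dry-snow
#' and thermal-insulation), combined terrain+climate, and global variants,
#' differing in which quadratic terms and optional factors are included.
#' Terms named `"<cov>_sq"` are quadratics and always accompany their
#' linear term. Model 14 — elevation and slope with quadratics plus snow
#' load, wetness, vegetation height and ruggedness — is the structure the
#' den simulations use as truth.
#'
#' @return list of 18 `model_spec` objects.
#' @export
candidate_set <- function() {
  list(
    ms(1L, "Terrain (sq)", c("dtm", "dtm_sq", "slope", "slope_sq", "tpi")),
    ms(2L, "Terrain", c("dtm", "dtm_sq", "slope", "slope_sq", "tpi", "tpi_sq")),
    ms(3L, "Terrain and vegetation",
       c("dtm", "dtm_sq", "slope", "slope_sq", "vhi", "tpi")),
    ms(4L, "Terrain and vegetation (sq)",
       c("dtm", "dtm_sq", "slope", "slope_sq", "vhi", "vhi_sq", "tpi", "tpi_sq")),
    ms(5L, "Terrain complexity (sq)", c("vrm", "tpi")),
    ms(6L, "Terrain complexity", c("vrm", "vrm_sq", "tpi", "tpi_sq")),
    ms(7L, "Climate dry snow (sq)", c("snow.load", "twi")),
    ms(8L, "Climate dry snow",
       c("snow.load", "snow.load_sq", "twi", "twi_sq")),
    ms(9L, "Climate thermal insulation (sq)", c("snow.load", "solrad")),
    ms(10L, "Climate thermal insulation",
        c("snow.load", "snow.load_sq", "solrad", "solrad_sq")),
    ms(11L, "Slope, vegetation and thermal (sq)",
        c("slope", "slope_sq", "snow.load", "snow.load_sq", "solrad",
          "tpi", "vhi")),
    ms(12L, "Slope, vegetation and thermal",
        c("slope", "slope_sq", "snow.load", "snow.load_sq", "solrad",
          "solrad_sq", "tpi", "tpi_sq", "vhi", "vhi_sq")),
    ms(13L, "Terrain, vegetation and dry/thermal snow",
        c("dtm", "dtm_sq", "slope", "slope_sq", "snow.load", "solrad",
          "solrad_sq", "twi", "vhi")),
    ms(14L, "Terrain, vegetation and dry snow",
        c("dtm", "dtm_sq", "slope", "slope_sq", "snow.load", "twi",
          "vhi", "vrm")),
    ms(15L, "Complex no-vrm (sq)",
        c("dtm", "dtm_sq", "slope", "slope_sq", "snow.load", "snow.load_sq",
          "solrad", "tpi", "twi", "vhi")),
    ms(16L, "Complex no-vrm quadratic",
        c("dtm", "dtm_sq", "slope", "slope_sq", "snow.load", "snow.load_sq",
          "solrad", "solrad_sq", "tpi", "tpi_sq", "twi", "twi_sq",
          "vhi", "vhi_sq")),
    ms(17L, "Complex (sq)",
        c("dtm", "dtm_sq", "slope", "slope_sq", "snow.load", "solrad",
          "tpi", "twi", "vhi", "vrm")),
    ms(18L, "Global",
        c("dtm", "dtm_sq", "slope", "slope_sq", "snow.load", "snow.load_sq",
          "solrad", "solrad_sq", "tpi", "tpi_sq", "twi", "twi_sq",
          "vhi", "vhi_sq", "vrm", "vrm_sq"))
  )
}

# design matrix (no intercept column; glm adds it) for a spec
term_columns <- function(design, terms) {
  out <- lapply(terms, function(tm) {
    pt <- parse_term(tm)
    if (is.null(design[[pt$cov]]))
      stop("design table lacks covariate '", pt$cov, "'")
    design[[pt$cov]]^pt$power
  })
  names(out) <- terms
  as.data.frame(out, check.names = FALSE)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (including the intercept).
#' @param n sample size (used + available rows).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a used-available logistic RSF model
#'
#' Maximum-likelihood logistic regression (used = 1, available = 0) of one
#' candidate specification on the standardized design table, via IRLS
#' (`stats::glm`). Reports Wald standard errors and 95% confidence
#' intervals (beta +/- 1.96 SE). The intercept is estimated but carries no
#' selection interpretation in a used-available design (it reflects the
#' arbitrary availability sample size), and is dropped when predicting
#' relative selection.
#'
#' @param design design table from [make_design()].
#' @param spec a `model_spec` from [candidate_set()].
#' @return object of class `"rsf_fit"`: `spec`, `beta`, `se`, `ci95`,
#'   `loglik`, `k`, `n`, `aicc`, `informative` (CI excludes zero).
#' @export
fit_rsf <- function(design, spec) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as.integer(design$label == "used")
  if (sum(y) < 1 || sum(1 - y) < 1)
    stop("need at least one used and one available row")
  X <- term_columns(design, spec$terms)
  if (anyNA(X)) stop("missing covariate values in design table")
  dat <- cbind(data.frame(.y = y), X)
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", spec$terms), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(
    fml, data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("singular design: aliased terms ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  # IRLS stops at the tolerance or the iteration cap; only a collapsed
  # deviance (every row perfectly classified, diverging beta) is an error
  if (fit$deviance < 1e-6)
    stop("perfect separation between used and available points")
  names(beta) <- c("(Intercept)", spec$terms)
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(beta)
  ci <- cbind(lo = beta - 1.96 * se, hi = beta + 1.96 * se)
  ll <- as.numeric(stats::logLik(fit))
  k <- length(beta)
  n <- nrow(dat)
  structure(list(
    spec = spec, beta = beta, se = se, ci95 = ci,
    loglik = ll, k = k, n = n, aicc = aicc(ll, k, n),
    informative = ci[, "lo"] > 0 | ci[, "hi"] < 0
  ), class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> model %d (%s): k = %d, n = %d, logLik = %.3f, AICc = %.3f\n",
              x$spec$id, x$spec$name, x$k, x$n, x$loglik, x$aicc))
  tab <- data.frame(beta = round(x$beta, 3), se = round(x$se, 3),
                    lo = round(x$ci95[, 1], 3), hi = round(x$ci95[, 2], 3))
  print(tab)
  invisible(x)
}

#' Akaike weights from AICc values
#' @param aicc_values numeric vector of AICc scores on the same data.
#' @return list with `delta` and `weight` (weights sum to 1).
#' @export
akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' Rank fitted models by AICc
#'
#' Computes Delta AICc and Akaike weights over a set of fits on identical
#' data and returns the model-selection table sorted by AICc (ties broken
#' by fewer parameters, then model id).
#'
#' @param fits list of `rsf_fit` objects fitted to the same design table.
#' @return data.frame with `id`, `name`, `k`, `loglik`, `aicc`, `delta`,
#'   `weight`, sorted ascending by AICc.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 2)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("fits were made on differing numbers of rows")
  tab <- data.frame(
    id = vapply(fits, function(f) f$spec$id, integer(1)),
    name = vapply(fits, function(f) f$spec$name, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1))
  )
  aw <- akaike_weights(tab$aicc)
  tab$delta <- aw$delta
  tab$weight <- aw$weight
  tab[order(tab$aicc, tab$k, tab$id), , drop = FALSE]
}

#' Predict the relative-selection (RSF) surface
#'
#' `w = exp(sum(beta * x))` per cell with the intercept omitted: scores are
#' proportional to the relative probability of selection, not absolute
#' probabilities. Nodata propagates.
#'
#' @param stack standardized covariate stack (same standardization as the
#'   fit's design table).
#' @param fit an `rsf_fit`.
#' @return grid of RSF scores.
#' @export
predict_surface <- function(stack, fit) {
  stopifnot(inherits(fit, "rsf_fit"))
  if (!isTRUE(stack$standardized))
    stop("stack must be standardized with the parameters used for fitting")
  beta <- fit$beta[names(fit$beta) != "(Intercept)"]
  lp <- stack_linear_predictor(stack, beta)
  template <- stack$grids[[parse_term(names(beta)[1])$cov]]
  grid_like(template, exp(lp))
}

#' Single-factor effect response curve
#'
#' Relative selection `w(x)` as one standardized covariate varies over a
#' range with all other covariates held at their mean (0 on the
#' standardized scale). For a linear + quadratic pair the curve's analytic
#' optimum sits at `-b1 / (2 b2)` standardized units from the mean.
#'
#' @param fit an `rsf_fit`.
#' @param covariate covariate name (e.g. `"slope"`).
#' @param range standardized range to evaluate (default -3..3).
#' @param n number of curve points.
#' @return data.frame `x` (standardized covariate), `w` (relative
#'   selection); attribute `optimum` gives the quadratic vertex when a
#'   quadratic term is present (otherwise `NA`).
#' @export
effect_curve <- function(fit, covariate, range = c(-3, 3), n = 201) {
  terms <- names(fit$beta)
  lin <- covariate
  quad <- paste0(covariate, "_sq")
  if (!(lin %in% terms))
    stop("covariate '", covariate, "' is not in the fitted model")
  b1 <- fit$beta[[lin]]
  b2 <- if (quad %in% terms) fit$beta[[quad]] else 0
  x <- seq(range[1], range[2], length.out = n)
  w <- exp(b1 * x + b2 * x^2)
  out <- data.frame(x = x, w = w)
  attr(out, "optimum") <- if (quad %in% terms && b2 != 0) -b1 / (2 * b2) else NA_real_
  out
}
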