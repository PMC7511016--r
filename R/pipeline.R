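#' Default den-selection simulation truth
#'
#' Named coefficient vector (standardized scale) used as the default truth
#' when simulating dens: strong avoidance of high elevation with a concave
#' quadratic, preference for moderately steep slopes, mild preference for
#' snow-loaded leeward sites and low vegetation, avoidance of wet and rugged
#' terrain. The structure matches candidate model 14.
#'
#' @return named numeric vector of coefficients.
#' @export
den_selection_truth <- function() {
  c(dtm = -1.91, dtm_sq = -1.78, slope = 0.64, slope_sq = -0.17,
    snow.load = 0.23, twi = -0.37, vhi = 0.18, vrm = -0.48)
}

#' Simulate a complete synthetic den-selection study
#'
#' Generates a landscape, derives and standardizes the covariate stack
#' (standardization reference = the availability sample), builds the
#' study-area mask, draws available points, simulates dens from a known
#' selection function, and assembles the used-available design table.
#'
#' @param seed integer seed driving every stochastic step.
#' @param cfg landscape configuration (default [landscape_config()] with
#'   this seed).
#' @param beta named truth coefficients (default [den_selection_truth()]).
#' @param n_dens number of dens to simulate.
#' @param n_available number of available points (`NULL` = 500 per km^2 of
#'   the masked area; small synthetic extents should pass an explicit n so
#'   the availability sample stays adequate).
#' @return list with `landscape`, `stack` (standardized), `mask`,
#'   `available`, `dens`, `design`, `truth`.
#' @export
simulate_den_study <- function(seed, cfg = landscape_config(seed = seed),
                               beta = den_selection_truth(),
                               n_dens = 500, n_available = 5000) {
  land <- simulate_landscape(cfg)
  stack <- build_covariates(land$dtm, land$dsm,
                            prevailing_bearing = cfg$prevailing_wind_bearing)
  mask <- build_study_mask(land$dtm, stack$grids$vhi, land$glaciers,
                           land$route)
  available <- draw_available(mask, seed = seed + 1L, n = n_available)
  ref <- suppressMessages(extract_covariates(available, stack))
  stack <- standardize_stack(stack, ref)
  truth <- true_selection(beta, n_dens)
  dens <- simulate_dens(stack, truth, mask, seed = seed + 2L)
  design <- suppressMessages(make_design(dens, available, stack))
  list(landscape = land, stack = stack, mask = mask, available = available,
       dens = dens, design = design, truth = truth)
}

#' Replicated parameter-recovery experiment
#'
#' Across replicate landscapes: simulate a study, fit the generating model
#' structure, record whether each 95% Wald CI covers its true coefficient,
#' and (optionally) fit the full 18-model candidate set and record which
#' model ranks first by AICc. This is the package's core self-check: the
#' fitting machinery must recover the selection function the simulator used.
#'
#' @param n_reps number of replicate landscapes.
#' @param seed base seed; replicate r uses `seed + 1000 * r` offsets.
#' @param n_dens,n_available per-replicate sample sizes.
#' @param rank_all also fit all 18 candidates per replicate (slower).
#' @param spec generating model spec (default candidate model 14).
#' @param beta truth coefficients (default [den_selection_truth()]).
#' @return list with `coverage` (replicates x terms logical matrix),
#'   `coverage_rate` (per-term), `top_id` (integer vector when `rank_all`),
#'   `top_rate` (share of replicates ranking the generating model first).
#' @export
recovery_experiment <- function(n_reps = 100, seed = 1L, n_dens = 500,
                                n_available = 5000, rank_all = TRUE,
                                spec = candidate_set()[[14]],
                                beta = den_selection_truth()) {
  stopifnot(setequal(names(beta), spec$terms))
  cover <- matrix(NA, n_reps, length(spec$terms),
                  dimnames = list(NULL, spec$terms))
  top_id <- rep(NA_integer_, n_reps)
  for (r in seq_len(n_reps)) {
    study <- simulate_den_study(seed + 1000L * r, n_dens = n_dens,
                                n_available = n_available, beta = beta)
    fit <- fit_rsf(study$design, spec)
    ci <- fit$ci95[spec$terms, , drop = FALSE]
    cover[r, ] <- beta[spec$terms] >= ci[, "lo"] & beta[spec$terms] <= ci[, "hi"]
    if (rank_all) {
      fits <- lapply(candidate_set(), function(s) fit_rsf(study$design, s))
      top_id[r] <- rank_models(fits)$id[1]
    }
  }
  list(
    coverage = cover,
    coverage_rate = colMeans(cover),
    top_id = if (rank_all) top_id else NULL,
    top_rate = if (rank_all) mean(top_id == spec$id) else NULL
  )
}
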