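#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), as used to
#' compare observed and expected bin proportions in binned cross-validation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("zero rank variance: correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' Binned k-fold cross-validation of an RSF model
#'
#' The used points are shuffled into `k` folds; for each fold the model is
#' refitted on the remaining used points plus all available points. The
#' available points are scored, sorted, and cut into `n_bins` equal-count
#' bins; the expected proportion per bin is the bin's mean score divided by
#' the sum of bin mean scores. Held-out used points are scored and assigned
#' to bins with the same breakpoints (upper-inclusive), giving observed
#' proportions; the fold statistic is the Spearman correlation of observed
#' vs expected across bins. Each iteration repartitions the used points and
#' reports the mean fold rho (or a single rho over pooled held-out points
#' when `pool_folds = TRUE`). High mean rho indicates that the model ranks
#' habitat proportionally to realized use.
#'
#' @param design design table from [make_design()].
#' @param spec a `model_spec`.
#' @param k number of folds (default 5).
#' @param n_bins number of score bins (default 10).
#' @param iterations number of random re-partitions (default 100).
#' @param seed integer seed.
#' @param pool_folds pool held-out points across folds before binning
#'   instead of averaging per-fold rho.
#' @return list of class `"validation_result"`: `per_iteration_rho`,
#'   `mean_rho`, `sd_rho`, `range`, `n_iterations`, `k_folds`, `n_bins`,
#'   `per_fold` (data.frame iteration/fold/rho when not pooling).
#' @export
kfold_validate <- function(design, spec, k = 5, n_bins = 10, iterations = 100,
                           seed = 1L, pool_folds = FALSE) {
  stopifnot(n_bins >= 2)
  used_idx <- which(design$label == "used")
  avail <- design[design$label == "available", , drop = FALSE]
  n_used <- length(used_idx)
  if (n_used < k) stop("need at least k used points")
  score <- function(fit, rows) {
    X <- term_columns(rows, fit$spec$terms)
    beta <- fit$beta[names(fit$beta) != "(Intercept)"]
    exp(as.matrix(X) %*% beta)[, 1]
  }
  per_fold <- list()
  rhos <- with_seed(seed, vapply(seq_len(iterations), function(it) {
    fold <- sample(rep_len(seq_len(k), n_used))
    fold_rho <- numeric(k)
    pooled_obs <- matrix(0, k, n_bins)
    expected <- matrix(0, k, n_bins)
    for (f in seq_len(k)) {
      hold <- used_idx[fold == f]
      if (length(hold) == 0) stop("a fold has zero held-out points")
      train <- rbind(design[setdiff(used_idx, hold), , drop = FALSE], avail)
      fit <- fit_rsf(train, spec)
      sa <- score(fit, avail)
      if (stats::sd(sa) == 0) stop("constant RSF scores: bins undefined")
      # equal-count bins on sorted available scores; upper-inclusive breaks
      srt <- sort(sa)
      cuts <- srt[floor(seq_len(n_bins - 1) * length(srt) / n_bins)]
      bin_of <- function(v) 1L + findInterval(v, cuts, left.open = TRUE)
      ab <- bin_of(sa)
      mean_by_bin <- vapply(seq_len(n_bins),
                            function(b) mean(sa[ab == b]), numeric(1))
      expected[f, ] <- mean_by_bin / sum(mean_by_bin)
      sh <- score(fit, design[hold, , drop = FALSE])
      ob <- tabulate(bin_of(sh), nbins = n_bins)
      pooled_obs[f, ] <- ob
      fold_rho[f] <- spearman_rho(ob / length(hold), expected[f, ])
    }
    per_fold[[length(per_fold) + 1L]] <<- data.frame(
      iteration = it, fold = seq_len(k), rho = fold_rho)
    if (pool_folds) {
      obs <- colSums(pooled_obs) / sum(pooled_obs)
      spearman_rho(obs, colMeans(expected))
    } else {
      mean(fold_rho)
    }
  }, numeric(1)))
  structure(list(
    per_iteration_rho = rhos,
    mean_rho = mean(rhos),
    sd_rho = stats::sd(rhos),
    range = range(rhos),
    n_iterations = iterations,
    k_folds = k,
    n_bins = n_bins,
    per_fold = do.call(rbind, per_fold)
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "<validation> %d iterations x %d folds, %d bins\n  mean rho %.3f (sd %.3f, range %.3f-%.3f)\n",
    x$n_iterations, x$k_folds, x$n_bins, x$mean_rho, x$sd_rho,
    x$range[1], x$range[2]))
  invisible(x)
}
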