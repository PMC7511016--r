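HABITAT_LABELS <- c("low", "low-moderate", "moderate", "moderate-high", "high")

#' Classify a surface into equal-area classes
#'
#' Breakpoints are placed at the 1/n, 2/n, ... quantiles of the non-nodata
#' pixel values (equal pixel counts per class, not equal value ranges), with
#' upper-inclusive class intervals so each breakpoint is the upper limit of
#' its class. With five classes, "prime" denning habitat is the top two
#' (moderate-high and high), which by construction cover 40% of the
#' unmasked area. Classification is invariant under strictly increasing
#' transforms of the surface.
#'
#' @param surface grid of raw scores (RSF, intensity, or risk).
#' @param n_classes number of classes (default 5).
#' @return object of class `"classified_surface"`: `raw`, `breakpoints`
#'   (n_classes - 1 ascending upper limits), `classes` (integer grid
#'   1..n_classes), `labels`, `class_areas_km2`.
#' @export
equal_area_classify <- function(surface, n_classes = 5) {
  v <- surface$values
  vv <- v[!is.na(v)]
  if (length(unique(vv)) < n_classes)
    stop("need at least ", n_classes, " distinct unmasked values")
  srt <- sort(vv)
  bp <- srt[floor(seq_len(n_classes - 1) * length(srt) / n_classes)]
  if (any(diff(bp) <= 0)) {
    counts <- table(findInterval(vv, unique(bp), left.open = TRUE))
    stop("ties span a quantile; achievable split: ",
         paste(counts, collapse = "/"))
  }
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- 1L + findInterval(v[ok], bp, left.open = TRUE)
  areas <- tabulate(cls[ok], nbins = n_classes) * surface$cellsize^2 / 1e6
  labels <- if (n_classes == 5) HABITAT_LABELS else paste0("class", seq_len(n_classes))
  structure(list(
    raw = surface,
    breakpoints = bp,
    classes = grid_like(surface, cls),
    labels = labels,
    n_classes = n_classes,
    class_areas_km2 = stats::setNames(areas, labels)
  ), class = "classified_surface")
}

#' @export
print.classified_surface <- function(x, ...) {
  cat(sprintf("<classified_surface> %d classes; breakpoints: %s\n",
              x$n_classes, paste(signif(x$breakpoints, 4), collapse = ", ")))
  print(round(x$class_areas_km2, 3))
  invisible(x)
}

#' Mask of prime habitat (top two of five classes)
#' @param classified a [equal_area_classify()] result with 5 classes.
#' @return 0/1 grid.
#' @export
prime_habitat_mask <- function(classified) {
  stopifnot(inherits(classified, "classified_surface"),
            classified$n_classes == 5)
  cls <- classified$classes$values
  grid_like(classified$classes, (!is.na(cls) & cls >= 4) * 1)
}

#' Tally dens by habitat class
#'
#' Looks up the habitat class under each den and reports per-class counts
#' and whole-percent shares, plus the share falling in prime habitat (top
#' two classes). Dens on nodata cells are counted in an "unclassified"
#' bucket and reported.
#'
#' @param classified a [equal_area_classify()] result.
#' @param dens data.frame with `x`, `y`.
#' @return list with `table` (class, count, pct), `n_dens`, `unclassified`,
#'   `prime_count`, `prime_pct` (whole percents of all dens).
#' @export
tally_dens <- function(classified, dens) {
  stopifnot(inherits(classified, "classified_surface"))
  cls <- grid_lookup(classified$classes, dens$x, dens$y)
  n <- nrow(dens)
  unclassified <- sum(is.na(cls))
  if (unclassified > 0)
    message(unclassified, " den(s) fell on unclassified (nodata) cells")
  counts <- tabulate(cls[!is.na(cls)], nbins = classified$n_classes)
  tab <- data.frame(
    class = classified$labels,
    count = counts,
    pct = round(100 * counts / n)
  )
  top2 <- classified$n_classes - 1:0
  prime_count <- sum(counts[top2])
  list(
    table = tab,
    n_dens = n,
    unclassified = unclassified,
    prime_count = prime_count,
    prime_pct = round(100 * prime_count / n)
  )
}
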