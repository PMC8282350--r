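## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Otsu threshold on the observed intensity range
#'
#' Thin wrapper around [EBImage::otsu()] that computes the threshold over the
#' observed range of `x`, which makes the resulting binarization equivariant
#' under uniform intensity scaling. Constant images return `Inf` so that the
#' corresponding mask is empty.
#'
#' @param x numeric matrix of intensities.
#' @return scalar threshold.
#' @keywords internal
otsu_threshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || diff(rng) <= .Machine$double.eps) return(Inf)
  EBImage::otsu(EBImage::Image(x), range = rng)
}

## Label connected components and return a list(labels, areas_px).
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  areas <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  list(labels = lab, areas_px = areas)
}

## Centroids (row, col) of labeled components, 1..n.
component_centroids <- function(labels) {
  n <- max(labels)
  if (n == 0) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  rows <- vapply(split(idx[, 1], lab), mean, numeric(1))
  cols <- vapply(split(idx[, 2], lab), mean, numeric(1))
  cbind(row = rows, col = cols)
}

## Deterministic RNG scope: all generators funnel through this.
with_rng_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## Clip numeric values into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Odd window length >= 3 closest to n samples.
odd_window <- function(n) {
  n <- max(3L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

## Structured "undefined result": an NA carrying an explicit reason, used
## where a metric must be signaled as undefined rather than silently 0.
undefined_result <- function(reason) {
  structure(NA_real_, undefined = TRUE, reason = reason)
}

#' Is a metric result explicitly undefined?
#'
#' Several metrics are undefined on degenerate inputs (no nuclei for the
#' myogenic index, fewer than three striation bands for sarcomere length,
#' no clusters for co-localization). Such results are `NA` values carrying
#' `undefined = TRUE` and a human-readable `reason` attribute; this
#' predicate tests for them.
#'
#' @param x a metric result.
#' @return `TRUE` when `x` is an explicitly undefined result.
#' @export
is_undefined <- function(x) isTRUE(attr(x, "undefined"))
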