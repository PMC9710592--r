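#' Entanglement configuration
#'
#' Settings shared by all metrics and untanglers.
#'
#' The displacement of a layout is the p-norm distance between matched leaf
#' positions, and the entanglement divides it by the worst case (the layout
#' whose right order is the exact reverse of the left). Two normalizations
#' are offered: `"power-ratio"` (default) divides the sums of p-th powers,
#' matching the entanglement of the dendextend R package; `"norm-ratio"`
#' takes the 1/p-th root of both before dividing. The two are related by a
#' strictly monotone transform, so they agree at 0 and 1 and rank layouts
#' identically — every algorithm in this package behaves the same under
#' either mode, only reported values differ.
#'
#' @param p norm order, a positive real; all results in the source study use
#'   `p = 2`.
#' @param mode `"power-ratio"` or `"norm-ratio"` (see above).
#' @param tol strict-improvement tolerance: a candidate counts as better only
#'   when its entanglement is lower by more than `tol`, preventing endless
#'   oscillation from floating-point rounding. Applied internally on the
#'   power-ratio scale.
#' @return An object of class `entanglement_config`.
#' @export
entanglement_config <- function(p = 2, mode = c("power-ratio", "norm-ratio"),
                                tol = 1e-12) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0)
    stop("p must be a single positive number", call. = FALSE)
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol < 0)
    stop("tol must be a single non-negative number", call. = FALSE)
  structure(list(p = p, mode = mode, tol = tol), class = "entanglement_config")
}

as_cfg <- function(cfg) {
  if (is.null(cfg)) return(entanglement_config())
  stopifnot(inherits(cfg, "entanglement_config"))
  cfg
}

tg_metrics <- function(L, p) {
  stopifnot(inherits(L, "tanglegram"))
  cpp_metrics(L$left$merge, L$right$merge, n_leaves(L), p)
}

# report a power-ratio entanglement on the configured scale
eps_on_scale <- function(ratio, cfg) {
  if (cfg$mode == "norm-ratio") ratio^(1 / cfg$p) else ratio
}

#' Displacement of a tanglegram layout
#'
#' Let the leaf occupying position `k` of the left order sit at position
#' `pi(k)` of the right order. The displacement is the p-norm
#' `(sum_k |k - pi(k)|^p)^(1/p)`; the raw power sum is attached as attribute
#' `"power_sum"` since the power-ratio entanglement is built from it.
#'
#' @param L a `tanglegram`.
#' @param cfg an [entanglement_config()].
#' @return Non-negative numeric with attribute `power_sum`.
#' @examples
#' Z <- comb_linkage(1:4)
#' displacement(tanglegram(Z, comb_linkage(4:1)))  # sqrt(20)
#' @export
displacement <- function(L, cfg = entanglement_config()) {
  cfg <- as_cfg(cfg)
  m <- tg_metrics(L, cfg$p)
  structure(m$power_sum^(1 / cfg$p), power_sum = m$power_sum)
}

#' Entanglement of a tanglegram layout
#'
#' The displacement divided by the worst displacement possible at that size
#' (right order the exact reverse of the left), an index in `[0, 1]`: 0 for
#' drawings with no crossings, 1 for the worst layout. See
#' [entanglement_config()] for the two normalization modes.
#'
#' @inheritParams displacement
#' @return Numeric in `[0, 1]`.
#' @examples
#' Z <- comb_linkage(1:4)
#' entanglement(tanglegram(Z, Z))                 # 0
#' entanglement(tanglegram(Z, comb_linkage(4:1)))  # 1
#' @export
entanglement <- function(L, cfg = entanglement_config()) {
  cfg <- as_cfg(cfg)
  m <- tg_metrics(L, cfg$p)
  eps_on_scale(m$power_sum / m$worst_sum, cfg)
}

#' Number of inter-tree edge crossings
#'
#' Two inter-tree edges cross exactly when their leaf positions invert
#' between the two sides, so the crossing count is the number of inversions
#' of the matching permutation, counted here in O(n log n) by merge
#' counting.
#'
#' @param L a `tanglegram`.
#' @return Non-negative integer.
#' @export
crossings <- function(L) {
  m <- tg_metrics(L, 2)
  as.integer(m$crossings)
}

#' Select the least entangled candidate (the selector)
#'
#' Argmin of [entanglement()] over a non-empty list of tanglegrams. Ties are
#' broken by earliest position in the list, which makes every algorithm
#' built on the selector deterministic given its input order.
#'
#' @param candidates non-empty list of `tanglegram` objects.
#' @param cfg an [entanglement_config()].
#' @return The winning `tanglegram`.
#' @export
select_best <- function(candidates, cfg = entanglement_config()) {
  if (!is.list(candidates) || length(candidates) == 0L)
    stop("select_best() needs a non-empty list of tanglegrams", call. = FALSE)
  cfg <- as_cfg(cfg)
  eps <- vapply(candidates, entanglement, numeric(1), cfg = cfg)
  candidates[[which.min(eps)]]
}

#' Metric report for a tanglegram
#'
#' Bundles displacement, entanglement and crossing count, ready for JSON
#' serialization (see [write_metric_report()]).
#'
#' @inheritParams displacement
#' @return List of class `metric_report` with elements `displacement`,
#'   `entanglement`, `crossings`, `p`, `mode`.
#' @export
metric_report <- function(L, cfg = entanglement_config()) {
  cfg <- as_cfg(cfg)
  m <- tg_metrics(L, cfg$p)
  structure(list(
    displacement = m$power_sum^(1 / cfg$p),
    entanglement = eps_on_scale(m$power_sum / m$worst_sum, cfg),
    crossings = as.integer(m$crossings),
    p = cfg$p,
    mode = cfg$mode
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("displacement %.6g | entanglement %.6g | crossings %d (p = %g, %s)\n",
              x$displacement, x$entanglement, x$crossings, x$p, x$mode))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param x a [metric_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(x, path) {
  stopifnot(inherits(x, "metric_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
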