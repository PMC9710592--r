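#' The step2side baseline untangler
#'
#' Greedy alternating hill climb, the strongest of the classic dendextend
#' untangle methods and the benchmark for everything else in this package.
#' Step 1 scans the internal vertices `i = 1..n-1` of the right tree in
#' ascending order, immediately accepting any rotation `Omega_i` that
#' strictly lowers the entanglement; Step 2 does the same on the left tree;
#' Step 3 repeats both until a full pass accepts nothing. The output is
#' locally optimal under single one-sided rotations, but — because it never
#' rotates both trees at once — it can terminate with crossings that a
#' coordinated pair of rotations would remove (see
#' [tanglegram_fixtures()]`$step2side_trap`).
#'
#' @param L a [tanglegram()].
#' @param cfg an [entanglement_config()].
#' @return An `untangle_result`: list with `tanglegram` (the optimized
#'   layout), `entanglement`, `crossings`, `method`, and `trace` (a
#'   `sweep_trace`: `passes`, `evaluations`, and `accepted_swaps`, a data
#'   frame of `(side, row)` in acceptance order).
#' @examples
#' L <- tanglegram_fixtures()$step2side_trap
#' step2side(L)$crossings  # stuck above the optimum of 0
#' @export
step2side <- function(L, cfg = entanglement_config()) {
  stopifnot(inherits(L, "tanglegram"))
  cfg <- as_cfg(cfg)
  res <- cpp_step2side(L$left$merge, L$right$merge, n_leaves(L), cfg$p, cfg$tol)
  make_untangle_result(L, res, "step2side", cfg,
                       trace_extra = list(passes = res$passes))
}

make_sweep_trace <- function(res, extra = list()) {
  tr <- c(list(
    evaluations = as.numeric(res$evaluations),
    accepted_swaps = data.frame(
      side = c("right", "left")[res$side],
      row = as.integer(res$row)
    )
  ), extra)
  class(tr) <- "sweep_trace"
  tr
}

make_untangle_result <- function(L, res, method, cfg, trace_extra = list()) {
  out_tg <- tg_with_merges(L, res$left, res$right)
  structure(list(
    tanglegram = out_tg,
    entanglement = eps_on_scale(res$entanglement, cfg),
    crossings = crossings(out_tg),
    method = method,
    trace = make_sweep_trace(res, trace_extra)
  ), class = "untangle_result")
}

#' @export
print.untangle_result <- function(x, ...) {
  cat(sprintf("%s: entanglement %.6g, crossings %d (%g evaluations",
              x$method, x$entanglement, x$crossings, x$trace$evaluations))
  if (!is.null(x$trace$passes)) cat(",", x$trace$passes, "passes")
  if (!is.null(x$trace$m_reached)) cat(", m reached", x$trace$m_reached)
  cat(")\n")
  invisible(x)
}
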