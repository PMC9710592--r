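#' Brute-force global optimum of a tanglegram
#'
#' Enumerates every one of the `2^(n-1) x 2^(n-1)` swap configurations of
#' the two trees and returns the globally minimal entanglement together
#' with the globally minimal crossing count (which may be attained at a
#' different configuration). Ties in entanglement are broken by the first
#' configuration in lexicographic order (left mask outer, right mask
#' inner), making the argmin layout deterministic. This is the ground truth
#' against which every heuristic is audited; the two-tree crossing
#' minimization problem is NP-complete, so the cap on `n` is essential.
#'
#' @param L a [tanglegram()].
#' @param cfg an [entanglement_config()].
#' @param max_leaves refuse instances larger than this (default 10, i.e.
#'   about 262,000 layouts).
#' @return An `oracle_result`: list with `min_entanglement`,
#'   `min_crossings`, `argmin_layout` (a `tanglegram`), and
#'   `layouts_evaluated`.
#' @examples
#' L <- tanglegram_fixtures()$step2side_trap
#' brute_force_optimum(L)$min_crossings  # 0: three-leaf pairs are drawable
#' @export
brute_force_optimum <- function(L, cfg = entanglement_config(), max_leaves = 10L) {
  stopifnot(inherits(L, "tanglegram"))
  cfg <- as_cfg(cfg)
  n <- n_leaves(L)
  if (n > max_leaves)
    stop(sprintf(paste0(
      "exhaustive enumeration over 4^%d layouts refused for n = %d leaves ",
      "(cap: %d). Raise max_leaves deliberately, or use a heuristic ",
      "untangler such as shuntan()."), n - 1L, n, max_leaves), call. = FALSE)
  res <- cpp_oracle(L$left$merge, L$right$merge, n, cfg$p)
  arg <- L
  arg$left <- swap_mask(L$left, as.integer(res$mask_left))
  arg$right <- swap_mask(L$right, as.integer(res$mask_right))
  structure(list(
    min_entanglement = eps_on_scale(res$min_entanglement, cfg),
    min_crossings = as.integer(res$min_crossings),
    argmin_layout = arg,
    layouts_evaluated = res$layouts_evaluated
  ), class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("oracle: min entanglement %.6g, min crossings %d (%g layouts)\n",
              x$min_entanglement, x$min_crossings, x$layouts_evaluated))
  invisible(x)
}

#' Enumerate all dendrogram topologies on n labelled leaves
#'
#' Generates one linkage matrix per unordered rooted binary tree shape over
#' leaves `1..n` — there are `(2n-3)!! = 1, 3, 15, 105, ...` of them — by
#' recursively splitting the leaf set at the root (the block containing the
#' smallest leaf is the canonical first child). Together with the
#' `2^(n-1)` child orderings reachable via [swap_omega()], this spans every
#' tanglegram side exhaustively, which is how the drawability boundary at
#' three leaves is verified.
#'
#' @param n number of leaves, `2 <= n <= 7` (the count grows as a double
#'   factorial).
#' @return List of `linkage_matrix` objects.
#' @examples
#' length(all_dendrograms(4))  # 15
#' @export
all_dendrograms <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2L || n > 7L)
    stop("n must be a single integer in 2..7", call. = FALSE)
  n <- as.integer(n)
  splits <- function(leafset) {
    # all unordered {A, B} partitions, A containing the smallest leaf
    first <- leafset[1L]
    rest <- leafset[-1L]
    out <- list()
    for (k in 0:(length(rest) - 1L)) {
      picks <- if (k == 0L) list(integer(0)) else
        apply(utils::combn(rest, k), 2L, identity, simplify = FALSE)
      for (pk in picks)
        out[[length(out) + 1L]] <- list(a = c(first, pk), b = setdiff(rest, pk))
    }
    out
  }
  enum <- function(leafset) {
    if (length(leafset) == 1L) return(list(leafset))
    out <- list()
    for (sp in splits(leafset))
      for (ta in enum(sp$a))
        for (tb in enum(sp$b))
          out[[length(out) + 1L]] <- list(ta, tb)
    out
  }
  nested_to_linkage <- function(tr) {
    rows <- matrix(0L, n - 1L, 3L)
    cnt <- 0L
    rec <- function(x) {
      if (!is.list(x)) return(c(x, 1L))
      a <- rec(x[[1L]])
      b <- rec(x[[2L]])
      cnt <<- cnt + 1L
      rows[cnt, ] <<- c(a[1L], b[1L], a[2L] + b[2L])
      c(n + cnt, a[2L] + b[2L])
    }
    rec(tr)
    linkage_matrix(cbind(rows[, 1:2, drop = FALSE], seq_len(n - 1L), rows[, 3L]))
  }
  lapply(enum(seq_len(n)), nested_to_linkage)
}
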