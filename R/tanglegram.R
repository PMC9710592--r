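#' Tanglegram: an ordered pair of dendrograms over the same leaves
#'
#' A tanglegram draws the left dendrogram facing the right one and joins leaf
#' `k` on one side to leaf `k` on the other by a straight inter-tree edge.
#' Both sides must therefore be linkage matrices over the same number of
#' leaves; leaf id `k` refers to the same object on both sides. Labels are
#' purely cosmetic: algorithms operate on ids.
#'
#' @param left,right `linkage_matrix` objects (or 4-column matrices, which
#'   are passed through [linkage_matrix()]).
#' @param labels optional named character vector mapping leaf ids to display
#'   labels, e.g. `c("1" = "setosa 9", ...)`.
#' @return An object of class `tanglegram`: list with `left`, `right`,
#'   `labels`.
#' @examples
#' Z <- linkage_matrix(rbind(c(1, 2, 0.3, 2), c(3, 5, 0.2, 3), c(4, 6, 0.7, 4)))
#' L <- tanglegram(Z, swap_omega(Z, 3))
#' entanglement(L)
#' @export
tanglegram <- function(left, right, labels = NULL) {
  if (!inherits(left, "linkage_matrix")) left <- linkage_matrix(left)
  if (!inherits(right, "linkage_matrix")) right <- linkage_matrix(right)
  if (left$n_leaves != right$n_leaves)
    stop(sprintf("leaf sets differ: left has %d leaves, right has %d",
                 left$n_leaves, right$n_leaves), call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (is.null(names(labels)) && length(labels) == left$n_leaves)
      names(labels) <- as.character(seq_len(left$n_leaves))
  }
  structure(list(left = left, right = right, labels = labels),
            class = "tanglegram")
}

#' @export
print.tanglegram <- function(x, ...) {
  m <- cpp_metrics(x$left$merge, x$right$merge, n_leaves(x), 2)
  cat("Tanglegram:", n_leaves(x), "leaves\n")
  cat("  left order :", paste(leaf_order(x$left), collapse = " "), "\n")
  cat("  right order:", paste(leaf_order(x$right), collapse = " "), "\n")
  cat(sprintf("  entanglement (p = 2): %.6g   crossings: %d\n",
              if (m$worst_sum > 0) m$power_sum / m$worst_sum else 0,
              as.integer(m$crossings)))
  invisible(x)
}

#' Mirror a tanglegram
#'
#' Rotates every internal vertex of both trees, reversing both leaf orders.
#' A mirrored tanglegram is the same drawing seen upside down, so its
#' displacement, entanglement and crossing count equal the original's.
#'
#' @param L a `tanglegram`.
#' @return The mirrored `tanglegram`.
#' @export
mirror_tanglegram <- function(L) {
  stopifnot(inherits(L, "tanglegram"))
  L$left$merge <- L$left$merge[, 2:1, drop = FALSE]
  L$right$merge <- L$right$merge[, 2:1, drop = FALSE]
  L
}

# rebuild a tanglegram from updated merge tables, keeping heights/sizes/labels
tg_with_merges <- function(L, ml, mr) {
  L$left$merge <- ml
  L$right$merge <- mr
  L
}
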