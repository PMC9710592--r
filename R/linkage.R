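#' Linkage matrix: the dendrogram encoding used throughout the package
#'
#' A dendrogram over `n` labelled leaves is stored as its linkage matrix: an
#' `(n-1) x 4` table in which row `t` merges the two nodes in its first two
#' columns into internal node `n + t`, records the merge height in column 3
#' and the number of leaves under the new node in column 4. Leaves are
#' numbered `1..n`, internal nodes `n+1..2n-1` (the root is `2n-1`), so every
#' child id in row `t` is smaller than `n + t`. Heights are retained for
#' faithful round-trip I/O but are never consulted by any untangling
#' algorithm, which operate on topology and child order alone.
#'
#' @param x numeric matrix (or data frame) with 4 columns and one row per
#'   merge, in the layout described above.
#' @param validate if `TRUE` (default), reject matrices violating the
#'   structural invariants; see [validate_linkage()].
#' @return An object of class `linkage_matrix`: a list with elements
#'   `merge` (integer `(n-1) x 2`), `height` (numeric), `size` (integer)
#'   and `n_leaves`.
#' @examples
#' Z <- linkage_matrix(rbind(
#'   c(1, 2, 0.3, 2),
#'   c(3, 5, 0.2, 3),
#'   c(4, 6, 0.7, 4)))
#' leaf_order(Z)
#' @seealso [leaf_order()], [swap_omega()], [locate_tau()], [tanglegram()]
#' @export
linkage_matrix <- function(x, validate = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || ncol(x) != 4L)
    stop("a linkage matrix must have exactly 4 columns", call. = FALSE)
  if (nrow(x) < 1L)
    stop("a linkage matrix needs at least one merge row (n >= 2)", call. = FALSE)
  if (!is.numeric(x) || anyNA(x))
    stop("linkage matrix entries must be numeric and non-missing", call. = FALSE)
  obj <- structure(list(
    merge = matrix(as.integer(round(x[, 1:2])), ncol = 2L),
    height = as.numeric(x[, 3L]),
    size = as.integer(round(x[, 4L])),
    n_leaves = nrow(x) + 1L
  ), class = "linkage_matrix")
  if (validate) {
    v <- validate_linkage(obj)
    if (length(v))
      stop("invalid linkage matrix:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  obj
}

#' @export
as.matrix.linkage_matrix <- function(x, ...) {
  cbind(x$merge[, 1L], x$merge[, 2L], x$height, x$size, deparse.level = 0)
}

#' @export
print.linkage_matrix <- function(x, ...) {
  cat("Linkage matrix:", x$n_leaves, "leaves,", nrow(x$merge), "merges\n")
  m <- as.matrix(x)
  dimnames(m) <- list(paste0("node", x$n_leaves + seq_len(nrow(m))),
                      c("child_a", "child_b", "height", "size"))
  print(m, ...)
  invisible(x)
}

#' Number of leaves of a linkage matrix or tanglegram
#'
#' @param x a `linkage_matrix` or `tanglegram`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(x) {
  if (inherits(x, "tanglegram")) return(x$left$n_leaves)
  if (inherits(x, "linkage_matrix")) return(x$n_leaves)
  stop("not a linkage_matrix or tanglegram", call. = FALSE)
}

#' Check the structural invariants of a linkage matrix
#'
#' Reports (rather than raises) every violation of the linkage-matrix
#' contract: `n - 1` rows; children created before their parent (ids in row
#' `t` below `n + t`); every node id except the root appearing exactly once
#' as a child; a size column consistent with the recursive leaf counts; and
#' non-negative heights.
#'
#' @param Z a `linkage_matrix` (possibly built with `validate = FALSE`).
#' @return Character vector of human-readable violations, empty when valid.
#' @examples
#' Z <- linkage_matrix(rbind(c(1, 2, 0.3, 2), c(3, 5, 0.2, 3), c(4, 6, 0.7, 4)))
#' validate_linkage(Z)  # character(0)
#' @export
validate_linkage <- function(Z) {
  if (!inherits(Z, "linkage_matrix"))
    stop("validate_linkage() expects a linkage_matrix", call. = FALSE)
  v <- character(0)
  n <- Z$n_leaves
  nr <- nrow(Z$merge)
  if (nr != n - 1L)
    v <- c(v, sprintf("expected %d merge rows for %d leaves, found %d", n - 1L, n, nr))
  kids <- as.vector(t(Z$merge))
  if (anyNA(kids)) return(c(v, "missing child ids"))
  for (t in seq_len(nr)) {
    for (j in 1:2) {
      k <- Z$merge[t, j]
      if (k < 1L || k >= n + t)
        v <- c(v, sprintf("row %d: child id %d out of range (must be in 1..%d)", t, k, n + t - 1L))
    }
    if (Z$merge[t, 1L] == Z$merge[t, 2L])
      v <- c(v, sprintf("row %d: both children are node %d", t, Z$merge[t, 1L]))
  }
  tab <- tabulate(kids[kids >= 1L & kids <= 2L * n - 1L], nbins = 2L * n - 1L)
  for (k in seq_len(2L * n - 2L)) {
    if (tab[k] == 0L) v <- c(v, sprintf("node %d never appears as a child", k))
    if (tab[k] > 1L) v <- c(v, sprintf("duplicate child: node %d appears %d times", k, tab[k]))
  }
  if (nr >= 1L && tab[2L * n - 1L] > 0L)
    v <- c(v, sprintf("root node %d must not appear as a child", 2L * n - 1L))
  if (!length(v)) {
    sz <- c(rep(1L, n), rep(NA_integer_, nr))
    for (t in seq_len(nr)) {
      sz[n + t] <- sz[Z$merge[t, 1L]] + sz[Z$merge[t, 2L]]
      if (sz[n + t] != Z$size[t])
        v <- c(v, sprintf("row %d: size mismatch (recorded %d, actual %d)",
                          t, Z$size[t], sz[n + t]))
    }
  }
  if (any(Z$height < 0))
    v <- c(v, sprintf("negative height in row(s) %s",
                      paste(which(Z$height < 0), collapse = ", ")))
  v
}

#' Leaf order induced by a linkage matrix
#'
#' The ordered leaf vector read off one side of the drawn dendrogram:
#' depth-first from the root (the last merge row), visiting each row's
#' column-1 child before its column-2 child. The source material leaves the
#' drawing convention open; this fixed convention makes every algorithm
#' deterministic, and any other fixed convention yields mirror-image layouts
#' with identical entanglement.
#'
#' @param Z a `linkage_matrix`.
#' @return Integer vector: a permutation of `1..n_leaves`.
#' @examples
#' Z <- linkage_matrix(rbind(c(1, 2, 0.3, 2), c(3, 5, 0.2, 3), c(4, 6, 0.7, 4)))
#' leaf_order(Z)  # 4 3 1 2
#' @export
leaf_order <- function(Z) {
  v <- validate_linkage(Z)
  if (length(v))
    stop("invalid linkage matrix:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  cpp_leaf_order(Z$merge, Z$n_leaves)
}

#' Rotate an internal vertex (the swap operator)
#'
#' Exchanges the two children of internal node `n + i`, i.e. swaps the first
#' two entries of row `i`. Graphically this rotates the subtree hanging off
#' that vertex; it changes the leaf order but not the (unordered) topology,
#' and applying it twice restores the input.
#'
#' @param Z a `linkage_matrix`.
#' @param i merge-row index, `1 <= i <= n_leaves - 1`.
#' @return A new `linkage_matrix` with row `i`'s children exchanged.
#' @examples
#' Z <- linkage_matrix(rbind(c(1, 2, 0.3, 2), c(3, 5, 0.2, 3), c(4, 6, 0.7, 4)))
#' leaf_order(swap_omega(Z, 3))  # 3 1 2 4
#' @export
swap_omega <- function(Z, i) {
  if (!inherits(Z, "linkage_matrix"))
    stop("swap_omega() expects a linkage_matrix", call. = FALSE)
  if (length(i) != 1L || is.na(i) || i < 1L || i > nrow(Z$merge))
    stop(sprintf("row index i must be in 1..%d", nrow(Z$merge)), call. = FALSE)
  i <- as.integer(i)
  Z$merge[i, ] <- Z$merge[i, 2:1]
  Z
}

#' Locate a node in a linkage matrix
#'
#' Returns the unique merge row in which node `k` appears as a child. Every
#' node except the root is a child in exactly one row; the location is
#' unchanged by [swap_omega()], which only reorders entries within a row.
#'
#' @param k node id (leaf `1..n` or internal `n+1..2n-2`; the root `2n-1`
#'   is never a child and raises an error).
#' @param Z a `linkage_matrix`.
#' @return Integer row index.
#' @examples
#' Z <- linkage_matrix(rbind(c(1, 2, 0.3, 2), c(3, 5, 0.2, 3), c(4, 6, 0.7, 4)))
#' locate_tau(5, Z)  # 2
#' @export
locate_tau <- function(k, Z) {
  if (!inherits(Z, "linkage_matrix"))
    stop("locate_tau() expects a linkage_matrix", call. = FALSE)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k))
    stop("k must be a single node id", call. = FALSE)
  if (k == 2L * Z$n_leaves - 1L)
    stop(sprintf("node %d is the root and appears in no row as a child", k), call. = FALSE)
  hit <- which(Z$merge[, 1L] == k | Z$merge[, 2L] == k)
  if (length(hit) != 1L)
    stop(sprintf("node %d not found as a child in the linkage matrix", k), call. = FALSE)
  hit
}

#' Caterpillar (comb) dendrogram realizing a prescribed leaf order
#'
#' Builds the maximally unbalanced binary dendrogram whose induced
#' [leaf_order()] equals `leaves`: leaf `leaves[1]` joins `leaves[2]` first,
#' and each later leaf joins the growing spine. Convenient for constructing
#' layouts with an exactly prescribed matching, e.g. the identical-order
#' (entanglement 0) and reversed-order (entanglement 1) endpoints.
#'
#' @param leaves integer vector, a permutation of `1..n` (`n >= 2`).
#' @param heights optional non-decreasing merge heights (default `1..n-1`).
#' @return A `linkage_matrix`.
#' @examples
#' leaf_order(comb_linkage(c(3, 1, 2)))  # 3 1 2
#' @export
comb_linkage <- function(leaves, heights = NULL) {
  n <- length(leaves)
  if (n < 2L || !setequal(leaves, seq_len(n)))
    stop("leaves must be a permutation of 1..n with n >= 2", call. = FALSE)
  if (is.null(heights)) heights <- seq_len(n - 1L)
  if (length(heights) != n - 1L)
    stop("heights must have length n - 1", call. = FALSE)
  m <- matrix(0L, n - 1L, 2L)
  m[1L, ] <- c(leaves[1L], leaves[2L])
  if (n > 2L)
    for (t in 2:(n - 1L)) m[t, ] <- c(n + t - 1L, leaves[t + 1L])
  linkage_matrix(cbind(m, heights, seq_len(n - 1L) + 1L))
}

# apply Omega at every row whose bit is set in mask (bit t-1 <-> row t)
swap_mask <- function(Z, mask) {
  for (t in seq_len(nrow(Z$merge)))
    if (bitwAnd(mask, bitwShiftL(1L, t - 1L)) != 0L)
      Z$merge[t, ] <- Z$merge[t, 2:1]
  Z
}
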