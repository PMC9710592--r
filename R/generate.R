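#' Generate a synthetic random tanglegram
#'
#' Emulates the experimental inputs of the study this package implements:
#' pairs of dendrograms obtained by clustering the same random point set
#' with two different linkage rules, so the two trees are related but not
#' identical.
#'
#' `mode = "clustered"` draws `n_leaves` points from a standard multivariate
#' normal in `n_features` dimensions and pairs the single-linkage tree
#' (left) with the complete-linkage tree (right) of their Euclidean
#' distances, via [stats::hclust()]. `mode = "random-topology"` instead
#' builds two independent uniformly random merge sequences (repeatedly
#' merging two active clusters chosen at random, with the merge step index
#' as height) — useful because the untanglers only ever see topology, so
#' the data source behind the trees is immaterial.
#'
#' @param n_leaves number of leaves, at least 2.
#' @param mode `"clustered"` (default) or `"random-topology"`; see above.
#' @param n_features dimensionality of the clustered point cloud
#'   (default 5).
#' @param seed optional integer; when given, the generator is reproducible
#'   and the caller's RNG state is left untouched.
#' @param labels optional leaf labels passed to [tanglegram()].
#' @return A [tanglegram()].
#' @examples
#' L <- generate_tanglegram(10, seed = 1)
#' entanglement(L)
#' @export
generate_tanglegram <- function(n_leaves, mode = c("clustered", "random-topology"),
                                n_features = 5L, seed = NULL, labels = NULL) {
  mode <- match.arg(mode)
  if (length(n_leaves) != 1L || is.na(n_leaves) || n_leaves < 2L)
    stop("n_leaves must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n_leaves)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  if (mode == "clustered") {
    x <- matrix(rnorm(n * n_features), nrow = n)
    d <- dist(x)
    left <- hclust_to_linkage(hclust(d, method = "single"))
    right <- hclust_to_linkage(hclust(d, method = "complete"))
  } else {
    left <- random_topology_linkage(n)
    right <- random_topology_linkage(n)
  }
  tanglegram(left, right, labels)
}

#' Convert an hclust object to a linkage matrix
#'
#' Maps the signed hclust merge encoding (negative = leaf, positive =
#' earlier merge row) onto this package's node numbering (leaves `1..n`,
#' row `t` creating node `n + t`), keeping child order, heights and sizes.
#'
#' @param h an object of class `hclust`.
#' @return A `linkage_matrix`.
#' @export
hclust_to_linkage <- function(h) {
  stopifnot(inherits(h, "hclust"))
  n <- nrow(h$merge) + 1L
  conv <- function(x) ifelse(x < 0, -x, x + n)
  m <- cbind(conv(h$merge[, 1L]), conv(h$merge[, 2L]))
  sz <- c(rep(1L, n), rep(NA_integer_, n - 1L))
  for (t in seq_len(n - 1L)) sz[n + t] <- sz[m[t, 1L]] + sz[m[t, 2L]]
  linkage_matrix(cbind(m, pmax(h$height, 0), sz[n + seq_len(n - 1L)]))
}

random_topology_linkage <- function(n) {
  active <- seq_len(n)
  m <- matrix(0L, n - 1L, 2L)
  sz <- rep(1L, 2L * n - 1L)
  for (t in seq_len(n - 1L)) {
    pick <- sample.int(length(active), 2L)
    m[t, ] <- active[pick]
    sz[n + t] <- sz[m[t, 1L]] + sz[m[t, 2L]]
    active <- c(active[-pick], n + t)
  }
  linkage_matrix(cbind(m, seq_len(n - 1L), sz[n + seq_len(n - 1L)]))
}

fixture_cache <- new.env(parent = emptyenv())

#' Worked tanglegram fixtures
#'
#' A named list of small instances used throughout the documentation and
#' tests:
#'
#' * `eq1` — the four-leaf toy linkage matrix
#'   `[[1,2,0.3,2], [3,5,0.2,3], [4,6,0.7,4]]` (a `linkage_matrix`, not a
#'   tanglegram), whose induced leaf order is `4 3 1 2`.
#' * `eq1_self` — `eq1` paired with itself (entanglement 0).
#' * `eq1_rootswap` — `eq1` paired with its root-rotated variant.
#' * `step2side_trap` — a three-leaf tanglegram on which [step2side()]
#'   terminates with crossings left, although every pair of three-leaf
#'   trees admits a zero-crossing layout; found by exhaustive search over
#'   all ordered three-leaf tree pairs. The coordinated untanglers all
#'   untangle it completely.
#' * `asym_gain` — an instance (found by seeded search over random
#'   topologies) on which the [asymmetric_pass()] strictly improves the
#'   fixed point of the depth-1 [symmetric_sweep()].
#'
#' The searched fixtures are recomputed deterministically on first use and
#' cached for the session.
#'
#' @return Named list as described above.
#' @export
tanglegram_fixtures <- function() {
  eq1 <- linkage_matrix(rbind(
    c(1, 2, 0.3, 2),
    c(3, 5, 0.2, 3),
    c(4, 6, 0.7, 4)))
  list(
    eq1 = eq1,
    eq1_self = tanglegram(eq1, eq1),
    eq1_rootswap = tanglegram(eq1, swap_omega(eq1, 3)),
    step2side_trap = find_step2side_trap(),
    asym_gain = find_asym_gain()
  )
}

# exhaustive search over all ordered pairs of 3-leaf dendrograms for one on
# which step2side stalls above zero crossings
find_step2side_trap <- function() {
  if (!is.null(fixture_cache$trap)) return(fixture_cache$trap)
  shapes <- all_dendrograms(3L)
  ordered <- list()
  for (z in shapes)
    for (mask in 0:3)
      ordered[[length(ordered) + 1L]] <- swap_mask(z, mask)
  for (zl in ordered) {
    for (zr in ordered) {
      L <- tanglegram(zl, zr)
      if (step2side(L)$crossings > 0L) {
        fixture_cache$trap <- L
        return(L)
      }
    }
  }
  stop("internal error: no step2side trap found among 3-leaf instances")
}

# seeded search for an instance where the asymmetric pass beats the
# symmetric sweep's fixed point
find_asym_gain <- function() {
  if (!is.null(fixture_cache$asym)) return(fixture_cache$asym)
  cfg <- entanglement_config()
  for (n in 6:8) {
    for (s in 1:300) {
      L <- generate_tanglegram(n, mode = "random-topology", seed = s)
      swept <- symmetric_sweep(L, m = 1L, cfg)
      e1 <- entanglement(swept, cfg)
      if (e1 <= cfg$tol) next
      e2 <- entanglement(asymmetric_pass(swept, cfg), cfg)
      if (e2 < e1 - cfg$tol) {
        fixture_cache$asym <- L
        return(L)
      }
    }
  }
  stop("internal error: no asymmetric-gain instance found in the searched range")
}
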