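# Independent reference implementations used as oracles: plain recursive R,
# no shared code with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_leaf_order <- function(Z) {
  n <- Z$n_leaves
  rec <- function(node) {
    if (node <= n) return(node)
    t <- node - n
    c(rec(Z$merge[t, 1]), rec(Z$merge[t, 2]))
  }
  rec(2L * n - 1L)
}

# leaves under a given node, as a set
ref_leafset <- function(Z, node) {
  n <- Z$n_leaves
  if (node <= n) return(node)
  t <- node - n
  sort(c(ref_leafset(Z, Z$merge[t, 1]), ref_leafset(Z, Z$merge[t, 2])))
}

ref_power_sum <- function(ol, orr, p = 2) {
  sum(abs(seq_along(ol) - match(ol, orr))^p)
}

ref_worst_sum <- function(n, p = 2) sum(abs(2 * seq_len(n) - n - 1)^p)

ref_entanglement <- function(L, p = 2) {
  ol <- ref_leaf_order(L$left)
  orr <- ref_leaf_order(L$right)
  ref_power_sum(ol, orr, p) / ref_worst_sum(length(ol), p)
}

# brute-force O(n^2) inversion count
ref_inversions <- function(perm) {
  n <- length(perm)
  s <- 0L
  for (a in seq_len(n - 1L))
    for (b in (a + 1L):n)
      if (perm[a] > perm[b]) s <- s + 1L
  s
}

# every leaf order reachable by child swaps, via recursive enumeration
ref_all_orders <- function(Z) {
  n <- Z$n_leaves
  rec <- function(node) {
    if (node <= n) return(list(node))
    t <- node - n
    A <- rec(Z$merge[t, 1])
    B <- rec(Z$merge[t, 2])
    out <- vector("list", 2L * length(A) * length(B))
    i <- 0L
    for (a in A) for (b in B) {
      out[[i + 1L]] <- c(a, b)
      out[[i + 2L]] <- c(b, a)
      i <- i + 2L
    }
    out
  }
  rec(2L * n - 1L)
}

rand_tg <- function(n, seed, mode = "random-topology") {
  generate_tanglegram(n, mode = mode, seed = seed)
}

# relabel leaves by permutation sigma on both sides (sigma[old] = new)
relabel_tg <- function(L, sigma) {
  n <- n_leaves(L)
  map_side <- function(Z) {
    m <- Z$merge
    m[m <= n] <- sigma[m[m <= n]]
    Z$merge <- m
    Z
  }
  tanglegram(map_side(L$left), map_side(L$right))
}

# all ordered 3-leaf dendrograms (3 shapes x 4 child orderings)
all_ordered_3leaf <- function() {
  out <- list()
  for (z in all_dendrograms(3)) {
    for (mask in 0:3) {
      zz <- z
      for (t in 1:2)
        if (bitwAnd(mask, bitwShiftL(1L, t - 1L)) != 0L)
          zz$merge[t, ] <- zz$merge[t, 2:1]
      out[[length(out) + 1L]] <- zz
    }
  }
  out
}
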