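#' The four-layout shuffle of a tanglegram
#'
#' Returns, in this fixed order, the unmodified tanglegram, the tanglegram
#' with the left tree rotated at vertex `i`, with the right tree rotated at
#' vertex `j`, and with both rotations applied. This quad is the elementary
#' move of the shuffled-restart untanglers ([shuf_s2s()], [shuntan()]); the
#' symmetric case `i == j` is the move of the symmetric sweep.
#'
#' @param L a [tanglegram()].
#' @param i,j merge-row indices in `1..n-1` (left and right tree
#'   respectively; `j` defaults to `i`).
#' @return List of 4 tanglegrams, first element identical to `L`.
#' @export
shuffle_quad <- function(L, i, j = i) {
  stopifnot(inherits(L, "tanglegram"))
  nr <- n_leaves(L) - 1L
  for (idx in c(i, j))
    if (length(idx) != 1L || is.na(idx) || idx < 1L || idx > nr)
      stop(sprintf("shuffle indices must be in 1..%d", nr), call. = FALSE)
  list(
    L,
    tanglegram(swap_omega(L$left, i), L$right, L$labels),
    tanglegram(L$left, swap_omega(L$right, j), L$labels),
    tanglegram(swap_omega(L$left, i), swap_omega(L$right, j), L$labels)
  )
}

#' The stepBothSides untangler
#'
#' Extends [step2side()] with a coordinated two-sided move. Step 1 runs
#' step2side to convergence. Step 2 scans all pairs `(i, j)` in
#' `[1, n-1]^2`, replacing the incumbent with
#' `[Omega_i(Z_l), Omega_j(Z_r)]` whenever that strictly lowers the
#' entanglement (first improvement; the scan continues against the updated
#' incumbent). Step 3 repeats both until neither reduces the entanglement.
#' The pair scan is what lets the search leave the one-sided local optima
#' where step2side stalls, at `O(n^2)` evaluations per round instead of
#' `O(n)`.
#'
#' @inheritParams step2side
#' @return An `untangle_result`; see [step2side()]. Its output entanglement
#'   never exceeds step2side's on the same input.
#' @export
step_both_sides <- function(L, cfg = entanglement_config()) {
  stopifnot(inherits(L, "tanglegram"))
  cfg <- as_cfg(cfg)
  res <- cpp_step_both_sides(L$left$merge, L$right$merge, n_leaves(L), cfg$p, cfg$tol)
  make_untangle_result(L, res, "stepBothSides", cfg,
                       trace_extra = list(passes = res$passes,
                                          outer_rounds = res$outer))
}

#' Symmetric sweep: rotate both trees together, leaves toward root
#'
#' Repeatedly applies `L <- xi(mu_i(L))` for `i = 1, 2, ..., n - m - 1`,
#' where `mu_i` rotates vertex `i` on the left, on the right, or on both
#' (see [shuffle_quad()]) and `xi` keeps the least-entangled of the four.
#' The full sequence is iterated until a sweep produces no reduction. The
#' sweep runs opposite to the shuffle schedule of [shuntan()]: shuffling
#' works from the root down `m` vertices, this optimizer works from the
#' leaves up through the remaining `n - m - 1`.
#'
#' @param L a [tanglegram()].
#' @param m shuffle depth determining the sweep range, `1 <= m <= n - 2`.
#' @param cfg an [entanglement_config()].
#' @return The swept `tanglegram`, entanglement never above the input's.
#' @export
symmetric_sweep <- function(L, m, cfg = entanglement_config()) {
  stopifnot(inherits(L, "tanglegram"))
  cfg <- as_cfg(cfg)
  n <- n_leaves(L)
  if (length(m) != 1L || is.na(m) || m < 1L || m > n - 2L)
    stop(sprintf("m must be in 1..%d", n - 2L), call. = FALSE)
  res <- cpp_symmetric_sweep(L$left$merge, L$right$merge, n, as.integer(m),
                             cfg$p, cfg$tol)
  tg_with_merges(L, res$left, res$right)
}

#' Asymmetric pass: per-leaf two-sided rotations
#'
#' For every leaf `k = 1..n`, locates the rows holding `k` on each side
#' (`tau(k, Z_l)`, `tau(k, Z_r)` — generally different) and keeps the best
#' of the quad `mu_{tau(k,Z_l), tau(k,Z_r)}(L)`. The scan over all leaves
#' repeats until one full iteration leaves the layout unchanged. Because the
#' paired rows need not match, this move reaches layouts the symmetric
#' sweep cannot, and it can strictly improve a symmetric-sweep fixed point
#' (see [tanglegram_fixtures()]`$asym_gain`).
#'
#' @inheritParams step2side
#' @return The improved `tanglegram`, entanglement never above the input's.
#' @export
asymmetric_pass <- function(L, cfg = entanglement_config()) {
  stopifnot(inherits(L, "tanglegram"))
  cfg <- as_cfg(cfg)
  res <- cpp_asymmetric_pass(L$left$merge, L$right$merge, n_leaves(L),
                             cfg$p, cfg$tol)
  tg_with_merges(L, res$left, res$right)
}

# Shared shuffle schedule of shufS2S and ShUnTan. `optimize` maps a pair of
# merge tables to list(left, right, entanglement, evaluations) for the
# current depth m. Candidate sets are built from the *unoptimized* sets of
# the previous generation; optimized layouts are never fed back in.
run_shuffled_search <- function(L, cfg, m_cutoff, optimize, method) {
  n <- n_leaves(L)
  if (is.null(m_cutoff)) m_cutoff <- n - 1L
  if (length(m_cutoff) != 1L || is.na(m_cutoff) || m_cutoff < 1L)
    stop("m_cutoff must be a single integer >= 1", call. = FALSE)
  m_cutoff <- min(as.integer(m_cutoff), n - 1L)

  m0 <- tg_metrics(L, cfg$p)
  best <- list(left = L$left$merge, right = L$right$merge,
               entanglement = m0$power_sum / m0$worst_sum)
  evals <- 0
  set_sizes <- integer(0)
  best_by_m <- numeric(0)
  m_reached <- 0L

  if (best$entanglement > cfg$tol) {
    ini <- list(list(l = L$left$merge, r = L$right$merge))
    for (m in seq_len(m_cutoff)) {
      v <- n - m  # shuffle the (n-m)th interior vertex: root first, then down
      expanded <- vector("list", 4L * length(ini))
      pos <- 0L
      for (cand in ini) {
        l2 <- cand$l; l2[v, ] <- l2[v, 2:1]
        r2 <- cand$r; r2[v, ] <- r2[v, 2:1]
        expanded[[pos + 1L]] <- cand
        expanded[[pos + 2L]] <- list(l = l2, r = cand$r)
        expanded[[pos + 3L]] <- list(l = cand$l, r = r2)
        expanded[[pos + 4L]] <- list(l = l2, r = r2)
        pos <- pos + 4L
      }
      keys <- vapply(expanded, function(x) paste(c(x$l, x$r), collapse = ","), "")
      ini <- expanded[!duplicated(keys)]
      m_reached <- m
      set_sizes <- c(set_sizes, length(ini))

      gen_best <- NULL
      for (cand in ini) {
        opt <- optimize(cand$l, cand$r, m)
        evals <- evals + opt$evaluations
        if (is.null(gen_best) || opt$entanglement < gen_best$entanglement)
          gen_best <- opt
      }
      best_by_m <- c(best_by_m, gen_best$entanglement)
      if (gen_best$entanglement < best$entanglement - cfg$tol) {
        best <- gen_best
        if (best$entanglement <= cfg$tol) break  # target layout reached
      } else break  # increasing m brought no improvement
    }
  }

  out_tg <- tg_with_merges(L, best$left, best$right)
  structure(list(
    tanglegram = out_tg,
    entanglement = eps_on_scale(best$entanglement, cfg),
    crossings = crossings(out_tg),
    method = method,
    trace = structure(list(
      evaluations = evals,
      m_reached = m_reached,
      set_sizes = set_sizes,
      best_by_m = eps_on_scale(best_by_m, cfg)
    ), class = "sweep_trace")
  ), class = "untangle_result")
}

#' The shufS2S untangler (shuffle, then step2side)
#'
#' Shuffled-restart scheme around [step2side()]. Starting from
#' `L_ini(0) = {L}`, generation `m` shuffles every member of the previous
#' (unoptimized) generation at the `(n - m)`th interior vertex — the root
#' first, then stepwise away from it — via the four-layout move of
#' [shuffle_quad()], giving up to `4^m` layouts (duplicates are pruned;
#' this cannot change the selected optimum). Each layout is optimized by
#' step2side and the generation's best is compared with the best found so
#' far: the search stops when a deeper shuffle brings no improvement, when
#' the entanglement reaches zero, or at the depth cutoff.
#'
#' @inheritParams step2side
#' @param m_cutoff optional maximum shuffle depth (default: no cutoff, i.e.
#'   `n - 1`); caps the exponentially growing candidate sets.
#' @return An `untangle_result` whose trace records `m_reached`,
#'   `set_sizes` (candidate-set size per generation) and `best_by_m`.
#' @export
shuf_s2s <- function(L, cfg = entanglement_config(), m_cutoff = NULL) {
  stopifnot(inherits(L, "tanglegram"))
  cfg <- as_cfg(cfg)
  n <- n_leaves(L)
  run_shuffled_search(L, cfg, m_cutoff, method = "shufS2S",
    optimize = function(ml, mr, m) {
      res <- cpp_step2side(ml, mr, n, cfg$p, cfg$tol)
      list(left = res$left, right = res$right,
           entanglement = res$entanglement,
           evaluations = res$evaluations)
    })
}

#' The ShUnTan untangler (shuffle and untangle)
#'
#' Same shuffle schedule as [shuf_s2s()], but each shuffled layout is
#' optimized by the two-stage untangler instead of step2side: the
#' [symmetric_sweep()] at depth `m` (rotating both trees together from the
#' leaves up through the `n - m - 1` vertices the shuffle did not touch),
#' followed by the [asymmetric_pass()] (per-leaf two-sided rotations, which
#' scan all leaves regardless of `m`). The best optimized layout of each
#' generation joins the candidate pool, and termination is as in shufS2S:
#' zero entanglement (the target layout), no improvement from a deeper
#' shuffle, or the depth cutoff.
#'
#' @inheritParams shuf_s2s
#' @return An `untangle_result`; see [shuf_s2s()].
#' @export
shuntan <- function(L, cfg = entanglement_config(), m_cutoff = NULL) {
  stopifnot(inherits(L, "tanglegram"))
  cfg <- as_cfg(cfg)
  n <- n_leaves(L)
  run_shuffled_search(L, cfg, m_cutoff, method = "ShUnTan",
    optimize = function(ml, mr, m) {
      res <- cpp_shuntan_optimize(ml, mr, n, m, cfg$p, cfg$tol)
      list(left = res$left, right = res$right,
           entanglement = res$entanglement,
           evaluations = res$evaluations)
    })
}

#' Run an untangler by name
#'
#' Dispatcher over the four untangling algorithms.
#'
#' @param L a [tanglegram()].
#' @param method one of `"step2side"`, `"stepbothsides"`, `"shufs2s"`,
#'   `"shuntan"` (case-insensitive).
#' @param cfg an [entanglement_config()].
#' @param m_cutoff optional shuffle-depth cutoff, used by the two shuffled
#'   methods and ignored otherwise.
#' @return An `untangle_result`.
#' @export
untangle <- function(L, method = c("step2side", "stepbothsides", "shufs2s", "shuntan"),
                     cfg = entanglement_config(), m_cutoff = NULL) {
  method <- match.arg(tolower(method[1L]),
                      c("step2side", "stepbothsides", "shufs2s", "shuntan"))
  switch(method,
    step2side = step2side(L, cfg),
    stepbothsides = step_both_sides(L, cfg),
    shufs2s = shuf_s2s(L, cfg, m_cutoff),
    shuntan = shuntan(L, cfg, m_cutoff))
}
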