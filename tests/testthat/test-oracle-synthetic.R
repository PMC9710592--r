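test_that("two-leaf tanglegrams are always drawable", {
  Z <- comb_linkage(1:2)
  Zs <- comb_linkage(2:1)
  for (pair in list(list(Z, Z), list(Z, Zs), list(Zs, Z))) {
    res <- brute_force_optimum(tanglegram(pair[[1]], pair[[2]]))
    expect_identical(res$min_crossings, 0L)
    expect_equal(res$min_entanglement, 0)
    expect_equal(res$layouts_evaluated, 4)
  }
})

test_that("the oracle refuses oversized instances with guidance", {
  expect_error(brute_force_optimum(rand_tg(12, 1)), "max_leaves")
})

test_that("the oracle agrees with an independent enumeration of reachable orders", {
  for (n in 3:5) {
    for (s in 1:6) {
      L <- rand_tg(n, s)
      res <- brute_force_optimum(L)
      ords_l <- ref_all_orders(L$left)
      ords_r <- ref_all_orders(L$right)
      best <- Inf
      minx <- Inf
      for (ol in ords_l) for (orr in ords_r) {
        best <- min(best, ref_power_sum(ol, orr) / ref_worst_sum(n))
        minx <- min(minx, ref_inversions(match(ol, orr)))
      }
      expect_equal(res$min_entanglement, best)
      expect_identical(res$min_crossings, as.integer(minx))
      expect_equal(res$layouts_evaluated, 4^(n - 1))
    }
  }
})

test_that("the argmin layout attains the reported minimum", {
  for (s in 1:8) {
    L <- rand_tg(6, s, mode = "clustered")
    res <- brute_force_optimum(L)
    expect_equal(entanglement(res$argmin_layout), res$min_entanglement)
  }
})

test_that("oracle entanglement lower-bounds every heuristic", {
  for (s in 1:15) {
    L <- rand_tg(8, s, mode = "clustered")
    opt <- brute_force_optimum(L)$min_entanglement
    for (f in list(step2side, step_both_sides, shuf_s2s, shuntan))
      expect_gte(f(L)$entanglement, opt - 1e-9)
  }
})

test_that("topology enumeration yields the double-factorial counts", {
  expect_length(all_dendrograms(2), 1)
  expect_length(all_dendrograms(3), 3)
  expect_length(all_dendrograms(4), 15)
  expect_length(all_dendrograms(5), 105)
  for (Z in all_dendrograms(4)) expect_length(validate_linkage(Z), 0)
  keys <- vapply(all_dendrograms(4), function(z)
    paste(sort(vapply(5:7, function(k) paste(ref_leafset(z, k), collapse = "."), "")),
          collapse = "|"), "")
  expect_identical(anyDuplicated(keys), 0L)  # all shapes distinct as unordered trees
})

test_that("the generator is seeded, valid, and produces varied instances", {
  a <- generate_tanglegram(20, seed = 11)
  b <- generate_tanglegram(20, seed = 11)
  expect_identical(a$left$merge, b$left$merge)
  expect_identical(a$right$merge, b$right$merge)
  expect_identical(a$left$height, b$left$height)
  c1 <- generate_tanglegram(20, mode = "random-topology", seed = 11)
  c2 <- generate_tanglegram(20, mode = "random-topology", seed = 11)
  expect_identical(c1$left$merge, c2$left$merge)
  for (s in 1:5) {
    g <- generate_tanglegram(15, seed = s)
    expect_length(validate_linkage(g$left), 0)
    expect_length(validate_linkage(g$right), 0)
    g2 <- generate_tanglegram(15, mode = "random-topology", seed = s)
    expect_length(validate_linkage(g2$left), 0)
  }
  eps <- vapply(1:100, function(s) entanglement(generate_tanglegram(20, seed = s)),
                numeric(1))
  expect_gt(length(unique(round(eps, 10))), 10)
  expect_error(generate_tanglegram(1), "n_leaves")
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_tanglegram(10, seed = 77))
  expect_identical(runif(1), before)
})

test_that("the shipped fixtures are valid and have their stated properties", {
  fx <- tanglegram_fixtures()
  expect_identical(as.matrix(fx$eq1),
                   cbind(c(1, 3, 4), c(2, 5, 6), c(0.3, 0.2, 0.7), c(2, 3, 4)))
  expect_equal(entanglement(fx$eq1_self), 0)
  expect_length(validate_linkage(fx$eq1), 0)
  for (tg in fx[c("eq1_self", "eq1_rootswap", "step2side_trap", "asym_gain")]) {
    expect_length(validate_linkage(tg$left), 0)
    expect_length(validate_linkage(tg$right), 0)
  }
  expect_gt(step2side(fx$step2side_trap)$crossings, 0L)
  expect_identical(brute_force_optimum(fx$step2side_trap)$min_crossings, 0L)
})
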