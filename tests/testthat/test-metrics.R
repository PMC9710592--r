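test_that("displacement matches hand-computed cases", {
  Z4 <- comb_linkage(1:4)
  expect_equal(as.numeric(displacement(tanglegram(Z4, Z4))), 0)
  rev4 <- tanglegram(Z4, comb_linkage(4:1))
  expect_equal(attr(displacement(rev4), "power_sum"), 20)  # 9 + 1 + 1 + 9
  expect_equal(as.numeric(displacement(rev4)), sqrt(20))
  swapped3 <- tanglegram(comb_linkage(1:3), comb_linkage(c(1, 3, 2)))
  expect_equal(attr(displacement(swapped3), "power_sum"), 2)
})

test_that("entanglement endpoints and the n = 3 ratio are exact", {
  expect_equal(entanglement(tanglegram(comb_linkage(1:5), comb_linkage(1:5))), 0)
  expect_equal(entanglement(tanglegram(comb_linkage(1:5), comb_linkage(5:1))), 1)
  swapped3 <- tanglegram(comb_linkage(1:3), comb_linkage(c(1, 3, 2)))
  expect_equal(entanglement(swapped3), 2 / 8)
  expect_equal(entanglement(swapped3, entanglement_config(mode = "norm-ratio")),
               sqrt(2 / 8))
})

test_that("entanglement lies in [0,1] and vanishes exactly when crossings do", {
  # exhaustive over every layout of every 3-leaf tree pair
  trees <- all_ordered_3leaf()
  for (zl in trees) for (zr in trees) {
    L <- tanglegram(zl, zr)
    e <- entanglement(L)
    x <- crossings(L)
    expect_gte(e, 0)
    expect_lte(e, 1)
    expect_identical(e == 0, x == 0L)
  }
  for (s in 1:30) {
    L <- rand_tg(15, s)
    e <- entanglement(L)
    expect_gte(e, 0)
    expect_lte(e, 1)
    expect_identical(e == 0, crossings(L) == 0L)
  }
})

test_that("crossing counts agree with the brute-force pair count", {
  Z4 <- comb_linkage(1:4)
  expect_identical(crossings(tanglegram(Z4, Z4)), 0L)
  expect_identical(crossings(tanglegram(Z4, comb_linkage(4:1))), 6L)
  # pi = (2, 4, 1, 3) has 3 inversions
  expect_identical(crossings(tanglegram(comb_linkage(c(3, 1, 4, 2)), Z4)), 3L)
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    L <- tanglegram(comb_linkage(sample(n)), comb_linkage(sample(n)))
    pi <- match(leaf_order(L$left), leaf_order(L$right))
    expect_identical(crossings(L), ref_inversions(pi))
  }
})

test_that("the two entanglement modes rank layouts identically", {
  cfg_p <- entanglement_config(mode = "power-ratio")
  cfg_n <- entanglement_config(mode = "norm-ratio")
  eps_p <- eps_n <- numeric(40)
  for (s in 1:40) {
    L <- rand_tg(12, s)
    eps_p[s] <- entanglement(L, cfg_p)
    eps_n[s] <- entanglement(L, cfg_n)
  }
  expect_identical(order(eps_p), order(eps_n))
  expect_equal(eps_n, eps_p^(1 / 2))
})

test_that("entanglement is invariant under relabelling and mirroring", {
  for (s in 1:10) {
    L <- rand_tg(10, s)
    e <- entanglement(L)
    sigma <- sample(10)
    expect_equal(entanglement(relabel_tg(L, sigma)), e)
    M <- mirror_tanglegram(L)
    expect_equal(entanglement(M), e)
    expect_identical(crossings(M), crossings(L))
  }
})

test_that("select_best is the first-listed argmin and rejects empty input", {
  Z <- comb_linkage(1:4)
  a <- tanglegram(Z, comb_linkage(c(3, 1, 2, 4)))  # some entanglement
  b <- tanglegram(Z, comb_linkage(c(1, 2, 4, 3)))  # tied pair below
  stopifnot(entanglement(a) > entanglement(b))
  picked <- select_best(list(a, b, b))
  expect_identical(picked, b)
  # tie between positions 2 and 3: position 2 wins (identical object anyway)
  expect_identical(select_best(list(a)), a)
  expect_identical(select_best(list(b, a)), b)
  expect_error(select_best(list()), "non-empty")
})

test_that("metric reports serialize to JSON with all fields", {
  L <- tanglegram(comb_linkage(1:4), comb_linkage(c(2, 1, 4, 3)))
  rep <- metric_report(L)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_metric_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$entanglement, rep$entanglement)
  expect_equal(back$crossings, rep$crossings)
  expect_identical(back$mode, "power-ratio")
})
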