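test_that("shuffle_quad returns the four layouts of the definition, in order", {
  L <- rand_tg(8, 1)
  q <- shuffle_quad(L, 3, 5)
  expect_length(q, 4)
  expect_identical(q[[1]]$left$merge, L$left$merge)
  expect_identical(q[[1]]$right$merge, L$right$merge)
  expect_identical(q[[2]]$left$merge, swap_omega(L$left, 3)$merge)
  expect_identical(q[[3]]$right$merge, swap_omega(L$right, 5)$merge)
  expect_identical(q[[4]]$left$merge, swap_omega(L$left, 3)$merge)
  expect_identical(q[[4]]$right$merge, swap_omega(L$right, 5)$merge)
  # pairwise distinct as ordered matrices
  keys <- vapply(q, function(x) paste(c(x$left$merge, x$right$merge), collapse = ","), "")
  expect_identical(anyDuplicated(keys), 0L)
  # the double swap is an involution
  back <- shuffle_quad(q[[4]], 3, 5)[[4]]
  expect_identical(back$left$merge, L$left$merge)
  expect_identical(back$right$merge, L$right$merge)
  expect_error(shuffle_quad(L, 0, 3), "indices")
  expect_error(shuffle_quad(L, 1, 8), "indices")
})

test_that("stepBothSides untangles every 3-leaf tanglegram completely", {
  trees <- all_ordered_3leaf()
  for (zl in trees) for (zr in trees) {
    res <- step_both_sides(tanglegram(zl, zr))
    expect_identical(res$crossings, 0L)
    expect_equal(res$entanglement, 0)
  }
})

test_that("stepBothSides dominates step2side and admits no improving pair", {
  for (s in 1:8) {
    L <- rand_tg(8, s, mode = "clustered")
    e_sbs <- step_both_sides(L)$entanglement
    expect_lte(e_sbs, step2side(L)$entanglement + 1e-12)
    out <- step_both_sides(L)$tanglegram
    e <- entanglement(out)
    for (i in 1:7) for (j in 1:7) {
      cand <- tanglegram(swap_omega(out$left, i), swap_omega(out$right, j))
      expect_gte(entanglement(cand), e - 1e-12)
    }
  }
})

test_that("the shuffled searches terminate immediately on a crossing-free input", {
  Z <- rand_tg(9, 2)$left
  L <- tanglegram(Z, Z)
  for (f in list(shuf_s2s, shuntan)) {
    res <- f(L)
    expect_equal(res$entanglement, 0)
    expect_identical(res$trace$m_reached, 0L)
    expect_identical(res$trace$evaluations, 0)
  }
})

test_that("shufS2S and ShUnTan untangle the step2side trap", {
  trap <- tanglegram_fixtures()$step2side_trap
  expect_identical(shuf_s2s(trap)$crossings, 0L)
  expect_identical(shuntan(trap)$crossings, 0L)
})

test_that("candidate sets grow fourfold per shuffle generation", {
  hits <- 0L
  for (s in 1:30) {
    res <- shuf_s2s(rand_tg(10, s, mode = "clustered"))
    m <- res$trace$m_reached
    if (m >= 1) {
      expect_identical(res$trace$set_sizes, as.integer(4^seq_len(m)))
      hits <- hits + 1L
    }
  }
  expect_gt(hits, 0L)
})

test_that("the symmetric sweep never increases entanglement and reaches a fixed point", {
  for (s in 1:10) {
    L <- rand_tg(8, s)
    e0 <- entanglement(L)
    swept <- symmetric_sweep(L, m = 1)
    e1 <- entanglement(swept)
    expect_lte(e1, e0 + 1e-12)
    again <- symmetric_sweep(swept, m = 1)
    expect_identical(again$left$merge, swept$left$merge)
    expect_identical(again$right$merge, swept$right$merge)
  }
  expect_error(symmetric_sweep(rand_tg(8, 1), m = 0), "m must be")
  expect_error(symmetric_sweep(rand_tg(8, 1), m = 7), "m must be")
})

test_that("the asymmetric pass can improve a symmetric-sweep fixed point", {
  L <- tanglegram_fixtures()$asym_gain
  swept <- symmetric_sweep(L, m = 1)
  e_sym <- entanglement(swept)
  e_asym <- entanglement(asymmetric_pass(swept))
  expect_lt(e_asym, e_sym)
  # and the pass itself never increases entanglement
  for (s in 1:10) {
    L <- rand_tg(8, s)
    expect_lte(entanglement(asymmetric_pass(L)), entanglement(L) + 1e-12)
  }
})

test_that("every method improves on the input and the novel ones on step2side", {
  for (n in c(6, 10, 20)) {
    for (s in 1:12) {
      L <- rand_tg(n, s, mode = "clustered")
      e0 <- entanglement(L)
      e_s2s <- step2side(L)$entanglement
      for (f in list(step_both_sides, shuf_s2s, shuntan)) {
        e <- f(L)$entanglement
        expect_lte(e, e0 + 1e-12)
        expect_lte(e, e_s2s + 1e-12)
      }
    }
  }
})

test_that("all methods are deterministic and mirror-equivariant", {
  runs <- list(
    function(L) step2side(L),
    function(L) step_both_sides(L),
    function(L) shuf_s2s(L),
    function(L) shuntan(L)
  )
  for (s in 1:4) {
    L <- rand_tg(10, s, mode = "clustered")
    M <- mirror_tanglegram(L)
    for (f in runs) {
      a <- f(L)
      b <- f(L)
      expect_identical(a$tanglegram$left$merge, b$tanglegram$left$merge)
      expect_identical(a$tanglegram$right$merge, b$tanglegram$right$merge)
      expect_identical(a$trace$evaluations, b$trace$evaluations)
      rm <- f(M)
      expect_equal(rm$entanglement, a$entanglement)
      mm <- mirror_tanglegram(rm$tanglegram)
      expect_identical(mm$left$merge, a$tanglegram$left$merge)
      expect_identical(mm$right$merge, a$tanglegram$right$merge)
    }
  }
})

test_that("on all 3-leaf instances every novel method reaches zero crossings", {
  trees <- all_ordered_3leaf()
  s2s_fails <- 0L
  for (zl in trees) for (zr in trees) {
    L <- tanglegram(zl, zr)
    if (step2side(L)$crossings > 0L) s2s_fails <- s2s_fails + 1L
    expect_identical(step_both_sides(L)$crossings, 0L)
    expect_identical(shuf_s2s(L)$crossings, 0L)
    expect_identical(shuntan(L)$crossings, 0L)
  }
  expect_gt(s2s_fails, 0L)
})

test_that("the dispatcher routes by name and rejects unknown methods", {
  L <- rand_tg(8, 5)
  expect_identical(untangle(L, "step2side")$method, "step2side")
  expect_identical(untangle(L, "ShUnTan")$method, "ShUnTan")
  expect_error(untangle(L, "dendser"))
  expect_error(shuf_s2s(L, m_cutoff = 0), "m_cutoff")
  res <- shuf_s2s(L, m_cutoff = 1)
  expect_lte(res$trace$m_reached, 1L)
})
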