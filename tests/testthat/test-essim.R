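test_that("equal splits halves edge contributions at every split", {
  expect_equal(unname(equal_splits(tree2())), c(1, 1))
  es <- equal_splits(tree3())
  expect_equal(es[["A"]], 1.5)
  expect_equal(es[["B"]], 1.5)
  expect_equal(es[["C"]], 2)
  bal4 <- read_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
  expect_true(all(abs(equal_splits(bal4) - 1.5) < 1e-12))
})

test_that("each edge's length is fully apportioned among descendant tips", {
  # conservation: summing ES over tips re-spends every edge exactly once
  for (seed in 1:5) {
    tr <- sim_yule_tree(sample(5:15, 1), 0.4, seed = seed)
    es <- equal_splits(tr)
    # sum over tips of ES equals sum over edges of len (each edge's
    # contributions over its descendant tips telescope to len)
    expect_equal(sum(es), total_branch_length(tr), tolerance = 1e-9)
  }
})

test_that("ES-sim statistics behave as a correlation test should", {
  tr <- sim_yule_tree(31, 0.12, seed = 61)
  stat <- log(1 / equal_splits(tr))
  self <- essim_test(tr, stats::setNames(stat, names(stat)), nsim = 300,
                     seed = 1)
  expect_equal(self$rho, 1)
  expect_equal(self$p_value, 1 / 301)

  x <- sim_bm_trait(tr, 5, seed = 62)
  r <- essim_test(tr, x, nsim = 300, seed = 2)
  expect_true(abs(r$rho) <= 1)
  expect_equal(length(r$null_rhos), 300L)
  # affine trait transformation leaves rho and p unchanged
  r2 <- essim_test(tr, 3 * x + 7, nsim = 300, seed = 2)
  expect_equal(r2$rho, r$rho, tolerance = 1e-12)
  expect_equal(r2$p_value, r$p_value)
  # the null distribution depends only on the tree (same seed)
  perm <- stats::setNames(sample(x), names(x))
  r3 <- essim_test(tr, perm, nsim = 300, seed = 2)
  expect_equal(r3$null_rhos, r$null_rhos, tolerance = 1e-12)
  expect_error(essim_test(tr, x * 0, nsim = 300, seed = 1), "variance")
  expect_error(essim_test(tr, x, nsim = 50, seed = 1), "nsim")
})

test_that("essim_table mirrors the per-measurement report layout", {
  tr <- sim_yule_tree(12, 0.3, seed = 63)
  tab <- data.frame(species = tr$tip.label,
                    wing_total = unname(sim_bm_trait(tr, 2, seed = 64)),
                    wing_red = unname(sim_bm_trait(tr, 2, seed = 65)))
  rownames(tab) <- tr$tip.label
  out <- essim_table(tr, tab, nsim = 200, seed = 3)
  expect_equal(names(out), c("measurement", "rho", "p_value"))
  expect_equal(nrow(out), 2L)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
})
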