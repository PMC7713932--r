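test_that("BM chains exclude jumps and shifts and are seed-reproducible", {
  tr <- sim_yule_tree(20, 0.3, seed = 51)
  x <- sim_bm_trait(tr, 3, seed = 52)
  r1 <- rjmcmc_bm(tr, x, "BM", ngen = 2e4, thin = 20, seed = 9)
  r2 <- rjmcmc_bm(tr, x, "BM", ngen = 2e4, thin = 20, seed = 9)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(r1$jump_prob == 0))
  expect_true(all(r1$shift_prob == 0))
  expect_true(all(r1$trace$k_jumps == 0))
  # posterior mean log-lik should sit near (slightly below) the ML optimum
  ml <- fit_bm_ml(tr, x)$loglik
  expect_lt(abs(mean(r1$trace$loglik) - ml), 4)
  expect_error(rjmcmc_bm(tr, x, "BM", ngen = 100, thin = 20, seed = 1),
               "10 \\* thin")
})

test_that("two seeds agree on per-branch jump probabilities on the recovery fixture", {
  tr <- sim_yule_tree(31, 0.12, seed = 53)
  b <- longest_stem_clade(tr, 4:8)
  x0 <- sim_bm_trait(tr, 4, seed = 54)
  xj <- sim_bm_trait(tr, 4, jumps = stats::setNames(8 * sd(x0), b), seed = 54)
  ra <- suppressWarnings(
    rjmcmc_bm(tr, xj, "jumpBM", ngen = 6e5, thin = 600, seed = 1))
  rb <- suppressWarnings(
    rjmcmc_bm(tr, xj, "jumpBM", ngen = 6e5, thin = 600, seed = 2))
  expect_gt(ra$jump_prob[b], 0.5)
  expect_gt(rb$jump_prob[b], 0.5)
  expect_lt(max(abs(ra$jump_prob - rb$jump_prob)), 0.1)
})

test_that("relaxed-rate chains recover a strong subtree rate shift", {
  tr <- sim_yule_tree(31, 0.12, seed = 55)
  b <- longest_stem_clade(tr, 5:10)
  xs <- sim_bm_trait(tr, 2, shifts = stats::setNames(40, b), seed = 56)
  rs <- suppressWarnings(
    rjmcmc_bm(tr, xs, "rBM1", ngen = 6e5, thin = 600, seed = 3))
  # the shift (or one of its immediate neighbours) carries high posterior mass
  neigh <- c(b, wingdiv:::subtree_edges(tr)[[b]])
  expect_gt(max(rs$shift_prob[neigh]), 0.5)
  expect_true(all(rs$trace$k_jumps == 0))
})

test_that("the four-model comparison report has the published table layout", {
  tr <- sim_yule_tree(20, 0.3, seed = 57)
  x <- sim_bm_trait(tr, 3, root_state = 50, seed = 58)
  res <- compare_bm_models(tr, x, models = c("BM", "jumpBM"),
                           ngen = 2e4, thin = 20, seed = 4)
  expect_named(res$aicm, c("BM", "jumpBM"))
  expect_true(res$selected %in% c("BM", "jumpBM"))
  expect_true(all(c("alpha_posterior", "alpha_ml", "jumps", "sigma2",
                    "LnL", "AIC", "model") %in% names(res$report)))
  # data simulated under plain BM should not elect the jump model
  expect_equal(res$selected, "BM")
})
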