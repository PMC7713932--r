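test_that("pruning BM likelihood equals the closed form on two tips", {
  ll <- bm_loglik(tree2(), c(A = 0, B = 0), sigma2 = 1, alpha_root = 0)
  expect_equal(ll, -log(2 * pi), tolerance = 1e-12)
  # a zero jump changes nothing
  ll2 <- bm_loglik(tree3(), c(A = 1, B = 0, C = 2), 1.3, 0.5,
                   jumps = c(`1` = 0))
  ll3 <- bm_loglik(tree3(), c(A = 1, B = 0, C = 2), 1.3, 0.5)
  expect_equal(ll2, ll3, tolerance = 1e-12)
})

test_that("pruning matches the dense multivariate-normal oracle", {
  set.seed(31)
  for (rep in 1:20) {
    tr <- sim_yule_tree(sample(4:10, 1), 0.4)
    x <- sim_bm_trait(tr, runif(1, 0.5, 3), root_state = rnorm(1))
    s2 <- runif(1, 0.2, 4); al <- rnorm(1)
    n <- ape::Ntip(tr)
    branch <- sample(setdiff(seq_len(n + tr$Nnode), n + 1L), 2)
    shifts <- stats::setNames(runif(1, 0.3, 3), branch[1])
    jumps <- stats::setNames(rnorm(1, 0, 4), branch[2])
    a <- bm_loglik(tr, x, s2, al, multipliers = shifts, jumps = jumps)
    b <- bm_loglik_dense(tr, x, s2, al, shifts = shifts, jumps = jumps)
    expect_equal(a, as.numeric(b), tolerance = 1e-8)
  }
})

test_that("ML Brownian fit matches the GLS estimator and its invariances", {
  tr <- sim_yule_tree(20, 0.3, seed = 33)
  x <- sim_bm_trait(tr, 2, root_state = 5, seed = 34)
  fit <- fit_bm_ml(tr, x)
  oracle <- bm_fit_dense(tr, x)
  expect_equal(fit$alpha_root, oracle$alpha, tolerance = 1e-6)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-6)
  shifted <- fit_bm_ml(tr, x + 1000)
  expect_equal(shifted$sigma2, fit$sigma2, tolerance = 1e-9)
  expect_warning(fit_bm_ml(tr, stats::setNames(rep(1, 20), tr$tip.label)),
                 "boundary")
})

test_that("BM rate recovery is unbiased at study scale", {
  set.seed(35)
  est <- replicate(150, {
    tr <- sim_yule_tree(31, 0.12)
    fit_bm_ml(tr, sim_bm_trait(tr, 53))$sigma2
  })
  expect_lt(abs(median(est) - 53) / 53, 0.15)
})

test_that("ancestral states equal the dense GLS oracle and ape::ace", {
  set.seed(36)
  for (rep in 1:5) {
    tr <- sim_yule_tree(8, 0.4)
    x <- sim_bm_trait(tr, 1.5, root_state = 2)
    fit <- fit_bm_ml(tr, x)
    a <- asr_continuous(tr, x, fit)
    expect_equal(a$estimate[1], fit$alpha_root, tolerance = 1e-8)
    expect_true(all(a$variance > 0))
    ace <- ape::ace(x[tr$tip.label], tr, method = "ML")
    expect_equal(a$estimate, unname(ace$ace), tolerance = 1e-4)
  }
  # symmetric two-tip case: root midway
  tr2 <- tree2()
  a2 <- asr_continuous(tr2, c(A = 0, B = 10),
                       params = list(sigma2 = 1, alpha_root = 5))
  expect_equal(a2$estimate, 5)
  # constant traits: every node at the constant, positive variance
  tr3b <- tree3()
  a3 <- asr_continuous(tr3b, c(A = 4, B = 4, C = 4),
                       params = list(sigma2 = 1, alpha_root = 4))
  expect_true(all(abs(a3$estimate - 4) < 1e-10))
  expect_true(all(a3$variance > 0))
})

test_that("AICM follows its moment formula", {
  expect_warning(v <- aicm(rep(-50, 200)), "zero variance")
  expect_equal(v, 100)
  set.seed(37)
  tr <- rnorm(1e4, -100, 2)
  expect_lt(abs(aicm(tr) - 208), 2)
  tr2 <- tr + 7
  expect_equal(aicm(tr2) - aicm(tr), -14, tolerance = 1e-9)
  expect_error(aicm(rnorm(50)), "100")
})

test_that("model selection applies the delta-AIC-2 simplicity rule", {
  expect_equal(select_model(c(BM = 260, jumpBM = 259)), "BM")
  expect_equal(select_model(c(BM = 292.55 + 5, jumpBM = 292.55)), "jumpBM")
  expect_equal(select_model(c(jumpRBM = 100)), "jumpRBM")
  expect_equal(select_model(c(rBM1 = 10, BM = 11.9, jumpBM = 9.99)), "BM")
  expect_error(select_model(numeric(0)), "no models")
})
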