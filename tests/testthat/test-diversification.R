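test_that("rate evaluation honours each functional form and the time direction", {
  expect_equal(rate_at(rates_model("constant", "zero", lambda0 = 0.12), 17),
               0.12)
  m <- rates_model("exponential", "zero", lambda0 = 0.15, lambda_coef = -0.03)
  expect_equal(rate_at(m, 0), 0.15)
  expect_equal(rate_at(m, 32), 0.15 * exp(-0.96))
  expect_lt(abs(rate_at(m, 32) - 0.057), 0.002)  # rises toward the present
  lin <- rates_model("linear", "zero", lambda0 = 0.1, lambda_coef = -0.02)
  expect_warning(v <- rate_at(lin, 10), "floored")
  expect_equal(v, 0)
  ec <- env_curve(c(0, 10), c(1, 3))
  me <- rates_model("env_exponential", "zero", lambda0 = 0.1,
                    lambda_coef = 0.5, env = ec)
  expect_equal(rate_at(me, 5), 0.1 * exp(0.5 * 2))
  expect_error(rates_model("env_exponential", "zero", lambda0 = 1),
               "env curve")
  expect_error(rates_model("constant", "zero", lambda0 = 1, mu0 = 0.1),
               "zero")
})

test_that("birth-death likelihood reduces to closed forms and nests properly", {
  for (seed in 1:5) {
    tr <- sim_yule_tree(sample(10:40, 1), 0.2, seed = seed)
    bt <- branching_times(tr)
    n <- attr(bt, "n_tips"); S <- attr(bt, "total_branch_length")
    lam <- runif(1, 0.05, 0.4)
    m <- rates_model("constant", "zero", lambda0 = lam)
    expect_equal(bd_loglik(tr, m), (n - 2) * log(lam) - lam * S,
                 tolerance = 1e-6)
    m2 <- rates_model("exponential", "zero", lambda0 = lam, lambda_coef = 0)
    expect_equal(bd_loglik(tr, m2), bd_loglik(tr, m), tolerance = 1e-8)
  }
  # env model with a constant curve == constant model at the effective rate
  tr <- sim_yule_tree(25, 0.15, seed = 6)
  ec <- env_curve(c(0, 40), c(1.7, 1.7))
  me <- rates_model("env_exponential", "zero", lambda0 = 0.06,
                    lambda_coef = 0.4, env = ec)
  mc <- rates_model("constant", "zero", lambda0 = 0.06 * exp(0.4 * 1.7))
  expect_equal(bd_loglik(tr, me), bd_loglik(tr, mc), tolerance = 1e-8)
})

test_that("pure-birth ML fit equals (n-2)/S and the AIC identity holds exactly", {
  for (seed in 1:4) {
    tr <- sim_yule_tree(31, 0.12, seed = seed + 70)
    bt <- branching_times(tr)
    f <- fit_bd(tr, "constant", "zero", seed = 1)
    expect_equal(f$model$lambda0,
                 (attr(bt, "n_tips") - 2) / attr(bt, "total_branch_length"),
                 tolerance = 1e-5)
    expect_identical(f$aic, 2 * f$n_params - 2 * f$loglik)
  }
})

test_that("model table bookkeeping reproduces published-style AIC arithmetic", {
  fits <- list(list(loglik = -90.9, n_params = 1, label = "constant"),
               list(loglik = -89.9, n_params = 2, label = "exponential"))
  tab <- model_table(fits)
  expect_equal(tab$AIC, c(183.8, 183.8))
  expect_equal(tab$delta_AIC, c(0, 0))
  tab2 <- model_table(c(fits, list(list(loglik = -89.7, n_params = 2,
                                        label = "andes"))))
  expect_equal(tab2$AIC[3], 183.4)
  expect_equal(tab2$delta_AIC, c(0.4, 0.4, 0))
  expect_true(all(abs(tab2$AIC - (2 * tab2$n_params - 2 * tab2$loglik)) == 0))
  expect_equal(model_table(fits[1])$delta_AIC, 0)
})

test_that("time-dependent fits recover the sign and prefer parsimony when nested", {
  set.seed(81)
  # parsimony: exponential fit on constant-rate trees stays within 2 AIC
  win <- replicate(12, {
    tr <- sim_yule_tree(31, 0.12)
    fc <- fit_bd(tr, "constant", "zero", nstart = 2, seed = 1)
    fe <- fit_bd(tr, "exponential", "zero", nstart = 2, seed = 1)
    fe$aic - fc$aic <= 2
  })
  expect_gt(mean(win), 0.75)
  # direction: rising lambda toward the present gives negative coefficients
  set.seed(82)
  signs <- replicate(8, {
    tr <- sim_bd_tree(35, function(t) 0.22 * exp(-0.05 * t))
    if (ape::Ntip(tr) < 25) return(NA)
    fe <- fit_bd(tr, "exponential", "zero", nstart = 2, seed = 1)
    fe$model$lambda_coef < 0
  })
  expect_gt(mean(signs, na.rm = TRUE), 0.85)
})

test_that("gamma statistic matches its published implementation and null moments", {
  for (seed in 1:6) {
    tr <- sim_yule_tree(sample(10:40, 1), 0.2, seed = seed + 90)
    expect_equal(gamma_stat(tr), ape::gammaStat(tr), tolerance = 1e-9)
  }
  # pushing all splits toward the root (early burst) drives gamma negative
  old_heavy <- read_newick(
    "((((A:9.7,B:9.7):0.1,C:9.8):0.1,D:9.9):0.1,E:10):0;")
  expect_lt(gamma_stat(old_heavy), 0)
  expect_error(gamma_stat(tree3()), "4 tips")
})

test_that("Magallon-Sanderson estimator inverts expected diversity", {
  expect_equal(ms_rate(10, log(10), 0, "stem"), 1)
  expect_equal(ms_rate(2, 7.3, 0, "crown"), 0)
  expect_error(ms_rate(5, 1, 1), "epsilon")
  # stem oracle: solve n = (e^{rt} - eps)/(1 - eps) numerically
  for (case in list(c(25, 27.6, 0.5), c(80, 12, 0.9), c(5, 3, 0.25))) {
    n <- case[1]; t <- case[2]; eps <- case[3]
    oracle <- uniroot(function(r) (exp(r * t) - eps) / (1 - eps) - n,
                      c(1e-8, 5), tol = 1e-12)$root
    expect_equal(ms_rate(n, t, eps, "stem"), oracle, tolerance = 1e-6)
  }
  # crown oracle: n (1 - alpha^2) = 2 e^{rt}, alpha the extinction prob
  for (case in list(c(31, 27.6, 0.5), c(12, 8, 0.2))) {
    n <- case[1]; t <- case[2]; eps <- case[3]
    oracle <- uniroot(function(r) {
      x <- exp(r * t)
      a <- eps * (x - 1) / (x - eps)
      n * (1 - a^2) - 2 * x
    }, c(1e-8, 5), tol = 1e-12)$root
    expect_equal(ms_rate(n, t, eps, "crown"), oracle, tolerance = 1e-6)
  }
  # continuity in epsilon near zero
  expect_lt(abs(ms_rate(31, 27.6, 1e-8, "crown") -
                  ms_rate(31, 27.6, 0, "crown")), 1e-6)
})

test_that("connectivity curve follows the per-epoch closed form", {
  ep0 <- migration_epochs(rates = c(0, 0, 0, 0, 0))
  c0 <- build_connectivity_curve(ep0)
  expect_true(all(c0$fun(c(0, 10, 30, 49)) == 0))
  ep <- migration_epochs(rates = c(0.1, 0.2, 0.5, 1, 2))
  cc <- build_connectivity_curve(ep)
  mid <- c(45, 30, 15, 6, 2)                 # one age inside each epoch
  expect_equal(cc$fun(mid), 1 - exp(-c(0.1, 0.2, 0.5, 1, 2)))
  expect_equal(cc$fun(2), 1 - exp(-2), tolerance = 1e-12)
  # values toward the present never decrease, also in the cumulative variant
  cum <- build_connectivity_curve(ep, cumulative = TRUE)
  ages <- seq(49, 0, by = -0.5)
  expect_true(all(diff(cc$fun(ages)) >= 0))
  expect_true(all(diff(cum$fun(ages)) >= 0))
  expect_error(migration_epochs(rates = c(-1, 0, 0, 0, 0)), ">= 0")
  expect_error(migration_epochs(rates = c(2, 1, 1, 1, 1)), "nondecreasing")
})
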