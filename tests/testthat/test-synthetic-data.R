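test_that("Yule simulator is seed-deterministic and logs its events", {
  a <- sim_yule_tree(10, 0.3, seed = 7)
  b <- sim_yule_tree(10, 0.3, seed = 7)
  expect_identical(write_newick(a), write_newick(b))
  expect_lt(max(abs(attr(a, "event_ages") - branching_times(a))), 1e-9)
  expect_error(sim_yule_tree(1, 0.3), "n_tips")
  two <- sim_yule_tree(2, 0.5, seed = 1)
  expect_equal(ape::Ntip(two), 2L)
  expect_equal(length(attr(two, "event_ages")), 1L)
})

test_that("Yule crown ages match the analytic waiting-time expectation", {
  lambda <- 0.12; n <- 31
  set.seed(41)
  crowns <- replicate(400, crown_age(sim_yule_tree(n, lambda)))
  expected <- sum(1 / ((2:n) * lambda))
  expect_lt(abs(mean(crowns) - expected) / expected, 0.15)
})

test_that("birth-death simulator nests the pure-birth case and honours rising rates", {
  # mu = 0, constant lambda over a fixed duration: crown age equals the
  # duration and the tip count matches the pure-birth expectation
  # 2 e^{lambda T} from two crown lineages
  set.seed(5)
  lambda <- 0.25; T0 <- 10
  sims <- replicate(250, {
    tr <- sim_bd_tree(T0, function(t) lambda)
    c(crown_age(tr), ape::Ntip(tr))
  })
  expect_true(all(abs(sims[1, ] - T0) < 1e-8))
  expected_n <- 2 * exp(lambda * T0)
  expect_lt(abs(mean(sims[2, ]) - expected_n) / expected_n, 0.15)

  # increasing lambda(t) toward the present concentrates nodes recently:
  # LTT slope near the present exceeds the slope near the root
  rising <- function(t) 0.15 * exp(-0.03 * t)
  set.seed(6)
  hits <- replicate(60, {
    tr <- sim_bd_tree(28, rising)
    bt <- branching_times(tr)
    n <- attr(bt, "n_tips")
    if (n < 6) return(NA)
    young <- sum(bt < median(bt)) / median(bt)
    old <- sum(bt >= median(bt)) / (max(bt) - median(bt))
    young > old
  })
  expect_gt(mean(hits, na.rm = TRUE), 0.6)

  # with extinction, some replicates get rejected and the retry log shows it
  set.seed(7)
  tr <- sim_bd_tree(20, function(t) 0.3, function(t) 0.25)
  expect_true(is.numeric(attr(tr, "retries")))
})

test_that("BM trait simulator obeys its closed-form moments", {
  tr <- tree2()
  expect_equal(as.vector(sim_bm_trait(tr, 0, root_state = 3, seed = 1)),
               c(3, 3))
  set.seed(11)
  diffs <- replicate(1000, {
    x <- sim_bm_trait(tr, 1)
    x[["A"]] - x[["B"]]
  })
  expect_lt(abs(var(diffs) - 2) / 2, 0.1)
  expect_error(sim_bm_trait(tr, 1, jumps = c(`99` = 5)), "unknown branch")
})

test_that("a jump on a clade stem displaces exactly that clade", {
  tr <- sim_yule_tree(12, 0.3, seed = 21)
  sub <- wingdiv:::subtree_edges(tr)
  n <- ape::Ntip(tr)
  stems <- which(vapply(sub, function(s) sum(s <= n), 0L) %in% 3:6)
  b <- stems[stems > n][1]
  inside <- tr$tip.label[sub[[b]][sub[[b]] <= n]]
  set.seed(2)
  gaps <- replicate(200, {
    x <- sim_bm_trait(tr, 1, jumps = stats::setNames(100, b))
    mean(x[inside]) - mean(x[setdiff(tr$tip.label, inside)])
  })
  expect_lt(abs(mean(gaps) - 100), 5)
})

test_that("wing-region fixtures have the promised pixel structure", {
  fx <- sim_wing_region(c(10, 200, 30), noise_fraction = 0, shape = c(20, 20),
                        seed = 1)
  expect_true(all(fx$pixels[, , 1][fx$mask] == 10))
  fx2 <- sim_wing_region(c(10, 200, 30), noise_fraction = 0.3,
                         shape = c(60, 60), seed = 2)
  frac <- mean(fx2$pixels[, , 2][fx2$mask] == 200)
  expect_gt(frac, 0.5)
  expect_error(sim_wing_region(c(1, 2, 3), noise_fraction = 0.5), "noise")
  expect_identical(sim_wing_region(c(5, 5, 5), 0.2, seed = 9)$pixels,
                   sim_wing_region(c(5, 5, 5), 0.2, seed = 9)$pixels)
})

test_that("DEC history simulation is internally consistent with the rate matrix", {
  sp <- build_state_space(c("A", "B", "C"),
                          rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE),
                                c(FALSE, TRUE, TRUE)))
  tr <- tree3()
  h0 <- sim_dec_history(tr, sp, d = 0, e = 0, root_range = 1L, seed = 3)
  expect_true(all(h0$tip_ranges == 1L))
  expect_true(all(h0$node_ranges == 1L))

  sp1 <- build_state_space("X")
  h1 <- sim_dec_history(tree3(), sp1, d = 5, e = 0, root_range = 1L, seed = 4)
  expect_true(all(h1$tip_ranges == 1L))

  # Poisson event-count check: integrate the realised gain intensity along
  # every edge trajectory (reconstructed from the event log) and compare
  # the observed number of gain events with that cumulative intensity
  tr50 <- sim_yule_tree(50, 0.5, seed = 4)
  h <- sim_dec_history(tr50, sp, d = 0.1, e = 0.02, root_range = 7L,
                       seed = 204)
  Q <- build_Q(sp, d = 0.1, e = 0.02)
  gain_rate <- vapply(seq_len(sp$n_states), function(s) {
    tgt <- which(wingdiv:::.popcount(sp$ranges) >
                   wingdiv:::.popcount(sp$ranges[s]))
    sum(Q[s, tgt])
  }, 0)
  tt <- ape::reorder.phylo(tr50, "cladewise")
  ages <- node_ages(tt)
  ntip <- ape::Ntip(tt)
  state_idx <- integer(ntip + tt$Nnode)
  state_idx[seq_len(ntip)] <- vapply(h$tip_ranges[tt$tip.label], function(m)
    unname(sp$index[as.character(m)]), 1L)
  state_idx[(ntip + 1):(ntip + tt$Nnode)] <- vapply(h$node_ranges, function(m)
    unname(sp$index[as.character(m)]), 1L)
  Lambda <- 0
  for (i in seq_len(nrow(tt$edge))) {
    p <- tt$edge[i, 1]; ch <- tt$edge[i, 2]
    ev <- h$events[h$events$edge == ch, , drop = FALSE]
    ev <- ev[order(-ev$age), , drop = FALSE]
    t_hi <- ages[p]
    s <- if (nrow(ev)) ev$from[1] else state_idx[ch]
    for (j in seq_len(nrow(ev))) {
      Lambda <- Lambda + gain_rate[s] * (t_hi - ev$age[j])
      t_hi <- ev$age[j]; s <- ev$to[j]
    }
    Lambda <- Lambda + gain_rate[s] * (t_hi - ages[ch])
  }
  gains <- sum(h$events$type == "gain")
  expect_lt(abs(gains - Lambda) / Lambda, 0.25)
})
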