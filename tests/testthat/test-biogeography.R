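chain3 <- function() build_state_space(
  c("A", "B", "C"),
  rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE)))

test_that("state space enumeration respects adjacency and size limits", {
  sp <- chain3()
  expect_equal(sp$n_states, 7L)                       # AC excluded, + empty
  expect_false("5" %in% names(sp$index))              # mask of {A,C}
  expect_equal(sp$labels[1], "()")
  full <- build_state_space(c("A", "B", "C", "D"))
  expect_equal(full$n_states, 2^4)
  solo <- build_state_space(letters[1:5], max_size = 1)
  expect_equal(solo$n_states, 6L)
  expect_error(build_state_space(character(0)), "empty")
})

test_that("DEC rate matrix has textbook structure", {
  two <- build_state_space(c("A", "B"))
  Q <- build_Q(two, d = 0.3, e = 0.07)
  expect_equal(Q["A", "A+B"], 0.3)
  expect_equal(Q["A+B", "A"], 0.07)
  expect_equal(Q["A", "()"], 0.07)
  expect_true(all(abs(rowSums(Q)) < 1e-12))
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
  expect_true(all(Q["()", ] == 0))                    # absorbing empty range
  # d = 0: only contractions remain
  sp3 <- chain3()
  Q0 <- build_Q(sp3, d = 0, e = 0.1)
  sz <- wingdiv:::.popcount(sp3$ranges)
  growing <- outer(sz, sz, "<")                       # target larger than source
  expect_true(all(Q0[growing] == 0))
  expect_gt(sum(Q0[outer(sz, sz, ">")]), 0)
  # a barrier multiplier silences one route and leaves others untouched
  m <- matrix(1, 3, 3); m[1, 2] <- m[2, 1] <- 0
  Qb <- build_Q(chain3(), d = 0.2, e = 0, multipliers = m)
  expect_equal(Qb["A", "A+B"], 0)
  expect_equal(Qb["B", "B+C"], 0.2)
})

test_that("cladogenetic tables enumerate the models' event sets", {
  sp <- chain3()
  cw <- cladogenesis_weights(sp, "DEC")
  ab <- cw[[unname(sp$index["3"])]]
  expect_equal(nrow(ab), 4L)
  expect_true(all(ab$weight == 0.25))
  pairs <- paste(sp$labels[ab$left], sp$labels[ab$right])
  expect_setequal(pairs, c("A+B A", "A+B B", "A B", "B A"))
  # singletons inherit identically under both models
  for (model in c("DEC", "DIVALIKE")) {
    w <- cladogenesis_weights(sp, model)[[2]]
    expect_equal(w, data.frame(left = 2, right = 2, weight = 1))
  }
  # DIVALIKE on a chain-adjacent triple: vicariant splits only, none using AC
  dv <- cladogenesis_weights(sp, "DIVALIKE")
  abc <- dv[[unname(sp$index["7"])]]
  plab <- paste(sp$labels[abc$left], sp$labels[abc$right])
  expect_setequal(plab, c("A B+C", "B+C A", "A+B C", "C A+B"))
  # weights always sum to one per parent
  for (model in c("DEC", "DIVALIKE")) {
    w <- cladogenesis_weights(sp, model)
    sums <- vapply(w[-1], function(x) sum(x$weight), 0)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("pruning likelihood equals the exhaustive-enumeration oracle", {
  set.seed(101)
  spaces <- list(build_state_space(c("A", "B")), chain3())
  trees <- list(tree3(), read_newick("((A:1,B:1):1.5,(C:2,D:2):0.5):0;"),
                read_newick("(((A:1,B:1):1,C:2):1,D:3):0;"))
  for (model in c("DEC", "DIVALIKE")) {
    for (sp in spaces) {
      for (tr in trees) {
        for (k in 1:5) {
          d <- runif(1, 0.01, 0.5); e <- runif(1, 0.01, 0.3)
          tip_ranges <- stats::setNames(
            sample(sp$ranges[-1], ape::Ntip(tr), replace = TRUE),
            tr$tip.label)
          a <- dec_loglik(tr, tip_ranges, sp, list(d = d, e = e),
                          model = model)
          b <- dec_loglik_oracle(tr, tip_ranges, sp, d, e, model = model)
          expect_equal(a, b, tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("likelihood is invariant to area relabelling", {
  set.seed(102)
  sp <- chain3()
  # reversing the chain A-B-C to C-B-A is an adjacency-preserving relabelling
  sp_rev <- build_state_space(
    c("C", "B", "A"),
    rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE)))
  tr <- read_newick("((A:1,B:1):1.5,(C:2,D:2):0.5):0;")
  relabel <- function(mask) {
    areas <- c("A", "B", "C")[which(bitwAnd(mask, c(1L, 2L, 4L)) > 0)]
    range_mask(sp_rev, areas)
  }
  for (k in 1:5) {
    tips <- stats::setNames(sample(sp$ranges[-1], 4, replace = TRUE),
                            tr$tip.label)
    tips_rev <- stats::setNames(vapply(tips, relabel, 1L), names(tips))
    d <- runif(1, 0.05, 0.4); e <- runif(1, 0.01, 0.2)
    expect_equal(dec_loglik(tr, tips, sp, list(d = d, e = e)),
                 dec_loglik(tr, tips_rev, sp_rev, list(d = d, e = e)),
                 tolerance = 1e-10)
  }
})

test_that("stratification with identical slices is a no-op and 1-area spaces are flat", {
  sp <- chain3()
  tr <- tree3()
  tips <- stats::setNames(c(1L, 2L, 4L), c("A", "B", "C"))
  base <- dec_loglik(tr, tips, sp, list(d = 0.1, e = 0.05))
  strat <- dec_config(slices = c(2.5, 1.2, 0.4, 0),
                      multipliers = matrix(1, 3, 3))
  expect_equal(dec_loglik(tr, tips, sp, list(d = 0.1, e = 0.05), strat),
               base, tolerance = 1e-10)
  one <- build_state_space("Z")
  expect_equal(dec_loglik(tr, stats::setNames(c(1L, 1L, 1L), tr$tip.label),
                          one, list(d = 9, e = 9)), 0)
})

test_that("ancestral marginals equal the brute-force posterior and normalise", {
  set.seed(103)
  sp <- build_state_space(c("A", "B"))
  tr <- tree3()
  for (k in 1:3) {
    tips <- stats::setNames(sample(sp$ranges[-1], 3, replace = TRUE),
                            tr$tip.label)
    d <- runif(1, 0.05, 0.4); e <- runif(1, 0.01, 0.2)
    got <- attr(ancestral_ranges(tr, tips, sp, list(d = d, e = e)), "matrix")
    want <- dec_marginals_oracle(tr, tips, sp, d, e)[, -1, drop = FALSE]
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
    expect_true(all(abs(rowSums(got) - 1) < 1e-8))
  }
  # degenerate dispersal: everything stays in the tips' shared range
  tipsA <- stats::setNames(rep(1L, 3), tr$tip.label)
  gotA <- attr(ancestral_ranges(tr, tipsA, sp, list(d = 1e-9, e = 1e-9)),
               "matrix")
  expect_true(all(gotA[, "A"] > 0.999))
})

test_that("hypothesis comparison flags identical hypotheses as ties", {
  sp <- chain3()
  tr <- sim_yule_tree(12, 0.4, seed = 104)
  h <- sim_dec_history(tr, sp, d = 0.15, e = 0.05, root_range = 7L,
                       seed = 105)
  cfgs <- list(HoA = dec_config(label = "HoA"),
               HoB = dec_config(label = "HoB"))
  tab <- compare_hypotheses(tr, h$tip_ranges, sp, cfgs, models = "DEC",
                            nstart = 2)
  expect_equal(nrow(tab), 2L)
  expect_lt(abs(tab$LnL[1] - tab$LnL[2]), 1e-6)
  expect_lt(abs(diff(tab$delta_AIC)), 1e-6)
  expect_error(compare_hypotheses(tr, h$tip_ranges, sp,
                                  unname(cfgs), models = "DEC"),
               "named")
})

test_that("range tables round-trip through the tab-delimited format", {
  geo <- neotropical_geography()
  tr <- sim_yule_tree(8, 0.4, seed = 106)
  h <- sim_dec_history(tr, geo$space, d = 0.1, e = 0.02,
                       root_range = range_mask(geo$space, c("EAnd", "Amaz")),
                       seed = 107)
  f <- tempfile(fileext = ".tsv")
  write_range_table(h$tip_ranges, geo$space, f)
  back <- read_range_table(f, geo$space)
  expect_identical(back[names(h$tip_ranges)], h$tip_ranges)
})
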