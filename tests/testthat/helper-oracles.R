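# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately written as direct, dense computations so they
# share no code path with the package implementations they check.

tree3 <- function() read_newick("((A:1,B:1):1,C:2):0;")
tree2 <- function() read_newick("(A:1,B:1):0;")

# Dense multivariate-normal BM log-likelihood via the phylogenetic
# covariance matrix (shared path lengths), with optional subtree rate
# multipliers and jumps applied by brute force.
bm_loglik_dense <- function(tree, traits, sigma2, alpha, shifts = NULL,
                            jumps = NULL) {
  n <- ape::Ntip(tree)
  x <- traits[tree$tip.label]
  # per-edge rates: multiplier applies to named branch and all its descendants
  mult <- rep(1, n + tree$Nnode)
  offset <- numeric(n + tree$Nnode)
  desc <- function(node) {
    if (node <= n) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    c(node, unlist(lapply(kids, desc)))
  }
  for (nm in names(shifts)) {
    idx <- desc(as.integer(nm))
    mult[idx] <- mult[idx] * shifts[[nm]]
  }
  for (nm in names(jumps)) {
    idx <- desc(as.integer(nm))
    offset[idx] <- offset[idx] + jumps[[nm]]
  }
  # covariance: sum of sigma2 * mult * length over shared root-to-tip edges
  paths <- lapply(seq_len(n), function(tip) {
    p <- integer(0)
    node <- tip
    while (node != n + 1L) {
      e <- which(tree$edge[, 2] == node)
      p <- c(p, e)
      node <- tree$edge[e, 1]
    }
    p
  })
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(sigma2 * mult[tree$edge[shared, 2]] *
                     tree$edge.length[shared])
  }
  mu <- alpha + offset[seq_len(n)]
  -n / 2 * log(2 * pi) - 0.5 * determinant(C)$modulus[1] -
    0.5 * t(x - mu) %*% solve(C) %*% (x - mu)
}

# Dense GLS estimates of sigma2 and root state.
bm_fit_dense <- function(tree, traits) {
  n <- ape::Ntip(tree)
  x <- traits[tree$tip.label]
  C <- ape::vcv(tree)
  Ci <- solve(C)
  one <- rep(1, n)
  alpha <- as.numeric(t(one) %*% Ci %*% x / (t(one) %*% Ci %*% one))
  sigma2 <- as.numeric(t(x - alpha) %*% Ci %*% (x - alpha)) / n
  list(alpha = alpha, sigma2 = sigma2)
}

# Exhaustive-enumeration DEC likelihood for small trees and spaces.
# Sums over all assignments of parent states and cladogenetic daughter
# pairs, with dense matrix exponentials along branches. The cladogenetic
# event sets are re-derived here from first principles.
dec_events_oracle <- function(space, parent_state, model) {
  r <- space$ranges[parent_state]
  k <- length(space$areas)
  bits <- bitwShiftL(1L, 0:(k - 1))
  occ <- which(bitwAnd(r, bits) > 0)
  if (length(occ) == 1L)
    return(data.frame(left = parent_state, right = parent_state, weight = 1))
  L <- integer(0); R <- integer(0)
  if (model == "DEC") {
    for (a in occ) {
      ai <- unname(space$index[as.character(bits[a])])
      L <- c(L, parent_state); R <- c(R, ai)
      rem <- r - bits[a]
      ri <- space$index[as.character(rem)]
      if (!is.na(ri)) { L <- c(L, ai); R <- c(R, unname(ri)) }
    }
  } else {
    for (ui in seq_along(space$ranges)) {
      u <- space$ranges[ui]
      if (u == 0L || u == r || bitwAnd(u, r) != u) next
      v <- r - u
      vi <- space$index[as.character(v)]
      if (!is.na(vi)) { L <- c(L, ui); R <- c(R, unname(vi)) }
    }
  }
  data.frame(left = L, right = R, weight = 1 / length(L))
}

# Likelihood by recursion with explicit sums; unstratified only.
dec_loglik_oracle <- function(tree, tip_ranges, space, d, e, model = "DEC",
                              multipliers = NULL) {
  S <- space$n_states
  Q <- build_Q(space, d, e, multipliers = multipliers)
  ages <- wingdiv::node_ages(tree)
  n <- ape::Ntip(tree)
  tip_state <- vapply(tip_ranges[tree$tip.label], function(m)
    unname(space$index[as.character(m)]), 1L)
  Pm <- function(dt) as.matrix(Matrix::expm(Q * dt))
  # subtree likelihood given the state at the START (top) of the branch
  # leading to `node`
  below <- function(node, P_branch) {
    if (node <= n) {
      v <- numeric(S); v[tip_state[node]] <- 1
      return(as.vector(P_branch %*% v))
    }
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    lens <- ages[node] - ages[kids]
    bl <- below(kids[1], Pm(lens[1]))
    br <- below(kids[2], Pm(lens[2]))
    inner <- numeric(S)
    for (s in 2:S) {
      ev <- dec_events_oracle(space, s, model)
      tot <- 0
      for (j in seq_len(nrow(ev))) {
        tot <- tot + ev$weight[j] *
          (bl[ev$left[j]] * br[ev$right[j]] +
             bl[ev$right[j]] * br[ev$left[j]]) / 2
      }
      inner[s] <- tot
    }
    as.vector(P_branch %*% inner)
  }
  root <- n + 1L
  v <- below(root, diag(S))
  log(mean(v[2:S]))
}

# Marginal node-range posterior by brute force over joint assignments.
dec_marginals_oracle <- function(tree, tip_ranges, space, d, e, model = "DEC") {
  S <- space$n_states
  Q <- build_Q(space, d, e)
  ages <- wingdiv::node_ages(tree)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  tip_state <- vapply(tip_ranges[tree$tip.label], function(mm)
    unname(space$index[as.character(mm)]), 1L)
  Pm <- function(dt) as.matrix(Matrix::expm(Q * dt))
  nodes <- (n + 1L):(n + m)
  grids <- rep(list(2:S), m)
  combos <- as.matrix(expand.grid(grids))
  post <- matrix(0, m, S)
  for (ci in seq_len(nrow(combos))) {
    node_state <- combos[ci, ]
    names(node_state) <- nodes
    # joint probability of this node-state assignment and the tip data:
    # sum over daughter-start states via per-node event tables
    lik <- 1 / (S - 1)
    ok <- TRUE
    for (nd in nodes) {
      s <- node_state[as.character(nd)]
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      ev <- dec_events_oracle(space, s, model)
      tot <- 0
      for (j in seq_len(nrow(ev))) {
        for (ordpair in list(c(ev$left[j], ev$right[j]),
                             c(ev$right[j], ev$left[j]))) {
          p <- ev$weight[j] / 2
          for (kk in 1:2) {
            kid <- kids[kk]
            P <- Pm(ages[nd] - ages[kid])
            tgt <- if (kid <= n) tip_state[kid] else
              node_state[as.character(kid)]
            p <- p * P[ordpair[kk], tgt]
          }
          tot <- tot + p
        }
      }
      lik <- lik * tot
      if (lik == 0) { ok <- FALSE; break }
    }
    if (ok) for (i in seq_len(m)) post[i, node_state[i]] <-
        post[i, node_state[i]] + lik
  }
  sweep(post, 1, rowSums(post), "/")
}

# The stem branch (child node id) of the clade with tip count in `sizes`
# whose stem is longest: a well-identifiable location for jump/shift
# recovery fixtures.
longest_stem_clade <- function(tree, sizes = 4:8) {
  n <- ape::Ntip(tree)
  sub <- wingdiv:::subtree_edges(tree)
  cand <- which(vapply(sub, function(s) sum(s <= n), 0L) %in% sizes)
  cand <- cand[cand > n]
  stopifnot(length(cand) > 0)
  lens <- vapply(cand, function(b) tree$edge.length[tree$edge[, 2] == b], 0)
  cand[which.max(lens)]
}
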