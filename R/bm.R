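# Brownian-motion likelihood by Felsenstein pruning, closed-form ML fit,
# and GLS ancestral state reconstruction.

# Expand named subtree multipliers / jumps into per-node vectors.
.expand_branch_effects <- function(tree, shifts, jumps) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  mult <- rep(1, n_all)
  offset <- numeric(n_all)
  if (!is.null(shifts) || !is.null(jumps)) {
    sub <- subtree_edges(tree)
    chk <- function(v, what) {
      if (is.null(v)) return(v)
      ids <- as.integer(names(v))
      if (anyNA(ids) || any(ids < 1L) || any(ids > n_all) || any(ids == n_tip + 1L))
        stop("unknown branch id in ", what)
      v
    }
    shifts <- chk(shifts, "multipliers"); jumps <- chk(jumps, "jumps")
    for (nm in names(shifts)) {
      idx <- sub[[as.integer(nm)]]
      mult[idx] <- mult[idx] * shifts[[nm]]
    }
    for (nm in names(jumps)) {
      idx <- sub[[as.integer(nm)]]
      offset[idx] <- offset[idx] + jumps[[nm]]
    }
  }
  list(mult = mult, tip_offset = offset[seq_len(n_tip)])
}

#' Brownian-motion log-likelihood (pruning algorithm)
#'
#' Multivariate-normal log density of the tip values under Brownian motion
#' with rate `sigma2`, root value `alpha_root`, optional branch-specific rate
#' multipliers (each applying to the named branch and its subtree) and
#' optional mean jumps added at the rootward end of named branches. Computed
#' by the contrast/pruning recursion in O(n) without forming the dense
#' covariance.
#'
#' @param tree A binary `phylo` object.
#' @param traits Named numeric vector covering all tips.
#' @param sigma2 Brownian rate (> 0), squared trait units per Ma.
#' @param alpha_root Root state (trait units).
#' @param multipliers Named numeric vector of subtree rate multipliers
#'   (names = branch/child-node ids), or `NULL`.
#' @param jumps Named numeric vector of jump sizes, or `NULL`.
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, traits, sigma2, alpha_root,
                      multipliers = NULL, jumps = NULL) {
  x <- .match_tip_values(tree, traits)
  if (!(sigma2 > 0)) stop("sigma2 must be > 0")
  eff <- .expand_branch_effects(tree, multipliers, jumps)
  x <- x - eff$tip_offset
  pr <- .bm_prune(tree, x, sigma2 * eff$mult)
  pr$loglik_contrasts +
    stats::dnorm(pr$root_value, alpha_root, sqrt(pr$root_var), log = TRUE)
}

.match_tip_values <- function(tree, traits) {
  if (is.null(names(traits))) {
    if (length(traits) != ape::Ntip(tree)) stop("traits must cover all tips")
    return(as.numeric(traits))
  }
  x <- traits[tree$tip.label]
  if (anyNA(x)) stop("traits must cover all tips")
  as.numeric(x)
}

# Core pruning pass. edge_rate: per-node rate (indexed by child node id).
.bm_prune <- function(tree, x, edge_rate) {
  if (any(!is.finite(x))) stop("non-finite traits")
  tt <- tree_traversal(tree)
  n_tip <- tt$n_tip
  root <- n_tip + 1L
  if (length(edge_rate) == 1L) edge_rate <- rep(edge_rate, n_tip + tt$n_node)
  xv <- c(x, numeric(tt$n_node))
  sv <- numeric(n_tip + tt$n_node)
  pend_x <- rep(NA_real_, n_tip + tt$n_node)
  pend_v <- rep(NA_real_, n_tip + tt$n_node)
  ll <- 0
  for (i in seq_along(tt$child)) {
    ch <- tt$child[i]; p <- tt$parent[i]
    v <- sv[ch] + edge_rate[ch] * tt$length[i]
    if (is.na(pend_x[p])) {
      pend_x[p] <- xv[ch]; pend_v[p] <- v
    } else {
      V <- pend_v[p] + v
      if (V <= 0) stop("singular covariance: zero-length cherry")
      ll <- ll + stats::dnorm(pend_x[p] - xv[ch], 0, sqrt(V), log = TRUE)
      xv[p] <- (pend_x[p] * v + xv[ch] * pend_v[p]) / V
      sv[p] <- pend_v[p] * v / V
      pend_x[p] <- NA_real_
    }
  }
  list(loglik_contrasts = ll, root_value = xv[root], root_var = sv[root])
}

#' Maximum-likelihood fit of single-rate Brownian motion
#'
#' Closed-form ML estimates: the root state is the GLS mean and the rate is
#' the mean squared standardised contrast (ML scaling, divisor n), both
#' obtained from one pruning pass.
#'
#' @param tree A binary ultrametric `phylo`.
#' @param traits Named numeric tip values.
#' @return List with `sigma2`, `alpha_root`, `loglik`, `n`, `boundary`
#'   (TRUE when the rate estimate collapses to zero, e.g. constant traits).
#' @export
fit_bm_ml <- function(tree, traits) {
  x <- .match_tip_values(tree, traits)
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips")
  tt <- tree_traversal(tree)
  pr <- .bm_prune(tree, x, 1)
  # recover the quadratic form from the unit-rate pruning pass
  n <- tt$n_tip
  q <- .bm_quadform(tree, x, pr$root_value)
  if (q <= 0) {
    warning("trait variance is zero: sigma2 at the boundary")
    return(list(sigma2 = 0, alpha_root = pr$root_value, loglik = NA_real_,
                n = n, boundary = TRUE))
  }
  sigma2 <- q / n
  ll <- bm_loglik(tree, traits, sigma2, pr$root_value)
  list(sigma2 = sigma2, alpha_root = pr$root_value, loglik = ll, n = n,
       boundary = FALSE)
}

.bm_quadform <- function(tree, x, alpha) {
  tt <- tree_traversal(tree)
  n_tip <- tt$n_tip
  xv <- c(x, numeric(tt$n_node))
  sv <- numeric(n_tip + tt$n_node)
  pend_x <- rep(NA_real_, n_tip + tt$n_node)
  pend_v <- rep(NA_real_, n_tip + tt$n_node)
  q <- 0
  for (i in seq_along(tt$child)) {
    ch <- tt$child[i]; p <- tt$parent[i]
    v <- sv[ch] + tt$length[i]
    if (is.na(pend_x[p])) {
      pend_x[p] <- xv[ch]; pend_v[p] <- v
    } else {
      V <- pend_v[p] + v
      q <- q + (pend_x[p] - xv[ch])^2 / V
      xv[p] <- (pend_x[p] * v + xv[ch] * pend_v[p]) / V
      sv[p] <- pend_v[p] * v / V
      pend_x[p] <- NA_real_
    }
  }
  root <- n_tip + 1L
  q + (xv[root] - alpha)^2 / sv[root]
}

#' GLS ancestral state reconstruction for a Brownian trait
#'
#' Maximum-likelihood (generalised-least-squares) estimates of ancestral
#' states at every internal node, with prediction variances that include the
#' uncertainty of the estimated root state. The root estimate equals the
#' fitted root value.
#'
#' @param tree A binary ultrametric `phylo`.
#' @param traits Named numeric tip values.
#' @param params Optional list with `sigma2` and `alpha_root` (e.g. from
#'   [fit_bm_ml()]); fitted by ML when `NULL`.
#' @return data.frame with columns `node`, `estimate`, `variance`.
#' @export
asr_continuous <- function(tree, traits, params = NULL) {
  x <- .match_tip_values(tree, traits)
  if (is.null(params)) params <- fit_bm_ml(tree, traits)
  sigma2 <- params$sigma2; alpha <- params$alpha_root
  n <- ape::Ntip(tree); m <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  Cfull <- matrix(depth[mr], nrow = n + m)
  tipi <- seq_len(n); nodei <- (n + 1L):(n + m)
  Ctt <- Cfull[tipi, tipi]
  Cat <- Cfull[nodei, tipi, drop = FALSE]
  Ctt_inv <- solve(Ctt)
  w <- Cat %*% Ctt_inv
  est <- alpha + as.vector(w %*% (x - alpha))
  one <- rep(1, n)
  denom <- as.numeric(t(one) %*% Ctt_inv %*% one)
  base_var <- diag(Cfull)[nodei] - rowSums(w * Cat)
  alpha_term <- (1 - as.vector(w %*% one))^2 / denom
  vr <- pmax(sigma2 * (base_var + alpha_term), 0)
  if (sigma2 == 0) vr <- sigma2 * 0 + alpha_term  # degenerate, keep shape
  data.frame(node = nodei, estimate = est, variance = vr)
}
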