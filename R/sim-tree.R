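# Forward birth(-death) simulation with explicit lineage records, converted
# to ape phylo objects. Lineages are recorded as (born, ended, fate) so the
# simulator's own event log can be compared against branching_times().

.lineage_env <- function() {
  e <- new.env(parent = emptyenv())
  e$born <- numeric(0); e$ended <- numeric(0)
  e$fate <- character(0)            # "alive", "split", "dead"
  e$kids <- list()
  e
}

.new_lineage <- function(env, t) {
  i <- length(env$born) + 1L
  env$born[i] <- t; env$ended[i] <- NA_real_
  env$fate[i] <- "alive"; env$kids[[i]] <- integer(0)
  i
}

.split_lineage <- function(env, i, t) {
  env$ended[i] <- t; env$fate[i] <- "split"
  k1 <- .new_lineage(env, t); k2 <- .new_lineage(env, t)
  env$kids[[i]] <- c(k1, k2)
  c(k1, k2)
}

# Build an ape phylo from lineage records; `root_kids` are the two lineages
# born at time 0; `present` is total elapsed time.
.records_to_phylo <- function(env, root_kids, present, tip_prefix = "t") {
  env$ended[env$fate == "alive"] <- present
  tips <- which(env$fate != "split")
  splits <- which(env$fate == "split")
  n <- length(tips)
  node_id <- integer(length(env$born))
  node_id[tips] <- seq_len(n)
  splits <- splits[order(env$ended[splits])]
  node_id[splits] <- n + 1L + seq_along(splits)
  root <- n + 1L
  parent_of <- integer(length(env$born))
  for (i in seq_along(env$kids)) for (k in env$kids[[i]]) parent_of[k] <- i
  edge <- matrix(0L, nrow = length(env$born), ncol = 2)
  elen <- numeric(length(env$born))
  for (i in seq_along(env$born)) {
    p <- parent_of[i]
    edge[i, ] <- c(if (p == 0L) root else node_id[p], node_id[i])
    elen[i] <- env$ended[i] - env$born[i]
  }
  tr <- structure(list(
    edge = edge, edge.length = elen, Nnode = n - 1L,
    tip.label = paste0(tip_prefix, seq_len(n))
  ), class = "phylo", order = "cladewise")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a pure-birth (Yule) tree conditioned on tip count
#'
#' Constant-rate pure-birth simulation started from the crown (two lineages).
#' The process runs until the `n_tips`-th lineage is born; the present is an
#' inspection time placed in the following waiting interval, which by
#' memorylessness adds a fresh `Exp(n_tips * lambda)` pendant interval, so
#' every internode interval with k lineages is exactly `Exp(k * lambda)` and
#' the expected crown age is the Yule waiting-time sum. The recorded
#' speciation event ages are attached as attribute `"event_ages"`
#' (descending; first element = crown age).
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param lambda Speciation rate per lineage per Ma (> 0).
#' @param seed Optional integer seed fixing all randomness.
#' @return An ultrametric `phylo` with `n_tips` tips.
#' @export
sim_yule_tree <- function(n_tips, lambda, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!(lambda > 0)) stop("lambda must be > 0")
  if (!is.null(seed)) set.seed(seed)
  env <- .lineage_env()
  root_kids <- c(.new_lineage(env, 0), .new_lineage(env, 0))
  active <- root_kids
  t <- 0
  times <- numeric(0)
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = k * lambda)
    i <- active[sample.int(k, 1L)]
    kids <- .split_lineage(env, i, t)
    active <- c(setdiff(active, i), kids)
    times <- c(times, t)
  }
  # the present falls at a memoryless inspection time while n lineages
  # exist, so the pendant interval beyond the n-th birth is itself
  # Exp(n * lambda); this makes every internode interval exactly Exp(k * lambda)
  present <- t + stats::rexp(1, rate = n_tips * lambda)
  tr <- .records_to_phylo(env, root_kids, present)
  attr(tr, "event_ages") <- sort(present - c(0, times), decreasing = TRUE)
  tr
}

#' Simulate a reconstructed birth-death tree with time-varying rates
#'
#' Forward Gillespie simulation over a fixed duration (the intended crown
#' age), with time-inhomogeneous speciation and extinction honoured by
#' thinning against a rate bound. Extinct lineages are pruned and the
#' replicate is rejected unless at least two lineages survive to the
#' present; rejected replicates are retried up to `retry` times and counted
#' in the `"retries"` attribute.
#'
#' @param duration Crown-to-present time span in Ma.
#' @param lambda_fn,mu_fn Functions of age (Ma before present) returning
#'   non-negative per-lineage rates.
#' @param seed Optional integer seed.
#' @param retry Retry budget for replicates losing all (or all but one)
#'   lineages.
#' @return An ultrametric `phylo` of the surviving lineages with attribute
#'   `"retries"` (number of rejected replicates).
#' @export
sim_bd_tree <- function(duration, lambda_fn, mu_fn = function(t) 0,
                        seed = NULL, retry = 1000) {
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, duration, length.out = 257)
  bound <- max(vapply(grid, function(a) lambda_fn(a) + mu_fn(a), 0)) * 1.05
  if (!is.finite(bound) || bound <= 0) stop("rates must be positive somewhere")
  for (attempt in 0:retry) {
    env <- .lineage_env()
    root_kids <- c(.new_lineage(env, 0), .new_lineage(env, 0))
    active <- root_kids
    t <- 0
    ok <- TRUE
    while (TRUE) {
      k <- length(active)
      if (k == 0L) { ok <- FALSE; break }
      t_cand <- t + stats::rexp(1, rate = k * bound)
      if (t_cand > duration) break
      t <- t_cand
      age <- duration - t
      lam <- lambda_fn(age); mu <- mu_fn(age)
      if (lam < 0 || mu < 0) stop("rate functions must be non-negative")
      u <- stats::runif(1) * bound
      if (u < lam) {
        i <- active[sample.int(k, 1L)]
        kids <- .split_lineage(env, i, t)
        active <- c(setdiff(active, i), kids)
      } else if (u < lam + mu) {
        i <- active[sample.int(k, 1L)]
        env$ended[i] <- t; env$fate[i] <- "dead"
        active <- setdiff(active, i)
      }
    }
    if (ok && length(active) >= 2L) {
      tr <- .records_to_phylo(env, root_kids, duration)
      ages <- node_ages(tr)[seq_len(ape::Ntip(tr))]
      extinct <- tr$tip.label[ages > 1e-10]
      if (length(extinct)) tr <- ape::drop.tip(tr, extinct)
      if (!is.null(tr) && ape::Ntip(tr) >= 2L) {
        tr$tip.label <- paste0("t", seq_len(ape::Ntip(tr)))
        attr(tr, "retries") <- attempt
        return(tr)
      }
    }
  }
  stop("survival not achieved within retry budget")
}
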