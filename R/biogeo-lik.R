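# Time-stratified DEC / DIVALIKE pruning likelihood, marginal ancestral
# ranges, ML fitting and hypothesis comparison.

#' Configuration of a (possibly time-stratified) DEC analysis
#'
#' @param slices Slice boundaries in Ma, strictly decreasing and ending at
#'   0 (e.g. `c(32, 23, 10, 7, 0)` gives four slices); `NULL` for an
#'   unstratified analysis. Branch segments older than the first boundary
#'   use the oldest slice.
#' @param multipliers A single area-by-area dispersal multiplier matrix, or
#'   a list with one matrix per slice (oldest first).
#' @param distances Area-by-area centroid distance matrix (km), needed when
#'   the hypothesis estimates a distance exponent.
#' @param use_distance Whether the distance exponent `x` is a free
#'   parameter of the hypothesis.
#' @param label Optional hypothesis label (e.g. `"Ho1"`).
#' @return Object of class `dec_config`.
#' @export
dec_config <- function(slices = NULL, multipliers = NULL, distances = NULL,
                       use_distance = FALSE, label = NULL) {
  if (!is.null(slices)) {
    if (any(diff(slices) >= 0) || slices[length(slices)] != 0)
      stop("slices must be strictly decreasing and end at 0")
  }
  n_slice <- if (is.null(slices)) 1L else length(slices) - 1L
  if (!is.null(multipliers) && is.matrix(multipliers))
    multipliers <- rep(list(multipliers), n_slice)
  if (!is.null(multipliers) && length(multipliers) != n_slice)
    stop("need one multiplier matrix per slice")
  if (use_distance && is.null(distances))
    stop("use_distance = TRUE needs a distance matrix")
  structure(list(slices = slices, multipliers = multipliers,
                 distances = distances, use_distance = use_distance,
                 label = label),
            class = "dec_config")
}

# Matrix exponential by scaling and squaring with a machine-precision
# Taylor core (dense, state spaces here are <= ~120 states).
.expm_dense <- function(A) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  S <- diag(nrow(A)) + As
  term <- As
  for (k in 2:24) {
    term <- term %*% As / k
    S <- S + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) S <- S %*% S
  S
}

# Flattened cladogenetic event arrays, memoised per (space, model).
.clado_cache <- new.env(parent = emptyenv())

.clado_flat <- function(space, model) {
  key <- paste(model, length(space$ranges),
               paste(space$ranges, collapse = "."), sep = "|")
  hit <- .clado_cache[[key]]
  if (!is.null(hit)) return(hit)
  cw <- cladogenesis_weights(space, model)
  par <- l <- r <- integer(0); w <- numeric(0)
  for (s in seq_along(cw)) {
    if (is.null(cw[[s]])) next
    par <- c(par, rep.int(s, nrow(cw[[s]])))
    l <- c(l, cw[[s]]$left); r <- c(r, cw[[s]]$right)
    w <- c(w, cw[[s]]$weight)
  }
  out <- list(par = par, l = l, r = r, w = w)
  .clado_cache[[key]] <- out
  out
}

# Per-slice propagator factory: returns function(v, dt, slice) = expm(Q dt) %*% v.
# Eigendecomposition is reused across branch segments; ill-conditioned
# eigenbases fall back to dense expm.
.slice_propagators <- function(space, params, config) {
  n_slice <- if (is.null(config$slices)) 1L else length(config$slices) - 1L
  mats <- lapply(seq_len(n_slice), function(i) {
    m <- if (is.null(config$multipliers)) NULL else config$multipliers[[i]]
    build_Q(space, params$d, params$e, x = params$x %||% 0,
            multipliers = m, distances = config$distances)
  })
  props <- lapply(mats, function(Q) {
    eg <- tryCatch(eigen(Q), error = function(e) NULL)
    use_eig <- !is.null(eg) && all(is.finite(Mod(eg$values)))
    if (use_eig) {
      Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
      if (is.null(Vi)) {
        use_eig <- FALSE
      } else {
        # accept the eigenbasis only if it actually reconstructs Q
        recon <- Re(eg$vectors %*% (eg$values * Vi))
        scale <- max(abs(Q), 1e-12)
        if (max(abs(recon - Q)) / scale > 1e-9) use_eig <- FALSE
      }
    }
    if (use_eig) {
      V <- eg$vectors; lam <- eg$values
      function(v, dt) {
        w <- Re(V %*% (exp(lam * dt) * (Vi %*% v)))
        pmax(w, 0)
      }
    } else {
      cache <- new.env(parent = emptyenv())
      function(v, dt) {
        key <- format(dt, digits = 12)
        P <- cache[[key]]
        if (is.null(P)) {
          P <- .expm_dense(Q * dt)
          cache[[key]] <- P
        }
        pmax(as.vector(P %*% v), 0)
      }
    }
  })
  list(props = props, n_slice = n_slice)
}

# Which slice covers ages in [lo, hi)? Slice i covers [slices[i+1], slices[i]);
# anything at or above slices[1] belongs to slice 1.
.slice_of <- function(config, age) {
  if (is.null(config$slices)) return(1L)
  b <- config$slices
  for (i in seq_len(length(b) - 1L)) {
    if (age < b[i] && age >= b[i + 1L]) return(i)
  }
  if (age >= b[1]) return(1L)
  length(b) - 1L
}

# Propagate a conditional-likelihood vector from the bottom (age t_bot) to
# the top (age t_top) of a branch, slicing at stratification boundaries.
.propagate_branch <- function(v, t_bot, t_top, config, pr) {
  if (t_top - t_bot < 1e-12) return(v)
  cuts <- if (is.null(config$slices)) numeric(0) else
    config$slices[config$slices > t_bot + 1e-12 & config$slices < t_top - 1e-12]
  pts <- c(t_bot, sort(cuts), t_top)
  for (i in seq_len(length(pts) - 1L)) {
    lo <- pts[i]; hi <- pts[i + 1L]
    s <- .slice_of(config, (lo + hi) / 2)
    v <- pr$props[[s]](v, hi - lo)
  }
  v
}

# Symmetrised cladogenetic combination of two daughter vectors, vectorised
# over the flattened event arrays.
.combine_clado <- function(fl, D1, D2, n_states) {
  contrib <- fl$w * (D1[fl$l] * D2[fl$r] + D1[fl$r] * D2[fl$l]) / 2
  acc <- rowsum(contrib, fl$par, reorder = FALSE)
  out <- numeric(n_states)
  out[as.integer(rownames(acc))] <- acc
  out
}

.resolve_tip_states <- function(space, tip_ranges, tips) {
  if (is.character(tip_ranges)) stop("tip ranges must be integer bitmasks")
  v <- tip_ranges[tips]
  if (anyNA(v)) stop("missing tip range(s): ",
                     paste(tips[is.na(v)], collapse = ", "))
  if (any(v == 0L)) stop("tips may not have the empty range")
  vapply(v, function(m) .state_of(space, m), 1L)
}

# Shared downpass. Returns per-node combined vectors (N), per-branch
# bottom vectors (D) and top vectors (B), log scaling, and traversal info.
# tip_ranges = NULL runs the "survival" pass in which every tip accepts any
# non-empty range, giving the probability that no sampled lineage died out.
.dec_downpass <- function(tree, tip_ranges, space, params, config, model) {
  stop_if_not_ultrametric(tree)
  tt <- tree_traversal(tree)
  n_tip <- tt$n_tip
  n_all <- n_tip + tt$n_node
  ages <- node_ages(tt$tree)
  clado <- .clado_flat(space, model)
  pr <- .slice_propagators(space, params, config)

  S <- space$n_states
  D <- matrix(0, S, n_all)   # at node (bottom of its branch), after clado/tip
  B <- matrix(0, S, n_all)   # at top of the node's branch (daughter start)
  logscale <- 0
  if (is.null(tip_ranges)) {
    tip_state <- NULL
    D[2:S, seq_len(n_tip)] <- 1
  } else {
    tip_state <- .resolve_tip_states(space, tip_ranges, tt$tree$tip.label)
    for (i in seq_len(n_tip)) D[tip_state[i], i] <- 1
  }
  pend <- integer(n_all)   # 0 = no child seen yet
  for (e in seq_along(tt$child)) {
    ch <- tt$child[e]; p <- tt$parent[e]
    B[, ch] <- .propagate_branch(D[, ch], ages[ch], ages[p], config, pr)
    if (pend[p] == 0L) {
      pend[p] <- ch
    } else {
      c1 <- pend[p]; c2 <- ch
      v <- .combine_clado(clado, B[, c1], B[, c2], S)
      m <- max(v)
      if (m <= 0) return(list(loglik = -Inf))
      D[, p] <- v / m
      logscale <- logscale + log(m)
      pend[p] <- 0L
    }
  }
  root <- n_tip + 1L
  nonempty <- 2:S
  lik <- mean(D[nonempty, root])
  list(loglik = log(lik) + logscale, D = D, B = B, tt = tt, ages = ages,
       clado = clado, pr = pr, tip_state = tip_state, root = root,
       n_tip = n_tip, n_all = n_all, S = S)
}

#' DEC / DIVALIKE log-likelihood
#'
#' Pruning over the tree: conditional likelihood vectors are carried along
#' branches by matrix exponentials of the slice-specific rate matrix
#' (branches cut at slice boundaries) and combined at nodes through the
#' cladogenetic weight tables. The root is weighted uniformly over the
#' allowed non-empty ranges; the empty range is an absorbing anagenetic
#' state excluded from observations and from the root prior.
#'
#' @param tree An ultrametric `phylo`.
#' @param tip_ranges Named integer vector of range bitmasks covering all
#'   tips (see [range_mask()], [read_range_table()]).
#' @param space A `range_space`.
#' @param params List with `d`, `e` and optionally `x`.
#' @param config A [dec_config()] (default: unstratified, no multipliers).
#' @param model `"DEC"` or `"DIVALIKE"`.
#' @param condition_survival Divide by the probability that every sampled
#'   lineage is extant somewhere (no tip in the empty range). The standard
#'   DEC likelihood does not condition (`FALSE`, the default); conditioning
#'   is the consistent choice when the data-generating process discards
#'   histories in which a lineage dies out, as the range-history simulator
#'   does.
#' @return Log-likelihood.
#' @export
dec_loglik <- function(tree, tip_ranges, space, params, config = dec_config(),
                       model = c("DEC", "DIVALIKE"),
                       condition_survival = FALSE) {
  model <- match.arg(model)
  if (space$n_states == 2L) return(0)  # single possible history
  ll <- .dec_downpass(tree, tip_ranges, space, params, config, model)$loglik
  if (condition_survival) {
    ll <- ll -
      .dec_downpass(tree, NULL, space, params, config, model)$loglik
  }
  ll
}

#' Marginal ancestral range probabilities
#'
#' Standard two-pass conditioning: the downpass computes subtree likelihoods
#' and the root-to-tip uppass carries the likelihood of everything outside
#' each node's subtree through the cladogenetic tables and branch
#' propagators; their product, normalised over non-empty ranges, is the
#' marginal probability of each range at each internal node.
#'
#' @inheritParams dec_loglik
#' @return data.frame of class `ancestral_ranges`: one row per internal
#'   node and range with columns `node`, `range`, `prob`; attribute
#'   `"matrix"` holds the node-by-range probability matrix.
#' @export
ancestral_ranges <- function(tree, tip_ranges, space, params,
                             config = dec_config(), model = c("DEC", "DIVALIKE")) {
  model <- match.arg(model)
  dp <- .dec_downpass(tree, tip_ranges, space, params, config, model)
  if (!is.finite(dp$loglik)) stop("data have zero likelihood under these parameters")
  tt <- dp$tt; S <- dp$S; ages <- dp$ages
  U <- matrix(0, S, dp$n_all)          # outside likelihood at node (branch bottom)
  U[2:S, dp$root] <- 1 / (S - 1)
  # children of each internal node, from the postorder edge list
  kids <- split(tt$child, tt$parent)
  # preorder: visit parents before children
  ord <- rev(seq_along(tt$child))
  for (e in ord) {
    ch <- tt$child[e]; p <- tt$parent[e]
    sib <- setdiff(kids[[as.character(p)]], ch)
    # daughter-start weight at the split, seen from ch's side
    fl <- dp$clado
    Bs <- dp$B[, sib]
    base <- U[fl$par, p] * fl$w / 2
    A <- numeric(S)
    a1 <- rowsum(base * Bs[fl$r], fl$l, reorder = FALSE)
    A[as.integer(rownames(a1))] <- A[as.integer(rownames(a1))] + a1
    a2 <- rowsum(base * Bs[fl$l], fl$r, reorder = FALSE)
    A[as.integer(rownames(a2))] <- A[as.integer(rownames(a2))] + a2
    # carry from the top of ch's branch down to ch (transpose propagation)
    U[, ch] <- .propagate_up(A, ages[ch], ages[p], config, dp$pr, space, params)
  }
  nodes <- (dp$n_tip + 1L):dp$n_all
  P <- matrix(0, length(nodes), S - 1L,
              dimnames = list(nodes, space$labels[-1]))
  for (i in seq_along(nodes)) {
    v <- U[, nodes[i]] * dp$D[, nodes[i]]
    v[1] <- 0
    if (sum(v) <= 0) stop("degenerate marginal at node ", nodes[i])
    P[i, ] <- v[-1] / sum(v)
  }
  out <- data.frame(
    node = rep(nodes, each = S - 1L),
    range = rep(space$labels[-1], times = length(nodes)),
    prob = as.vector(t(P))
  )
  attr(out, "matrix") <- P
  class(out) <- c("ancestral_ranges", class(out))
  out
}

# Uppass propagation uses the transpose of the branch transition operator;
# realised by building the per-segment matrices explicitly (state spaces are
# small, <= ~120 states).
.propagate_up <- function(v, t_bot, t_top, config, pr, space, params) {
  if (t_top - t_bot < 1e-12) return(v)
  cuts <- if (is.null(config$slices)) numeric(0) else
    config$slices[config$slices > t_bot + 1e-12 & config$slices < t_top - 1e-12]
  pts <- c(t_bot, sort(cuts), t_top)
  # from top to bottom: v_bottom = t(P_young) %*% ... %*% t(P_old) %*% v_top
  for (i in rev(seq_len(length(pts) - 1L))) {
    lo <- pts[i]; hi <- pts[i + 1L]
    s <- .slice_of(config, (lo + hi) / 2)
    m <- if (is.null(config$multipliers)) NULL else config$multipliers[[s]]
    Q <- build_Q(space, params$d, params$e, x = params$x %||% 0,
                 multipliers = m, distances = config$distances)
    P <- as.matrix(Matrix::expm(Q * (hi - lo)))
    v <- pmax(as.vector(t(P) %*% v), 0)
  }
  v
}

#' Maximum-likelihood DEC / DIVALIKE fit
#'
#' Maximises [dec_loglik()] over `d` and `e` (log scale) and, when the
#' hypothesis includes distance, the exponent `x` (bounded below at 0), by
#' multi-start Nelder-Mead. Boundary estimates (e.g. all tips sharing the
#' root range driving `d` and `e` to zero) are flagged.
#'
#' @inheritParams dec_loglik
#' @param nstart Number of optimiser starts (default 5).
#' @param seed Integer seed for the start jitter (default 1).
#' @return List of class `dec_fit`: `params` (`d`, `e`, `x` or `NA`),
#'   `loglik`, `n_params`, `aic`, `boundary`, `model`, `label`.
#' @export
fit_dec <- function(tree, tip_ranges, space, config = dec_config(),
                    model = c("DEC", "DIVALIKE"), nstart = 5, seed = 1,
                    condition_survival = FALSE) {
  model <- match.arg(model)
  fit_x <- isTRUE(config$use_distance)
  k <- 2L + fit_x
  unpack <- function(p) {
    out <- list(d = exp(p[1]), e = exp(p[2]))
    out$x <- if (fit_x) exp(p[3]) else 0
    out
  }
  negll <- function(p) {
    # rates below ~1e-6 are numerically indistinguishable from zero here
    if (any(!is.finite(p)) || any(p > 12) || any(p < -14)) return(1e10)
    ll <- try(dec_loglik(tree, tip_ranges, space, unpack(p), config, model,
                         condition_survival = condition_survival),
              silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  base <- c(log(0.05), log(0.05), if (fit_x) 0)
  best <- NULL
  for (s in seq_len(nstart)) {
    p0 <- if (s == 1) base else base + stats::rnorm(length(base), 0, 1)
    opt <- try(stats::optim(p0, negll, method = "Nelder-Mead",
                            control = list(maxit = 300, reltol = 1e-9)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10)
    stop("all optimiser starts failed")
  params <- unpack(best$par)
  if (!fit_x) params$x <- NA_real_
  boundary <- any(best$par[1:2] < -13)
  structure(list(params = params, loglik = -best$value, n_params = k,
                 aic = 2 * k + 2 * best$value, boundary = boundary,
                 model = model, label = config$label),
            class = "dec_fit")
}

#' Compare biogeographic hypotheses under DEC and DIVALIKE
#'
#' Fits every hypothesis under each model and assembles a Table-5-style
#' comparison (LnL, parameter count, d, e, x, AIC, delta-AIC; best row
#' flagged).
#'
#' @param tree An ultrametric `phylo`.
#' @param tip_ranges Named integer bitmask vector.
#' @param space A `range_space`.
#' @param hypotheses Named list of [dec_config()] objects.
#' @param models Character vector among `"DEC"`, `"DIVALIKE"`.
#' @param nstart,seed Passed to [fit_dec()].
#' @return data.frame with one row per model x hypothesis.
#' @export
compare_hypotheses <- function(tree, tip_ranges, space, hypotheses,
                               models = c("DEC", "DIVALIKE"), nstart = 5,
                               seed = 1) {
  if (is.null(names(hypotheses))) stop("hypotheses must be a named list")
  rows <- list()
  for (m in models) {
    for (h in names(hypotheses)) {
      f <- fit_dec(tree, tip_ranges, space, hypotheses[[h]], model = m,
                   nstart = nstart, seed = seed)
      rows[[paste(m, h)]] <- data.frame(
        model = m, hypothesis = h, LnL = f$loglik, n_params = f$n_params,
        d = f$params$d, e = f$params$e, x = f$params$x, AIC = f$aic
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$delta_AIC <- out$AIC - min(out$AIC)
  out$best <- out$delta_AIC == 0
  out
}

#' Read a species-by-area presence/absence table
#'
#' Tab-delimited with a `species` column and one 0/1 column per area; the
#' header must name the areas of the state space.
#'
#' @param file Path.
#' @param space A `range_space`.
#' @return Named integer vector of range bitmasks.
#' @export
read_range_table <- function(file, space) {
  x <- utils::read.delim(file, check.names = FALSE)
  if (!("species" %in% names(x))) stop("range table needs a 'species' column")
  miss <- setdiff(space$areas, names(x))
  if (length(miss)) stop("range table lacks area column(s): ",
                         paste(miss, collapse = ", "))
  masks <- vapply(seq_len(nrow(x)), function(i) {
    range_mask(space, space$areas[as.logical(unlist(x[i, space$areas]))])
  }, 1L)
  stats::setNames(masks, x$species)
}

#' Write a species-by-area presence/absence table
#' @param tip_ranges Named integer bitmask vector.
#' @param space A `range_space`.
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_range_table <- function(tip_ranges, space, file) {
  k <- length(space$areas)
  m <- t(vapply(tip_ranges, function(r)
    as.integer(bitwAnd(r, bitwShiftL(1L, 0:(k - 1))) > 0), integer(k)))
  colnames(m) <- space$areas
  out <- cbind(data.frame(species = names(tip_ranges)), as.data.frame(m))
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
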