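# Range state space, anagenetic rate matrix and cladogenetic event tables
# for DEC / DIVALIKE ancestral range estimation. Ranges are encoded as
# bitmasks over the ordered area list; state 1 is always the empty range
# (an absorbing anagenetic state, never observed and never reported).

.popcount <- function(m) {
  n <- integer(length(m))
  while (any(m > 0L)) {
    n <- n + bitwAnd(m, 1L)
    m <- bitwShiftR(m, 1L)
  }
  n
}

.mask_areas <- function(mask, k) which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) > 0L)

.mask_connected <- function(mask, adjacency) {
  areas <- .mask_areas(mask, ncol(adjacency))
  if (length(areas) <= 1L) return(TRUE)
  seen <- areas[1]
  frontier <- areas[1]
  while (length(frontier)) {
    nxt <- setdiff(areas[colSums(adjacency[frontier, areas, drop = FALSE]) > 0],
                   seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(areas)
}

#' Build an adjacency-restricted range state space
#'
#' Enumerates all non-empty subsets of the areas whose size does not exceed
#' `max_size` and whose induced subgraph of the area adjacency graph is
#' connected, plus the empty range. Ordering is deterministic: by range
#' size, then by ascending bitmask. Range connectivity is evaluated on the
#' static adjacency graph; time-slice barriers act through dispersal
#' multipliers, never by pruning the state space, so likelihood vectors are
#' comparable across slices.
#'
#' @param areas Ordered character vector of area labels.
#' @param adjacency Symmetric logical/0-1 matrix over the areas; `NULL`
#'   means complete adjacency.
#' @param max_size Maximum number of areas in a range.
#' @return Object of class `range_space` with elements `areas`, `adjacency`,
#'   `max_size`, `ranges` (integer bitmasks, `ranges[1] = 0`), `labels`,
#'   `index` (bitmask -> state lookup), `n_states`.
#' @export
build_state_space <- function(areas, adjacency = NULL, max_size = length(areas)) {
  k <- length(areas)
  if (k == 0) stop("empty area list")
  if (max_size < 1 || max_size > k) stop("max_size must be in 1..#areas")
  if (is.null(adjacency)) adjacency <- matrix(TRUE, k, k)
  adjacency <- adjacency > 0
  if (!isSymmetric(unname(adjacency * 1))) stop("adjacency must be symmetric")
  dimnames(adjacency) <- list(areas, areas)
  masks <- 1:(2^k - 1)
  masks <- masks[.popcount(masks) <= max_size]
  masks <- masks[vapply(masks, .mask_connected, TRUE, adjacency = adjacency)]
  masks <- masks[order(.popcount(masks), masks)]
  ranges <- c(0L, as.integer(masks))
  labels <- c("()", vapply(masks, function(m)
    paste(areas[.mask_areas(m, k)], collapse = "+"), ""))
  index <- stats::setNames(seq_along(ranges), ranges)
  structure(list(areas = areas, adjacency = adjacency, max_size = max_size,
                 ranges = ranges, labels = labels, index = index,
                 n_states = length(ranges)),
            class = "range_space")
}

#' @method print range_space
#' @export
print.range_space <- function(x, ...) {
  cat(sprintf("range_space: %d areas, max size %d, %d states (incl. empty)\n",
              length(x$areas), x$max_size, x$n_states))
  invisible(x)
}

#' Bitmask of a range given its area labels
#' @param space A `range_space`.
#' @param areas Character vector of area labels (may be empty).
#' @return Integer bitmask.
#' @export
range_mask <- function(space, areas) {
  idx <- match(areas, space$areas)
  if (anyNA(idx)) stop("unknown area(s): ", paste(areas[is.na(idx)], collapse = ", "))
  if (length(idx) == 0) return(0L)
  as.integer(sum(bitwShiftL(1L, idx - 1L)))
}

.state_of <- function(space, mask) {
  s <- space$index[as.character(mask)]
  if (is.na(s)) stop("range not in state space: mask ", mask)
  unname(s)
}

#' Anagenetic DEC rate matrix over ranges
#'
#' Dispersal into area `a` from range `R` proceeds at rate
#' `d * sum_{b in R} m[b, a] * (dist[b, a] / mean_dist)^(-x)`, provided the
#' enlarged range is in the state space; each occupied area is lost at rate
#' `e` (singletons decay into the absorbing empty range). Rows sum to zero.
#'
#' @param space A `range_space`.
#' @param d,e Dispersal and extirpation rates per Ma (>= 0).
#' @param x Distance-decay exponent (>= 0); requires `distances` when > 0.
#' @param multipliers Area-by-area dispersal multiplier matrix in `[0, 1]`
#'   (default all 1).
#' @param distances Area-by-area centroid distances (km); normalised by
#'   their off-diagonal mean so `x` is dimensionless.
#' @return Dense rate matrix over the state space.
#' @export
build_Q <- function(space, d, e, x = 0, multipliers = NULL, distances = NULL) {
  if (is.na(x)) x <- 0
  if (d < 0 || e < 0 || x < 0) stop("d, e and x must be >= 0")
  k <- length(space$areas)
  S <- space$n_states
  if (is.null(multipliers)) multipliers <- matrix(1, k, k)
  if (x > 0) {
    if (is.null(distances)) stop("distance exponent x > 0 needs a distance matrix")
    if (any(!is.finite(distances[upper.tri(distances)])))
      stop("non-finite distances with x > 0")
    dn <- distances / mean(distances[upper.tri(distances) | lower.tri(distances)])
    wdist <- dn^(-x)
  } else {
    wdist <- matrix(1, k, k)
  }
  Q <- matrix(0, S, S)
  bits <- bitwShiftL(1L, 0:(k - 1))
  for (s in 2:S) {
    r <- space$ranges[s]
    occ <- .mask_areas(r, k)
    for (a in setdiff(seq_len(k), occ)) {
      tgt <- bitwOr(r, bits[a])
      ti <- space$index[as.character(tgt)]
      if (is.na(ti)) next
      Q[s, ti] <- d * sum(multipliers[occ, a] * wdist[occ, a])
    }
    for (a in occ) {
      tgt <- bitwAnd(r, bitwNot(bits[a]))
      ti <- space$index[as.character(tgt)]
      if (is.na(ti)) next
      Q[s, ti] <- Q[s, ti] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(space$labels, space$labels)
  Q
}

#' Cladogenetic daughter-range tables
#'
#' For each parent range, the list of permitted daughter-range pairs and
#' their weights (summing to 1). Under `DEC`, a single-area parent is
#' inherited identically; a wider parent either undergoes subset sympatry
#' (one daughter keeps the full range, the other a single member area) or
#' vicariance with one singleton daughter. Under `DIVALIKE`, a single-area
#' parent is inherited identically and a wider parent splits into any
#' ordered pair of disjoint, allowed, non-empty ranges covering it (wide
#' vicariance). At likelihood evaluation the daughter assignment is
#' symmetrised over the two descendant branches.
#'
#' @param space A `range_space`.
#' @param model `"DEC"` or `"DIVALIKE"`.
#' @return List indexed by state; each non-empty state holds a data.frame
#'   with columns `left`, `right` (state indices) and `weight`.
#' @export
cladogenesis_weights <- function(space, model = c("DEC", "DIVALIKE")) {
  model <- match.arg(model)
  k <- length(space$areas)
  bits <- bitwShiftL(1L, 0:(k - 1))
  out <- vector("list", space$n_states)
  for (s in 2:space$n_states) {
    r <- space$ranges[s]
    occ <- .mask_areas(r, k)
    if (length(occ) == 1L) {
      out[[s]] <- data.frame(left = s, right = s, weight = 1)
      next
    }
    L <- integer(0); R <- integer(0)
    if (model == "DEC") {
      for (a in occ) {
        ai <- space$index[as.character(bits[a])]
        # subset sympatry: (R, {a})
        L <- c(L, s); R <- c(R, unname(ai))
        # vicariance with a singleton daughter: ({a}, R \ {a})
        rem <- bitwAnd(r, bitwNot(bits[a]))
        ri <- space$index[as.character(rem)]
        if (!is.na(ri)) { L <- c(L, unname(ai)); R <- c(R, unname(ri)) }
      }
    } else {
      # all ordered vicariant bipartitions into allowed non-empty ranges
      sub <- bitwAnd(r, space$ranges)
      cand <- which(sub == space$ranges & space$ranges != 0L & space$ranges != r)
      for (ui in cand) {
        v <- bitwAnd(r, bitwNot(space$ranges[ui]))
        vi <- space$index[as.character(v)]
        if (!is.na(vi) && v != 0L) { L <- c(L, ui); R <- c(R, unname(vi)) }
      }
    }
    if (!length(L)) stop("parent range has no permitted cladogenetic event: ",
                         space$labels[s])
    out[[s]] <- data.frame(left = L, right = R, weight = 1 / length(L))
  }
  out
}
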