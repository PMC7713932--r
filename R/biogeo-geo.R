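# Example Neotropical geography (areas, adjacency, centroid distances) and
# the eight dispersal-restriction hypotheses, plus the DEC history simulator.
#
# The multiplier values are illustrative defaults (barrier 0.1, open 1.0,
# Panama connectivity stepping 0.1 / 0.25 / 0.5 / 1.0 across the slices);
# analyses of real data should replace them with measured matrices through
# dec_config().

#' Example eight-area Neotropical geography
#'
#' The eight areas used for Neotropical canopy butterflies - Central
#' America, Caribbean, Choco and Caribbean lowlands, Western Andes, Eastern
#' Andes, Amazon (with Chaco and Cerrado), Guianas, Atlantic Forest - with
#' a plausible adjacency graph and great-circle centroid distances computed
#' from rough area centroids. Adjacency and distances are package defaults
#' for examples and simulation studies, not published matrices.
#'
#' @param max_size Maximum range size (default 6).
#' @return List with `space` (a `range_space`), `distances` (km) and
#'   `centroids`.
#' @export
neotropical_geography <- function(max_size = 6) {
  areas <- c("CAm", "Car", "Cho", "WAnd", "EAnd", "Amaz", "Guia", "AtlF")
  cent <- rbind(
    CAm = c(15, -90), Car = c(19, -72), Cho = c(6, -77), WAnd = c(1, -78.5),
    EAnd = c(-3, -77.5), Amaz = c(-5, -63), Guia = c(4, -58.5),
    AtlF = c(-17, -43)
  )
  pairs <- rbind(
    c("CAm", "Car"), c("CAm", "Cho"), c("Car", "Cho"), c("Car", "Guia"),
    c("Cho", "WAnd"), c("WAnd", "EAnd"), c("EAnd", "Amaz"), c("EAnd", "Guia"),
    c("Amaz", "Guia"), c("Amaz", "AtlF"), c("Guia", "AtlF")
  )
  adj <- matrix(FALSE, 8, 8, dimnames = list(areas, areas))
  for (i in seq_len(nrow(pairs))) {
    adj[pairs[i, 1], pairs[i, 2]] <- TRUE
    adj[pairs[i, 2], pairs[i, 1]] <- TRUE
  }
  hav <- function(a, b) {
    rad <- pi / 180
    dlat <- (b[1] - a[1]) * rad; dlon <- (b[2] - a[2]) * rad
    h <- sin(dlat / 2)^2 + cos(a[1] * rad) * cos(b[1] * rad) * sin(dlon / 2)^2
    2 * 6371 * asin(sqrt(h))
  }
  D <- matrix(0, 8, 8, dimnames = list(areas, areas))
  for (i in 1:8) for (j in 1:8) D[i, j] <- hav(cent[i, ], cent[j, ])
  list(space = build_state_space(areas, adj, max_size), distances = D,
       centroids = cent)
}

#' The eight dispersal-restriction hypotheses
#'
#' Builds the Ho1-Ho8 grid of [dec_config()] objects over the four
#' paleogeological time slices (default boundaries 32, 23, 10, 7, 0 Ma):
#' Ho1 no restriction; Ho2 distance only; Ho3 Panama; Ho4 Andes; Ho5
#' distance + Andes; Ho6 distance + Panama; Ho7 Panama + Andes; Ho8 all
#' three. Panama scales dispersal between the Central American/Caribbean
#' block and South America by 0.1, 0.25, 0.5 and 1.0 across the slices
#' (oldest first); the Andes barrier penalises trans-Andean pairs by 0.1 in
#' the two post-uplift slices.
#'
#' @param geography Output of [neotropical_geography()] (or a compatible
#'   list with `space` and `distances`).
#' @param slices Slice boundaries, strictly decreasing, ending at 0.
#' @param barrier Barrier multiplier (default 0.1).
#' @param panama_steps Panama multipliers per slice, oldest first.
#' @return Named list `Ho1`..`Ho8` of `dec_config` objects.
#' @export
dispersal_hypotheses <- function(geography, slices = c(32, 23, 10, 7, 0),
                                 barrier = 0.1,
                                 panama_steps = c(0.1, 0.25, 0.5, 1.0)) {
  areas <- geography$space$areas
  n_slice <- length(slices) - 1L
  if (length(panama_steps) != n_slice)
    stop("need one Panama multiplier per slice")
  ones <- matrix(1, length(areas), length(areas),
                 dimnames = list(areas, areas))
  north <- intersect(c("CAm", "Car"), areas)
  south <- setdiff(areas, north)
  west <- intersect(c("CAm", "Car", "Cho", "WAnd"), areas)
  east <- setdiff(areas, west)
  panama <- lapply(seq_len(n_slice), function(i) {
    m <- ones
    m[north, south] <- panama_steps[i]
    m[south, north] <- panama_steps[i]
    m
  })
  andes <- lapply(seq_len(n_slice), function(i) {
    m <- ones
    if (i > n_slice - 2L) {           # post-uplift slices
      m[west, east] <- barrier
      m[east, west] <- barrier
    }
    m
  })
  both <- lapply(seq_len(n_slice), function(i) panama[[i]] * andes[[i]])
  mk <- function(mult, dist, label)
    dec_config(slices = slices, multipliers = mult,
               distances = if (dist) geography$distances else NULL,
               use_distance = dist, label = label)
  list(
    Ho1 = mk(NULL, FALSE, "Ho1"),
    Ho2 = mk(NULL, TRUE, "Ho2"),
    Ho3 = mk(panama, FALSE, "Ho3"),
    Ho4 = mk(andes, FALSE, "Ho4"),
    Ho5 = mk(andes, TRUE, "Ho5"),
    Ho6 = mk(panama, TRUE, "Ho6"),
    Ho7 = mk(both, FALSE, "Ho7"),
    Ho8 = mk(both, TRUE, "Ho8")
  )
}

#' Simulate a DEC range history on a tree
#'
#' Anagenetic events follow the continuous-time Markov chain defined by the
#' same [build_Q()] rate matrix used by the likelihood (shared code path);
#' cladogenetic daughter ranges are drawn from the same
#' [cladogenesis_weights()] tables. Replicates in which any lineage decays
#' into the empty range are rejected and retried, and the rejections
#' counted.
#'
#' @param tree An ultrametric `phylo`.
#' @param space A `range_space`.
#' @param d,e DEC rates per Ma.
#' @param model `"DEC"` or `"DIVALIKE"`.
#' @param root_range Bitmask of the root range (must be allowed,
#'   non-empty); default: all areas (or the largest allowed range
#'   containing area 1 if that is disallowed).
#' @param config Optional [dec_config()] for stratified simulation.
#' @param seed Optional integer seed.
#' @param retry Rejection budget (default 1000).
#' @return List with `tip_ranges` (named bitmasks), `node_ranges` (bitmask
#'   per internal node, indexed by ape node id), `events` (data.frame of
#'   anagenetic gains/losses with ages) and `rejected` (count).
#' @export
sim_dec_history <- function(tree, space, d, e, model = c("DEC", "DIVALIKE"),
                            root_range = NULL, config = dec_config(),
                            seed = NULL, retry = 1000) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(root_range)) {
    sizes <- .popcount(space$ranges)
    root_range <- space$ranges[which.max(sizes)]
  }
  root_state <- .state_of(space, root_range)
  if (root_range == 0L) stop("root range may not be empty")
  clado <- cladogenesis_weights(space, model)
  n_slice <- if (is.null(config$slices)) 1L else length(config$slices) - 1L
  Qs <- lapply(seq_len(n_slice), function(i) {
    m <- if (is.null(config$multipliers)) NULL else config$multipliers[[i]]
    build_Q(space, d, e, x = 0, multipliers = m,
            distances = config$distances)
  })
  tr <- ape::reorder.phylo(tree, "cladewise")
  ages <- node_ages(tr)
  n_tip <- ape::Ntip(tr)
  n_all <- n_tip + tr$Nnode

  for (attempt in 0:retry) {
    state <- integer(n_all)
    state[n_tip + 1L] <- root_state
    events <- list()
    failed <- FALSE
    # cladogenetic draw at each internal node, then anagenesis along edges
    daughter <- matrix(0L, n_all, 2)
    kid_no <- integer(n_all)
    for (i in seq_len(nrow(tr$edge))) {
      p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
      if (kid_no[p] == 0L) {
        ev <- clado[[state[p]]]
        j <- sample.int(nrow(ev), 1L, prob = ev$weight)
        lr <- c(ev$left[j], ev$right[j])
        if (stats::runif(1) < 0.5) lr <- rev(lr)   # symmetrise daughters
        daughter[p, ] <- lr
      }
      kid_no[p] <- kid_no[p] + 1L
      s <- daughter[p, kid_no[p]]
      # anagenesis from ages[p] down to ages[ch]
      t_now <- ages[p]
      t_end <- ages[ch]
      while (TRUE) {
        sl <- .slice_of(config, max(t_now - 1e-12, t_end))
        rate <- -Qs[[sl]][s, s]
        # time to next slice boundary below t_now
        bnd <- if (is.null(config$slices)) t_end else {
          b <- config$slices[config$slices < t_now - 1e-12]
          if (length(b)) max(t_end, b[1]) else t_end
        }
        if (rate <= 0) { t_now <- bnd } else {
          wait <- stats::rexp(1, rate)
          if (t_now - wait < bnd) { t_now <- bnd } else {
            t_now <- t_now - wait
            probs <- Qs[[sl]][s, ]; probs[s] <- 0
            s_new <- sample.int(length(probs), 1L, prob = pmax(probs, 0))
            events[[length(events) + 1L]] <- data.frame(
              age = t_now, edge = ch, from = s, to = s_new,
              type = if (.popcount(space$ranges[s_new]) >
                           .popcount(space$ranges[s])) "gain" else "loss"
            )
            s <- s_new
            if (space$ranges[s] == 0L) { failed <- TRUE; break }
          }
        }
        if (t_now <= t_end + 1e-12) break
      }
      if (failed) break
      state[ch] <- s
    }
    if (!failed) {
      return(list(
        tip_ranges = stats::setNames(space$ranges[state[seq_len(n_tip)]],
                                     tr$tip.label),
        node_ranges = space$ranges[state[(n_tip + 1L):n_all]],
        events = if (length(events)) do.call(rbind, events) else
          data.frame(age = numeric(0), edge = integer(0), from = integer(0),
                     to = integer(0), type = character(0)),
        rejected = attempt
      ))
    }
  }
  stop("range history hit the empty range in every replicate")
}
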