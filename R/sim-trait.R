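#' Simulate a Brownian trait on a tree, with optional rate shifts and jumps
#'
#' Gaussian increments along each edge with variance `sigma2 * length *`
#' the edge's effective rate multiplier. A shift placed on a branch
#' multiplies the rate of that branch and its whole subtree; a jump adds a
#' fixed displacement at the rootward end of the named branch, so all of its
#' descendants inherit the pulse before drifting on ("pulse then drift").
#' Branches are named by child node id (see [branch_of_clade()]).
#'
#' @param tree A `phylo` object.
#' @param sigma2 Brownian rate, squared trait units per Ma (>= 0).
#' @param root_state Trait value at the root.
#' @param shifts Named numeric vector of rate multipliers, names = branch ids.
#' @param jumps Named numeric vector of jump sizes (trait units), names =
#'   branch ids.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values; internal-node values attached
#'   as attribute `"node_states"`.
#' @export
sim_bm_trait <- function(tree, sigma2, root_state = 0, shifts = NULL,
                         jumps = NULL, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  .check_branch_ids <- function(v, what) {
    if (is.null(v)) return(numeric(0))
    ids <- as.integer(names(v))
    if (anyNA(ids) || any(ids < 1L) || any(ids > n_all) ||
        any(ids == n_tip + 1L))
      stop("unknown branch id in ", what)
    stats::setNames(as.numeric(v), ids)
  }
  shifts <- .check_branch_ids(shifts, "shifts")
  jumps <- .check_branch_ids(jumps, "jumps")

  mult <- rep(1, n_all)
  sub <- subtree_edges(tree)
  for (nm in names(shifts)) {
    idx <- sub[[as.integer(nm)]]
    mult[idx] <- mult[idx] * shifts[[nm]]
  }

  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  state <- numeric(n_all)
  state[n_tip + 1L] <- root_state
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    inc <- stats::rnorm(1, 0, sqrt(sigma2 * mult[ch] * tr$edge.length[i]))
    j <- if (as.character(ch) %in% names(jumps)) jumps[[as.character(ch)]] else 0
    state[ch] <- state[p] + j + inc
  }
  out <- stats::setNames(state[seq_len(n_tip)], tree$tip.label)
  attr(out, "node_states") <- state[(n_tip + 1L):n_all]
  out
}

#' Simulate a wing-region pixel fixture
#'
#' Emulates a photographed wing region whose colour distribution has a
#' dominant modal RGB value plus uniformly random noise pixels, the
#' structure assumed by modal colour measurement. Masked pixels equal
#' `true_mode` with probability `1 - noise_fraction`, otherwise each channel
#' is uniform on 0..255; pixels outside the mask are uniform noise.
#'
#' @param true_mode Integer RGB triple (0-255) of the dominant colour.
#' @param noise_fraction Proportion of noise pixels in the mask, at most
#'   0.45 so the mode stays recoverable with high probability.
#' @param shape Height/width of the image, default `c(50, 50)`.
#' @param mask Logical matrix of the region; default: all pixels.
#' @param seed Optional integer seed.
#' @return A list with `pixels` (H x W x 3 integer array), `mask` (logical
#'   matrix) and `true_mode`.
#' @export
sim_wing_region <- function(true_mode, noise_fraction = 0.2,
                            shape = c(50, 50), mask = NULL, seed = NULL) {
  true_mode <- as.integer(true_mode)
  if (length(true_mode) != 3L || any(true_mode < 0L) || any(true_mode > 255L))
    stop("true_mode must be an RGB triple in 0..255")
  if (noise_fraction < 0 || noise_fraction > 0.45)
    stop("noise_fraction must be in [0, 0.45]")
  if (!is.null(seed)) set.seed(seed)
  h <- shape[1]; w <- shape[2]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  pix <- array(0L, dim = c(h, w, 3L))
  npix <- h * w
  noisy <- matrix(stats::runif(npix) < noise_fraction, h, w)
  noisy[!mask] <- TRUE
  for (c in 1:3) {
    ch <- matrix(true_mode[c], h, w)
    nn <- sum(noisy)
    ch[noisy] <- sample.int(256L, nn, replace = TRUE) - 1L
    pix[, , c] <- ch
  }
  list(pixels = pix, mask = mask, true_mode = true_mode)
}

#' Write synthetic trait and range tables
#'
#' Tab-delimited writers matching the formats the analysis stages read.
#'
#' @param traits Named vector or species-by-trait data.frame (first column
#'   `species` or rownames used as species).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_trait_table <- function(traits, file) {
  if (is.numeric(traits)) {
    traits <- data.frame(species = names(traits), value = unname(traits))
  } else if (!("species" %in% names(traits))) {
    traits <- cbind(species = rownames(traits), as.data.frame(traits))
  }
  utils::write.table(traits, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a tab-delimited trait table
#' @param file Path to a table with a `species` column.
#' @return data.frame with rownames set to species.
#' @export
read_trait_table <- function(file) {
  x <- utils::read.delim(file, check.names = FALSE)
  if (!("species" %in% names(x))) stop("trait table needs a 'species' column")
  rownames(x) <- x$species
  x
}
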