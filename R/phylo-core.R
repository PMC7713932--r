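#' Read and validate a Newick tree
#'
#' Parses a Newick string (or a file containing one) into an [ape::phylo]
#' object and validates the structural assumptions the rest of the package
#' relies on: branch lengths present and non-negative, unique tip labels,
#' and a binary topology. Ages throughout the package are measured in Ma
#' before present, with the present at 0.
#'
#' @param text A Newick string, or the path of a file holding one.
#' @param resolve_polytomies If `TRUE`, polytomies are resolved randomly with
#'   zero-length edges (for robustness experiments). By default polytomies are
#'   rejected, since a dated maximum-clade-credibility tree is binary.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(text, resolve_polytomies = FALSE) {
  if (length(text) != 1L || !is.character(text))
    stop("`text` must be a single character string or file path")
  tr <- if (file.exists(text) && !grepl(";", text, fixed = TRUE)) {
    ape::read.tree(file = text)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  validate_phylo(tr, resolve_polytomies = resolve_polytomies)
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 15)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

validate_phylo <- function(tree, resolve_polytomies = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be present and non-negative")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!ape::is.binary(tree)) {
    if (resolve_polytomies) {
      tree <- ape::multi2di(tree, random = TRUE)
      tree$edge.length[is.na(tree$edge.length)] <- 0
    } else {
      stop("tree contains polytomies (set resolve_polytomies = TRUE to resolve)")
    }
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Node ages (Ma before present)
#'
#' Root-to-node path lengths turned into ages: the deepest tip sits at 0.
#' Works on any rooted tree; for ultrametric trees every tip age is 0.
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `Ntip + Nnode`, indexed by ape node id.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Crown age of a tree
#' @param tree A `phylo` object.
#' @return Age of the root node in Ma.
#' @export
crown_age <- function(tree) {
  unname(node_ages(tree)[ape::Ntip(tree) + 1L])
}

#' Total branch length
#' @param tree A `phylo` object.
#' @return Sum of all edge lengths (Ma).
#' @export
total_branch_length <- function(tree) sum(tree$edge.length)

#' Check a tree for ultrametricity
#'
#' A tree passes when the spread of root-to-tip path lengths does not exceed
#' `tol`. The default tolerance scales with crown age so that numerically
#' dated trees are accepted while genuinely non-clock trees are not. Trees
#' failing the check are rejected by downstream analyses, never silently
#' stretched.
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance in Ma; default `1e-6 *` crown age.
#' @return `TRUE` or `FALSE`.
#' @export
validate_ultrametric <- function(tree, tol = NULL) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (is.null(tol)) tol <- 1e-6 * max(depth)
  (max(depth) - min(depth)) <= tol
}

stop_if_not_ultrametric <- function(tree, tol = NULL) {
  if (!validate_ultrametric(tree, tol))
    stop("tree is not ultrametric within tolerance")
  invisible(tree)
}

#' Branching times of an ultrametric tree
#'
#' Ages of the internal nodes, sorted descending, so the first element is the
#' crown age. These are the data entering every birth-death likelihood.
#'
#' @param tree An ultrametric `phylo` object.
#' @return Numeric vector of `Ntip - 1` ages with attributes `n_tips` and
#'   `total_branch_length`.
#' @export
branching_times <- function(tree) {
  stop_if_not_ultrametric(tree)
  ages <- node_ages(tree)[(ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)]
  ages <- sort(unname(ages), decreasing = TRUE)
  attr(ages, "n_tips") <- ape::Ntip(tree)
  attr(ages, "total_branch_length") <- total_branch_length(tree)
  ages
}

#' Lineage-through-time curve
#'
#' Step curve of the number of reconstructed lineages against age. Starts at
#' 2 at the crown, increments at every internal node, and ends at the number
#' of tips at the present.
#'
#' @param tree An ultrametric `phylo` object.
#' @return A data.frame with columns `time` (Ma before present, descending to
#'   0) and `lineages`.
#' @export
ltt <- function(tree) {
  bt <- branching_times(tree)
  n <- attr(bt, "n_tips")
  data.frame(time = c(bt, 0), lineages = c(2:n, n))
}

#' Drop outgroup tips before analysis
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels to remove.
#' @return The pruned `phylo` object.
#' @export
prune_tips <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  ape::drop.tip(tree, tips)
}

#' Export node ages as a table
#'
#' @param tree A `phylo` object.
#' @param file Optional path; written tab-delimited with columns
#'   `node_id`, `age_Ma`.
#' @return The data.frame, invisibly when written.
#' @export
node_age_table <- function(tree, file = NULL) {
  ages <- node_ages(tree)
  out <- data.frame(node_id = seq_along(ages), age_Ma = ages)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

# Edge id of the branch subtending the MRCA of a set of tips. Branches are
# identified throughout the package by their child node id.
#' Identify a branch by the clade it subtends
#'
#' Branches are named by their child (tipward) node id in ape's numbering.
#' This helper maps a set of tip labels to the branch above their MRCA,
#' which is how jump and shift locations are specified.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (a single label names the
#'   terminal branch).
#' @return The child node id of the stem branch.
#' @export
branch_of_clade <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip label(s)")
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# Postorder edge indices and convenience maps used by pruning algorithms.
tree_traversal <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(
    tree = tree,
    parent = tree$edge[, 1L],
    child = tree$edge[, 2L],
    length = tree$edge.length,
    n_tip = ape::Ntip(tree),
    n_node = tree$Nnode
  )
}

# Descendant edges (by child-node id) of each edge's subtree, including the
# edge itself. Used to apply subtree-wide rate multipliers.
subtree_edges <- function(tree) {
  tt <- tree_traversal(tree)
  res <- vector("list", tt$n_tip + tt$n_node)
  for (i in seq_along(tt$child)) {
    ch <- tt$child[i]
    below <- if (ch <= tt$n_tip) integer(0) else
      unlist(res[tt$child[tt$parent == ch]], use.names = FALSE)
    res[[ch]] <- c(ch, below)
  }
  res
}
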