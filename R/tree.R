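#' Read a rooted phylogenetic tree
#'
#' Reads a newick tree whose leaves are species codes, roots it on the
#' designated outgroup if it is not already rooted appropriately, and
#' validates the leaf set.
#'
#' @param path newick file path.
#' @param outgroup optional outgroup leaf name; required when the input
#'   tree is unrooted.
#' @param species optional character vector: the leaf set must equal it.
#' @return an [ape::read.tree] `phylo` object, rooted.
#' @export
read_tree <- function(path, outgroup = NULL, species = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file ", path, call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (length(tree$tip.label) < 2L) {
    stop("tree in ", path, " has fewer than two leaves", call. = FALSE)
  }
  if (!is.null(species)) {
    if (!setequal(tree$tip.label, species)) {
      stop("tree leaves {", paste(sort(tree$tip.label), collapse = ","),
           "} do not match species {", paste(sort(species), collapse = ","),
           "}", call. = FALSE)
    }
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not a leaf of the tree",
           call. = FALSE)
    }
    if (!ape::is.rooted(tree) || !.is_outgroup(tree, outgroup)) {
      tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    }
  } else if (!ape::is.rooted(tree)) {
    stop("tree in ", path, " is unrooted and no outgroup was supplied",
         call. = FALSE)
  }
  tree
}

# is `tip` attached directly at the root (sister to all other leaves)?
.is_outgroup <- function(tree, tip) {
  root <- ape::Ntip(tree) + 1L
  tip_id <- match(tip, tree$tip.label)
  any(tree$edge[, 1] == root & tree$edge[, 2] == tip_id)
}

#' Leaves descending from a node
#' @param tree a `phylo` object.
#' @param node node id (tip ids are `1..Ntip`).
#' @return character vector of tip labels, sorted.
#' @export
clade_leaves <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  acc <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= ntip) acc <- c(acc, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  sort(tree$tip.label[acc])
}

#' Most recent common ancestor of a set of leaves
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels.
#' @return node id (a tip id when `tips` has length 1).
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

# human-readable node label used in reports: tip name, or MRCA(...) list
.node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  paste0("MRCA(", paste(clade_leaves(tree, node), collapse = ","), ")")
}
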