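#' Fitch parsimony for binary characters on a rooted tree
#'
#' Unit-cost (Fitch) parsimony by dynamic programming: a bottom-up pass
#' computes, for every node and state, the minimal number of changes in the
#' subtree; a top-down pass adds the cost of the rest of the tree, giving
#' for every node the set of states attainable in at least one most
#' parsimonious reconstruction (MPR). The root state can be constrained —
#' the convention used when mapping association characters polarized by an
#' outgroup, where the root is fixed to the outgroup state 0.
#'
#' @param tree a rooted `phylo` object.
#' @param states a named 0/1 vector of leaf states (names = tip labels), or
#'   a `character_matrix`; with a matrix, every character is analyzed.
#' @param root_state optional fixed root state (0 or 1); `NULL` leaves the
#'   root free.
#' @return for a single character, a list with `changes` (the Fitch
#'   minimum) and `node_states` (logical matrix, nodes x states 0/1, `TRUE`
#'   when the state occurs in some MPR); for a matrix, a named list of such
#'   results.
#' @export
fitch_parsimony <- function(tree, states, root_state = NULL) {
  if (inherits(states, "character_matrix") || is.matrix(states)) {
    out <- lapply(colnames(states), function(ch) {
      fitch_parsimony(tree, stats::setNames(states[, ch],
                                            rownames(states)),
                      root_state = root_state)
    })
    names(out) <- colnames(states)
    return(out)
  }
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) {
    stop("leaf without a state: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(states[tree$tip.label] %in% c(0, 1))) {
    stop("states must be binary (0/1)", call. = FALSE)
  }
  post <- ape::reorder.phylo(tree, "postorder")$edge
  down <- matrix(Inf, nrow = nnode, ncol = 2L)  # columns: state 0, state 1
  for (i in seq_len(ntip)) {
    s <- states[[tree$tip.label[i]]]
    down[i, s + 1L] <- 0
  }
  internal <- unique(post[, 1])
  for (v in internal) down[v, ] <- 0
  for (k in seq_len(nrow(post))) {
    p <- post[k, 1]; ch <- post[k, 2]
    for (s in 1:2) {
      down[p, s] <- down[p, s] + min(down[ch, 1] + (s != 1),
                                     down[ch, 2] + (s != 2))
    }
  }
  up <- matrix(Inf, nrow = nnode, ncol = 2L)
  if (is.null(root_state)) {
    up[root, ] <- 0
  } else {
    up[root, root_state + 1L] <- 0
  }
  # pre-order over edges (reverse post-order)
  for (k in rev(seq_len(nrow(post)))) {
    p <- post[k, 1]; ch <- post[k, 2]
    sibs <- post[post[, 1] == p, 2]
    sibs <- sibs[sibs != ch]
    for (s in 1:2) {
      best <- Inf
      for (t in 1:2) {
        cost <- up[p, t] + (t != s)
        for (sb in sibs) {
          cost <- cost + min(down[sb, 1] + (t != 1), down[sb, 2] + (t != 2))
        }
        best <- min(best, cost)
      }
      up[ch, s] <- best
    }
  }
  total <- if (is.null(root_state)) min(down[root, ]) else
    down[root, root_state + 1L]
  node_states <- (down + up) <= total + 1e-9
  colnames(node_states) <- c("0", "1")
  list(changes = as.integer(total), node_states = node_states)
}

#' Exhaustively enumerate most parsimonious reconstructions
#'
#' Brute-force oracle for MPR ambiguity: tries every assignment of 0/1 to
#' the internal nodes, scores the number of state changes over the edges,
#' and returns all assignments achieving the minimum, in deterministic
#' (binary counting, node-ordered) order.
#'
#' @param tree a rooted `phylo` object with at most 12 internal nodes.
#' @param states named 0/1 vector of leaf states.
#' @param root_state optional fixed root state.
#' @return a list with `changes`, `count` and `reconstructions` (list of
#'   named integer vectors over internal node ids).
#' @export
enumerate_mprs <- function(tree, states, root_state = NULL) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  if (nint > 12L) {
    stop("size guard exceeded: ", nint, " internal nodes (max 12)",
         call. = FALSE)
  }
  root <- ntip + 1L
  node_state <- numeric(ntip + nint)
  node_state[seq_len(ntip)] <- states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(0:1), nint),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- as.character(ntip + seq_len(nint))
  if (!is.null(root_state)) {
    grid <- grid[grid[, as.character(root)] == root_state, , drop = FALSE]
  }
  scores <- apply(grid, 1, function(assig) {
    node_state[ntip + seq_len(nint)] <- assig
    sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
  })
  best <- min(scores)
  keep <- which(scores == best)
  recon <- lapply(keep, function(i) {
    stats::setNames(as.integer(grid[i, ]), colnames(grid))
  })
  list(changes = as.integer(best), count = length(keep),
       reconstructions = recon)
}

#' Place rearrangement characters on the study tree
#'
#' The outgroup-polarized placement convention of comparative painting
#' studies: a character present in all ingroup leaves is a single gain at
#' the ingroup's most recent common ancestor; presence in a monophyletic
#' subset is a synapomorphy at that clade's ancestor; presence in a single
#' leaf is a terminal autapomorphy; presence in a non-monophyletic subset
#' is treated as independent (convergent) terminal gains — a loss is never
#' inferred. The report flags every character whose placement is not the
#' unique most parsimonious reconstruction (checked against the Fitch
#' engine with the root constrained to the outgroup state).
#'
#' @param tree rooted `phylo` whose leaves are the matrix taxa.
#' @param cmat a `character_matrix` (see [build_character_matrix()]).
#' @return an object of class `placement_report`: a data.frame with one row
#'   per character (`character`, `placement_type`, `nodes`,
#'   `implied_changes`, `fitch_min`, `mpr_count`, `unique_mpr`,
#'   `annotation`), plus attribute `tree`.
#' @export
place_rearrangements <- function(tree, cmat) {
  stopifnot(inherits(cmat, "character_matrix"))
  outgroup <- attr(cmat, "outgroup")
  miss <- setdiff(tree$tip.label, rownames(cmat))
  if (length(miss)) {
    stop("missing taxon profile: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ingroup <- setdiff(tree$tip.label, outgroup)
  ann <- attr(cmat, "annotations")
  rows <- lapply(colnames(cmat), function(ch) {
    st <- stats::setNames(cmat[tree$tip.label, ch], tree$tip.label)
    S <- names(st)[st == 1L & names(st) %in% ingroup]
    if (length(S) == 0L) {
      return(NULL)
    } else if (setequal(S, ingroup)) {
      type <- "ancestral"
      nodes <- mrca_node(tree, ingroup)
    } else if (length(S) == 1L) {
      type <- "terminal_autapomorphy"
      nodes <- mrca_node(tree, S)
    } else if (setequal(clade_leaves(tree, mrca_node(tree, S)), S)) {
      type <- "clade_synapomorphy"
      nodes <- mrca_node(tree, S)
    } else {
      type <- "convergent_terminal"
      nodes <- vapply(sort(S), function(s) mrca_node(tree, s), 0L)
    }
    implied <- if (type == "convergent_terminal") length(nodes) else 1L
    fit <- fitch_parsimony(tree, st, root_state = 0L)
    mpr <- if (tree$Nnode <= 12L) {
      enumerate_mprs(tree, st, root_state = 0L)$count
    } else NA_integer_
    data.frame(
      character = ch,
      placement_type = type,
      nodes = paste(vapply(nodes, function(n) .node_label(tree, n), ""),
                    collapse = "|"),
      implied_changes = implied,
      fitch_min = fit$changes,
      mpr_count = mpr,
      unique_mpr = !is.na(mpr) && mpr == 1L && implied == fit$changes,
      annotation = if (ch %in% names(ann)) ann[[ch]] else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(character = character(), placement_type = character(),
                      nodes = character(), implied_changes = integer(),
                      fitch_min = integer(), mpr_count = integer(),
                      unique_mpr = logical(), annotation = character())
  }
  rownames(out) <- out$character
  structure(out, class = c("placement_report", class(out)), tree = tree)
}

#' @export
print.placement_report <- function(x, ...) {
  cat("<placement report> ", nrow(x), " characters\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Write a tree annotated with gained characters
#'
#' Node labels list the characters placed at each node (joined by `&`), so
#' the newick can be inspected in standard tree viewers.
#'
#' @param report a `placement_report`.
#' @param path output newick path.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(report, path) {
  tree <- attr(report, "tree")
  ntip <- ape::Ntip(tree)
  labels <- character(tree$Nnode)
  tip_extra <- character(ntip)
  for (i in seq_len(nrow(report))) {
    node_labels <- strsplit(report$nodes[i], "|", fixed = TRUE)[[1]]
    for (nl in node_labels) {
      if (nl %in% tree$tip.label) {
        j <- match(nl, tree$tip.label)
        tip_extra[j] <- paste(c(tip_extra[j][nzchar(tip_extra[j])],
                                report$character[i]), collapse = "&")
      } else {
        leaves <- strsplit(sub("^MRCA\\((.*)\\)$", "\\1", nl), ",")[[1]]
        node <- mrca_node(tree, leaves) - ntip
        labels[node] <- paste(c(labels[node][nzchar(labels[node])],
                                report$character[i]), collapse = "&")
      }
    }
  }
  out <- tree
  out$node.label <- gsub("/", "_", labels)
  out$tip.label <- ifelse(nzchar(tip_extra),
                          paste0(tree$tip.label, "_",
                                 gsub("/", "_", tip_extra)),
                          tree$tip.label)
  ape::write.tree(out, file = path)
  invisible(path)
}
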