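#' Default tree for recovery experiments
#'
#' The four-taxon study design: three ingroup tips in a ladder plus an
#' outgroup attached at the root with a zero-length branch, so the outgroup
#' profile is always the identity (no events accumulate on its branch).
#'
#' @param ingroup tip labels for the three ingroup taxa.
#' @param outgroup outgroup tip label.
#' @return a rooted `phylo`.
#' @export
default_recovery_tree <- function(ingroup = c("A", "B", "C"),
                                  outgroup = "OUT") {
  stopifnot(length(ingroup) == 3L)
  txt <- sprintf("(((%s:1,%s:1):1,%s:1):1,%s:0);",
                 ingroup[1], ingroup[2], ingroup[3], outgroup)
  ape::read.tree(text = txt)
}

# expected placement node label for an event on the branch above `child`
.expected_node_label <- function(tree, child_label) {
  leaves <- strsplit(child_label, ",", fixed = TRUE)[[1]]
  .node_label(tree, mrca_node(tree, leaves))
}

#' Simulate, analyze and score one replicate
#' @noRd
.recovery_replicate <- function(tree, rates, seed, noise, outgroup,
                                root_karyotype) {
  hist <- simulate_history(tree, root_karyotype = root_karyotype,
                           rates = rates, seed = seed)
  tips <- names(hist$tip_karyotypes)
  maps <- lapply(tips, function(tp) project_painting(hist, tp,
                                                     noise = noise))
  profiles <- lapply(maps, extract_syntenic_associations)
  names(profiles) <- tips
  cmat <- build_character_matrix(profiles, outgroup = outgroup)
  placed <- if (ncol(cmat)) place_rearrangements(tree, cmat) else NULL
  registry <- history_fusion_registry(hist)

  # --- placement accuracy over fusion joints -------------------------------
  n_fusions <- nrow(registry)
  single <- !(duplicated(registry$adjacency) |
                duplicated(registry$adjacency, fromLast = TRUE))
  correct <- logical(n_fusions)
  if (n_fusions) {
    for (i in seq_len(n_fusions)) {
      ch <- registry$adjacency[i]
      expected <- .expected_node_label(tree, registry$branch[i])
      got <- if (!is.null(placed) && ch %in% placed$character) {
        placed$nodes[match(ch, placed$character)]
      } else ""
      correct[i] <- identical(got, expected)
    }
  }

  # --- false associations (observed but never created by an event) ---------
  observed <- sort(unique(unlist(lapply(profiles[setdiff(tips, outgroup)],
                                        function(p) p$associations))))
  false_assoc <- setdiff(observed, registry$adjacency)

  # --- plesiomorphy recovery ------------------------------------------------
  # truth from the simulator state (event-log replay), independent of the
  # painting projection/extraction path
  state_intact <- function(kar) {
    ids <- vapply(kar$chroms, `[[`, "", "id")
    root_of <- lapply(kar$chroms, function(ch) unique(.seg_root(c(ch$p,
                                                                  ch$q))))
    solo <- unlist(root_of[lengths(root_of) == 1L])
    # a root chromosome is intact when some chromosome carries it alone and
    # none of its segments sit elsewhere
    vapply(unique(solo), function(rr) {
      sum(vapply(root_of, function(x) rr %in% x, TRUE)) == 1L
    }, TRUE) -> ok
    sort_chroms(setdiff(unique(solo)[ok], c("X", "Y")))
  }
  replayed <- replay_history(hist)
  truth_out <- state_intact(replayed[[outgroup]])
  truth_in <- sort_chroms(unique(unlist(
    lapply(replayed[setdiff(tips, outgroup)], state_intact))))
  truth_plesio <- intersect(truth_out, truth_in)
  inferred <- infer_plesiomorphic_chromosomes(profiles, outgroup)
  plesio_rec <- if (length(truth_plesio)) {
    length(intersect(inferred, truth_plesio)) / length(truth_plesio)
  } else 1

  data.frame(
    n_events = nrow(hist$events),
    n_fusions = n_fusions,
    n_single_origin = sum(single),
    placement_accuracy = if (n_fusions) mean(correct) else 1,
    single_origin_accuracy = if (any(single)) mean(correct[single]) else 1,
    false_association_rate = if (length(observed))
      length(false_assoc) / length(observed) else 0,
    plesiomorphy_recovery = plesio_rec)
}

#' Recovery experiment: simulate, project, analyze, place
#'
#' Runs replicate simulations at the given rates, pushes each through the
#' full analysis chain (painting projection, association extraction,
#' character matrix, placement) and scores the result against the event
#' log: the fraction of fusion joints placed on their true branch (overall
#' and among single-origin joints), the fraction of observed associations
#' never created by an event (false associations), and recovery of the
#' plesiomorphic chromosome set.
#'
#' @param tree rooted `phylo` with an outgroup tip
#'   (default [default_recovery_tree()]).
#' @param rates named per-kind event rates (see [simulate_history()]).
#' @param replicates number of replicates.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param noise ambiguity noise passed to [project_painting()].
#' @param outgroup outgroup tip label.
#' @param root_karyotype root `sim_karyotype`.
#' @return data.frame with one row per replicate and the metric columns
#'   described above.
#' @export
recovery_experiment <- function(tree = default_recovery_tree(),
                                rates = c(rb_fusion = 0.5),
                                replicates = 50L, seed = 1L, noise = 0,
                                outgroup = "OUT",
                                root_karyotype = make_sim_root()) {
  stopifnot(replicates >= 1L, replicates <= 1e4)
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a tip of the tree",
         call. = FALSE)
  }
  rows <- lapply(seq_len(replicates), function(r) {
    out <- .recovery_replicate(tree, rates, seed = seed + r, noise = noise,
                               outgroup = outgroup,
                               root_karyotype = root_karyotype)
    cbind(replicate = r, out)
  })
  do.call(rbind, rows)
}
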