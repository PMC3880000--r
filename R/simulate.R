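#' Karyotype evolution simulator
#'
#' Simulates rearrangement histories along a tree and projects painting
#' style homology maps with known ground truth, so that every analysis
#' stage (map validation, association extraction, character building,
#' placement) can be exercised against a known answer.
#'
#' A simulated chromosome is an ordered list of uniquely labeled arm
#' segments (the atomic unit of the generator is the ancestral chromosome
#' arm): `p` runs pter to centromere, `q` centromere to qter. Content is
#' conserved: events rearrange segments, never gain or lose them.
#'
#' @name karyo_sim
NULL

#' Rearrangement event kinds known to the simulator
#' @format character vector of event-kind names.
#' @export
EVENT_KINDS <- c("rb_fusion", "rb_fission", "tandem_fusion",
                 "pericentric_inversion", "whole_arm_translocation")

.sim_chrom <- function(id, p, q, morph) {
  list(id = id, p = p, q = q, morph = morph)
}

.is_acro <- function(ch) ch$morph == "acrocentric"

.seg_root <- function(segs) sub("[pq]$", "", segs)

#' Default root karyotype for simulations
#'
#' Mimics the hypothesized ancestral phyllostomid condition: 22 autosome
#' pairs of which 8 are bi-armed (2n = 46, FN = 60), plus an inert bi-armed
#' X. Fully configurable.
#'
#' @param n_autosomes number of autosome pairs.
#' @param n_biarmed how many of them are bi-armed.
#' @param species species code for the simulated ancestor.
#' @return an object of class `sim_karyotype`.
#' @export
make_sim_root <- function(n_autosomes = 22L, n_biarmed = 8L,
                          species = "ANC") {
  stopifnot(n_autosomes >= 1L, n_biarmed >= 0L, n_biarmed <= n_autosomes)
  chroms <- lapply(seq_len(n_autosomes), function(i) {
    id <- as.character(i)
    if (i <= n_biarmed) {
      .sim_chrom(id, paste0(id, "p"), paste0(id, "q"), "submetacentric")
    } else {
      .sim_chrom(id, character(), paste0(id, "q"), "acrocentric")
    }
  })
  chroms <- c(chroms, list(.sim_chrom("X", "Xp", "Xq", "submetacentric")))
  structure(list(species = species, chroms = chroms,
                 sex = "X"), class = "sim_karyotype")
}

#' @export
print.sim_karyotype <- function(x, ...) {
  k <- as_karyotype(x)
  cat("<simulated karyotype> ", x$species, ": 2n = ", diploid_number(k),
      ", FN = ", compute_fundamental_number(k), " (",
      length(x$chroms) - 1L, " autosome pairs)\n", sep = "")
  invisible(x)
}

#' Convert a simulated karyotype to a [karyotype] object
#' @param sim a `sim_karyotype`.
#' @return a [karyotype].
#' @export
as_karyotype <- function(sim) {
  stopifnot(inherits(sim, "sim_karyotype"))
  karyotype(sim$species, data.frame(
    chrom = vapply(sim$chroms, `[[`, "", "id"),
    morphology = vapply(sim$chroms, `[[`, "", "morph"),
    is_sex = vapply(sim$chroms, `[[`, "", "id") %in% c("X", "Y"),
    stringsAsFactors = FALSE))
}

.sim_autosome_ids <- function(kar) {
  ids <- vapply(kar$chroms, `[[`, "", "id")
  ids[!ids %in% c("X", "Y")]
}

.sim_get <- function(kar, id) {
  ids <- vapply(kar$chroms, `[[`, "", "id")
  kar$chroms[[match(id, ids)]]
}

.sim_drop <- function(kar, ids) {
  keep <- !vapply(kar$chroms, `[[`, "", "id") %in% ids
  kar$chroms <- kar$chroms[keep]
  kar
}

# feasible operand universe per event kind (autosomes only)
.feasible_operands <- function(kar, kind) {
  ids <- .sim_autosome_ids(kar)
  chs <- lapply(ids, function(i) .sim_get(kar, i))
  acro <- ids[vapply(chs, .is_acro, TRUE)]
  biarmed_p <- ids[vapply(chs, function(c) length(c$p) > 0L, TRUE)]
  switch(kind,
    rb_fusion = if (length(acro) >= 2L) list(pool = acro, k = 2L),
    rb_fission = if (length(biarmed_p) >= 1L) list(pool = biarmed_p, k = 1L),
    tandem_fusion = if (length(ids) >= 2L) list(pool = ids, k = 2L),
    pericentric_inversion = if (length(ids) >= 1L) list(pool = ids, k = 1L),
    whole_arm_translocation = if (length(biarmed_p) >= 2L)
      list(pool = biarmed_p, k = 2L))
}

#' Apply one rearrangement event to a simulated karyotype
#'
#' Robertsonian (centric) fusion joins two acrocentrics into one metacentric
#' (2n - 2, FN unchanged); Robertsonian fission is its inverse; tandem
#' fusion appends one chromosome end-to-end to another (2n - 2, FN reduced
#' by the arms lost); pericentric inversion toggles the morphology class
#' (and moves the centromere where segment boundaries allow) without
#' changing synteny; whole-arm translocation exchanges whole arms between
#' two bi-armed chromosomes (fission plus crosswise fusion).
#'
#' @param karyotype a `sim_karyotype`.
#' @param event a list with `kind` (an element of [EVENT_KINDS]),
#'   `chroms` (operand chromosome ids) and optional `params`.
#' @return the rearranged `sim_karyotype`.
#' @export
apply_event <- function(karyotype, event) {
  kar <- karyotype
  kind <- event$kind
  ids <- event$chroms
  if (!kind %in% EVENT_KINDS) stop("unknown event kind: ", kind,
                                   call. = FALSE)
  present <- vapply(kar$chroms, `[[`, "", "id")
  if (!all(ids %in% present)) {
    stop("infeasible operand: ", paste(setdiff(ids, present),
                                       collapse = ", "), call. = FALSE)
  }
  if (kind == "rb_fusion") {
    a <- .sim_get(kar, ids[1]); b <- .sim_get(kar, ids[2])
    if (!.is_acro(a) || !.is_acro(b)) {
      stop("rb_fusion requires two acrocentric chromosomes", call. = FALSE)
    }
    new <- .sim_chrom(paste(ids, collapse = "."),
                      p = rev(a$q), q = b$q, morph = "metacentric")
    kar <- .sim_drop(kar, ids)
    kar$chroms <- c(kar$chroms, list(new))
  } else if (kind == "rb_fission") {
    a <- .sim_get(kar, ids[1])
    if (length(a$p) == 0L) {
      stop("rb_fission requires a bi-armed chromosome", call. = FALSE)
    }
    c1 <- .sim_chrom(paste0(a$id, ".1"), character(), rev(a$p),
                     "acrocentric")
    c2 <- .sim_chrom(paste0(a$id, ".2"), character(), a$q, "acrocentric")
    kar <- .sim_drop(kar, ids[1])
    kar$chroms <- c(kar$chroms, list(c1, c2))
  } else if (kind == "tandem_fusion") {
    a <- .sim_get(kar, ids[1]); b <- .sim_get(kar, ids[2])
    new <- .sim_chrom(paste(ids, collapse = "."),
                      p = a$p, q = c(a$q, rev(b$p), b$q), morph = a$morph)
    kar <- .sim_drop(kar, ids)
    kar$chroms <- c(kar$chroms, list(new))
  } else if (kind == "pericentric_inversion") {
    a <- .sim_get(kar, ids[1])
    if (.is_acro(a)) {
      # move the centromere into the arm where a segment boundary allows;
      # with a single segment the new short arm is below paint resolution
      k <- if (!is.null(event$params$split)) event$params$split else
        max(0L, length(a$q) - 1L)
      k <- min(max(k, 0L), length(a$q) - 1L)
      new_morph <- if (!is.null(event$params$morph)) event$params$morph else
        "subtelocentric"
      if (k > 0L) {
        a$p <- rev(a$q[seq_len(k)])
        a$q <- a$q[-seq_len(k)]
      }
      a$morph <- new_morph
    } else {
      a$q <- c(rev(a$p), a$q)
      a$p <- character()
      a$morph <- "acrocentric"
    }
    kar <- .sim_drop(kar, ids[1])
    kar$chroms <- c(kar$chroms, list(a))
  } else if (kind == "whole_arm_translocation") {
    a <- .sim_get(kar, ids[1]); b <- .sim_get(kar, ids[2])
    if (length(a$p) == 0L || length(b$p) == 0L) {
      stop("whole_arm_translocation requires two bi-armed chromosomes",
           call. = FALSE)
    }
    c1 <- .sim_chrom(paste0(ids[1], "~", ids[2], ".1"),
                     p = a$p, q = b$q, morph = "metacentric")
    c2 <- .sim_chrom(paste0(ids[1], "~", ids[2], ".2"),
                     p = b$p, q = a$q, morph = "metacentric")
    kar <- .sim_drop(kar, ids)
    kar$chroms <- c(kar$chroms, list(c1, c2))
  }
  kar
}

# root-chromosome adjacencies created by an event (unordered pairs of
# distinct root chromosome ids at the new joints)
.event_adjacencies <- function(kar_before, event) {
  joint <- function(seg_a, seg_b) {
    ra <- .seg_root(seg_a); rb <- .seg_root(seg_b)
    if (identical(ra, rb)) return(NULL)
    canonical_association(ra, rb)
  }
  ids <- event$chroms
  if (event$kind == "rb_fusion") {
    a <- .sim_get(kar_before, ids[1]); b <- .sim_get(kar_before, ids[2])
    out <- joint(a$q[1], b$q[1])
  } else if (event$kind == "tandem_fusion") {
    a <- .sim_get(kar_before, ids[1]); b <- .sim_get(kar_before, ids[2])
    a_end <- if (length(a$q)) a$q[length(a$q)] else a$p[1]
    b_start <- if (length(b$p)) b$p[1] else b$q[1]
    out <- joint(a_end, b_start)
  } else if (event$kind == "whole_arm_translocation") {
    a <- .sim_get(kar_before, ids[1]); b <- .sim_get(kar_before, ids[2])
    out <- c(joint(a$p[length(a$p)], b$q[1]),
             joint(b$p[length(b$p)], a$q[1]))
  } else {
    out <- NULL
  }
  out
}

# stable, traversal-order-independent 31-bit hash of a string
.stable_hash <- function(x) {
  h <- 0
  for (cc in utf8ToInt(x)) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

# edge label: sorted tip set below the child node
.edge_label <- function(tree, child) {
  paste(clade_leaves(tree, child), collapse = ",")
}

#' Simulate a rearrangement history along a tree
#'
#' Per-branch event counts are drawn from a Poisson law with mean
#' rate x branch length for each event kind; events are applied
#' sequentially with operand feasibility checks. Randomness is fully
#' reproducible: a single root seed is combined with a stable hash of each
#' edge's descendant tip set, so subtree simulations do not depend on
#' traversal order.
#'
#' @param tree rooted `phylo`; missing branch lengths are taken as 1.
#' @param root_karyotype a `sim_karyotype` (default [make_sim_root()]).
#' @param rates named numeric vector of per-kind event rates per unit
#'   branch length (names among [EVENT_KINDS]).
#' @param seed integer seed.
#' @param retry_budget attempts to find feasible operands per event before
#'   giving up.
#' @return an object of class `sim_history`: `tree`, `root`, `events`
#'   (data.frame: branch, kind, operands, adjacency), `tip_karyotypes`
#'   (named list of `sim_karyotype`), `seed`, `rates`.
#' @export
simulate_history <- function(tree, root_karyotype = make_sim_root(),
                             rates = c(rb_fusion = 0.5), seed = 1L,
                             retry_budget = 100L) {
  stopifnot(all(names(rates) %in% EVENT_KINDS), all(rates >= 0))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kinds <- names(rates)[rates > 0]
  state <- vector("list", ntip + tree$Nnode)
  state[[root]] <- root_karyotype
  events <- list()
  # preorder over edges so the parent state exists before each branch
  post <- ape::reorder.phylo(tree, "postorder")$edge
  lens <- tree$edge.length[match(paste(post[, 1], post[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  ord <- rev(seq_len(nrow(post)))
  for (k in ord) {
    parent <- post[k, 1]; child <- post[k, 2]
    bl <- lens[k]
    label <- .edge_label(tree, child)
    sub_seed <- (abs(seed) %% 1000003L) * 2039L + .stable_hash(label)
    sub_seed <- as.integer(sub_seed %% 2147483647)
    kar <- state[[parent]]
    branch_events <- local({
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(sub_seed)
      counts <- stats::setNames(
        vapply(kinds, function(kk) stats::rpois(1L, rates[[kk]] * bl), 0L),
        kinds)
      sched <- rep(names(counts), counts)
      if (length(sched) > 1L) sched <- sample(sched)
      evs <- list()
      for (kind in sched) {
        # infeasible events are resampled among the rate-positive kinds
        # that still have operands, within the retry budget
        attempt <- 0L
        repeat {
          attempt <- attempt + 1L
          feas <- .feasible_operands(kar, kind)
          if (!is.null(feas)) break
          open <- kinds[!vapply(kinds, function(kk)
            is.null(.feasible_operands(kar, kk)), TRUE)]
          if (!length(open) || attempt >= retry_budget) {
            stop("retry budget exhausted: no feasible operands for ",
                 kind, " on branch ", label, call. = FALSE)
          }
          kind <- if (length(open) == 1L) open else sample(open, 1L)
        }
        ids <- if (feas$k == 1L && length(feas$pool) == 1L) feas$pool else
          sample(feas$pool, feas$k)
        ev <- list(kind = kind, chroms = ids, params = list())
        if (kind == "pericentric_inversion") {
          a <- .sim_get(kar, ids[1])
          if (.is_acro(a)) {
            ev$params$split <- sample.int(max(length(a$q), 1L), 1L) - 1L
            ev$params$morph <- sample(c("subtelocentric", "submetacentric",
                                        "metacentric"), 1L)
          }
        }
        ev$adjacency <- .event_adjacencies(kar, ev)
        kar <<- apply_event(kar, ev)
        evs[[length(evs) + 1L]] <- ev
      }
      evs
    })
    for (ev in branch_events) {
      events[[length(events) + 1L]] <-
        data.frame(branch = label, kind = ev$kind,
                   operands = paste(ev$chroms, collapse = ","),
                   adjacency = if (length(ev$adjacency))
                     paste(ev$adjacency, collapse = ";") else "",
                   split = if (length(ev$params$split))
                     ev$params$split else NA_integer_,
                   morph = if (length(ev$params$morph))
                     ev$params$morph else "",
                   stringsAsFactors = FALSE)
    }
    state[[child]] <- kar
  }
  tips <- stats::setNames(state[seq_len(ntip)], tree$tip.label)
  for (i in seq_len(ntip)) tips[[i]]$species <- tree$tip.label[i]
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(), kind = character(),
               operands = character(), adjacency = character(),
               split = integer(), morph = character())
  structure(list(tree = tree, root = root_karyotype, events = events,
                 tip_karyotypes = tips, seed = as.integer(seed),
                 rates = rates, retry_budget = retry_budget),
            class = "sim_history")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.sim_history <- function(x, ...) {
  cat("<simulated history> ", length(x$tip_karyotypes), " tips, ",
      nrow(x$events), " events (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Fusion adjacencies recorded in a history's event log
#'
#' @param history a `sim_history`.
#' @return data.frame with `branch` and `adjacency` (canonical pair name),
#'   one row per joint created by a fusion or whole-arm translocation.
#' @export
history_fusion_registry <- function(history) {
  ev <- history$events
  ev <- ev[nzchar(ev$adjacency), , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(branch = character(), kind = character(),
                      adjacency = character()))
  }
  adj <- strsplit(ev$adjacency, ";", fixed = TRUE)
  data.frame(branch = rep(ev$branch, lengths(adj)),
             kind = rep(ev$kind, lengths(adj)),
             adjacency = unlist(adj), stringsAsFactors = FALSE)
}

# unordered root-chromosome adjacencies present in a simulated karyotype
.state_adjacencies <- function(kar) {
  out <- character()
  for (ch in kar$chroms) {
    roots <- .seg_root(c(ch$p, ch$q))
    if (length(roots) < 2L) next
    runs <- rle(roots)$values
    if (length(runs) < 2L) next
    for (i in seq_len(length(runs) - 1L)) {
      out <- c(out, canonical_association(runs[i], runs[i + 1L]))
    }
  }
  sort(unique(out))
}

#' Project a painting experiment onto a simulated tip
#'
#' Emulates hybridization of root-species paints onto the tip karyotype:
#' consecutive segments from one root chromosome collapse into one painted
#' block (the generator's atomic unit is the ancestral arm, so arm and
#' block resolution coincide; sub-arm breakpoints never arise). Optional
#' ambiguity noise reports an `or` alternative (a different root
#' chromosome) for a block with the given probability, mimicking signals
#' that cannot be assigned unambiguously.
#'
#' @param history a `sim_history`.
#' @param tip tip label.
#' @param resolution `"arm"` or `"block"` (identical here; see above).
#' @param noise per-block probability of an ambiguous alternative.
#' @param seed seed for the noise channel (default derived from the
#'   history's seed and the tip name).
#' @return a region-type `homology_map` from the tip species back to the
#'   root species.
#' @export
project_painting <- function(history, tip, resolution = c("arm", "block"),
                             noise = 0, seed = NULL) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(history, "sim_history"))
  if (!tip %in% names(history$tip_karyotypes)) {
    stop("unknown tip: ", tip, call. = FALSE)
  }
  kar <- history$tip_karyotypes[[tip]]
  root_ids <- vapply(history$root$chroms, `[[`, "", "id")
  rows <- list()
  if (is.null(seed)) seed <- history$seed + .stable_hash(tip) %% 10000L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483647))
  for (ci in seq_along(kar$chroms)) {
    ch <- kar$chroms[[ci]]
    tc <- as.character(ci)
    if (ch$id %in% c("X", "Y")) tc <- ch$id
    segs <- c(ch$p, ch$q)
    cen <- length(ch$p)
    roots <- .seg_root(segs)
    r <- rle(roots)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nb <- length(r$values)
    for (j in seq_len(nb)) {
      src_chrom <- r$values[j]
      span <- segs[starts[j]:ends[j]]
      arms <- unique(sub("^.*([pq])$", "\\1", span))
      root_ch <- history$root$chroms[[match(src_chrom, root_ids)]]
      whole <- length(span) == length(c(root_ch$p, root_ch$q))
      src_region <- if (whole || length(arms) > 1L) src_chrom else
        paste0(src_chrom, arms)
      tr <- .project_region(tc, starts[j], ends[j], cen, length(segs),
                            j, nb)
      alt <- ""
      if (noise > 0 && stats::runif(1) < noise) {
        others <- setdiff(root_ids, c(src_chrom, "X", "Y"))
        if (length(others)) alt <- sample(others, 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        target_chrom = tc, order_index = j, target_region = tr,
        source_region = src_region, alternatives = alt, flags = "",
        stringsAsFactors = FALSE)
    }
  }
  homology_map(tip, history$root$species, do.call(rbind, rows))
}

# synthesize a target region label from block extent and centromere index
.project_region <- function(chrom, start, end, cen, n, j, nb) {
  if (start == 1L && end == n) return(chrom)
  in_p <- end <= cen
  in_q <- start > cen
  if (in_p) {
    if (start == 1L && end == cen) return(paste0(chrom, "p"))
    if (start == 1L) return(paste0(chrom, "pt"))
    if (end == cen) return(paste0(chrom, "pp"))
    return(paste0(chrom, "pi"))
  }
  if (in_q) {
    if (start == cen + 1L && end == n) return(paste0(chrom, "q"))
    if (start == cen + 1L) return(paste0(chrom, "qp"))
    if (end == n) return(paste0(chrom, "qt"))
    return(paste0(chrom, "qi"))
  }
  left <- if (start == 1L) "p" else "pp"
  right <- if (end == n) "q" else "qp"
  paste0(chrom, left, "/", right)
}

#' Replay a simulated history from its event log
#'
#' Re-applies the recorded events from the root karyotype; used to verify
#' that the log fully determines every tip (replay determinism).
#'
#' @param history a `sim_history`.
#' @return named list of `sim_karyotype` tips.
#' @export
replay_history <- function(history) {
  tree <- history$tree
  ntip <- ape::Ntip(tree)
  state <- vector("list", ntip + tree$Nnode)
  state[[ntip + 1L]] <- history$root
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in rev(seq_len(nrow(post)))) {
    parent <- post[k, 1]; child <- post[k, 2]
    label <- .edge_label(tree, child)
    kar <- state[[parent]]
    evs <- history$events[history$events$branch == label, , drop = FALSE]
    for (i in seq_len(nrow(evs))) {
      ev <- list(kind = evs$kind[i],
                 chroms = strsplit(evs$operands[i], ",", fixed = TRUE)[[1]],
                 params = list())
      if (!is.na(evs$split[i])) ev$params$split <- evs$split[i]
      if (nzchar(evs$morph[i])) ev$params$morph <- evs$morph[i]
      kar <- apply_event(kar, ev)
    }
    state[[child]] <- kar
  }
  tips <- stats::setNames(state[seq_len(ntip)], tree$tip.label)
  for (i in seq_len(ntip)) tips[[i]]$species <- tree$tip.label[i]
  tips
}

#' Multiset of root segment labels in a simulated karyotype
#' @param kar a `sim_karyotype`.
#' @return sorted character vector of all segment labels.
#' @export
segment_content <- function(kar) {
  sort(unlist(lapply(kar$chroms, function(ch) c(ch$p, ch$q))))
}
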