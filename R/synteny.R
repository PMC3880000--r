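#' Syntenic associations and association profiles
#'
#' A syntenic association is the canonical unordered pairing of two source
#' chromosomes found joined on a single target chromosome — the cladistic
#' character unit of comparative painting. Canonical names follow the
#' conventional ordering used for the named fusion products of the packaged
#' dataset (`13/3`, `9/17`, `18/5`, `16/19`); all other pairs are written in
#' ascending chromosome order.
#'
#' @param a,b source chromosome ids.
#' @return `canonical_association()`: the canonical `"a/b"` name.
#' @export
canonical_association <- function(a, b) {
  named <- c("13/3", "9/17", "18/5", "16/19")
  stopifnot(length(a) == length(b))
  out <- character(length(a))
  for (i in seq_along(a)) {
    pair <- c(a[i], b[i])
    pair <- pair[order(.chrom_rank(pair))]
    nm <- paste(pair, collapse = "/")
    rev_nm <- paste(rev(pair), collapse = "/")
    out[i] <- if (rev_nm %in% named) rev_nm else nm
  }
  out
}

# maximal runs of consecutive blocks sharing one source chromosome.
# Gap rows and blocks from outside `probes` break runs.  Returns a
# data.frame with one row per run: target_chrom, source_chrom, start/end
# order_index, ambiguous (chromosome-level), preceded_by_gap.
.map_runs <- function(map, probes = NULL) {
  b <- map$blocks
  out <- list()
  for (tc in unique(b$target_chrom)) {
    rows <- b[b$target_chrom == tc, , drop = FALSE]
    rows <- rows[order(rows$order_index), , drop = FALSE]
    cur <- NULL
    gap_pending <- FALSE
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      in_probes <- !r$is_gap &&
        (is.null(probes) || r$source_chrom %in% probes)
      if (!in_probes) {
        if (!is.null(cur)) out[[length(out) + 1L]] <- cur
        cur <- NULL
        gap_pending <- TRUE
        next
      }
      amb <- .chrom_ambiguous(r, map$source_kind)
      if (!is.null(cur) && cur$source_chrom == r$source_chrom &&
          !gap_pending) {
        cur$end <- r$order_index
        cur$ambiguous <- cur$ambiguous || amb
      } else {
        if (!is.null(cur)) out[[length(out) + 1L]] <- cur
        cur <- data.frame(target_chrom = tc,
                          source_chrom = r$source_chrom,
                          start = r$order_index, end = r$order_index,
                          ambiguous = amb,
                          preceded_by_gap = gap_pending,
                          stringsAsFactors = FALSE)
      }
      gap_pending <- FALSE
    }
    if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  }
  if (!length(out)) {
    return(data.frame(target_chrom = character(), source_chrom = character(),
                      start = integer(), end = integer(),
                      ambiguous = logical(), preceded_by_gap = logical()))
  }
  do.call(rbind, out)
}

# chromosome-level ambiguity: an `or` alternative naming a different source
# chromosome.  Arm-level alternatives within one chromosome leave the
# target-chromosome placement and the source chromosome certain.
.chrom_ambiguous <- function(block_row, source_kind = "region") {
  alt <- block_row$alternatives
  if (!nzchar(alt)) return(FALSE)
  if (source_kind != "region") return(TRUE)
  alt_chrom <- parse_region_label(alt)$blocks[[1]]$chrom
  !identical(alt_chrom, block_row$source_chrom)
}

#' Count conserved chromosomal regions
#'
#' The number of maximal runs of consecutive blocks on a target chromosome
#' sharing one source chromosome, restricted to the given probe set. A
#' centromere-spanning composite block is one run; blocks of the same source
#' separated by another source's block (or by an explicit gap row) are
#' distinct runs.
#'
#' @param map a `homology_map`.
#' @param probes character vector of source chromosomes to count (default:
#'   every autosomal source detected in the map, i.e. all sources except X
#'   and Y).
#' @return integer scalar.
#' @export
count_conserved_regions <- function(map, probes = NULL) {
  stopifnot(inherits(map, "homology_map"))
  if (is.null(probes)) {
    probes <- setdiff(unique(map$blocks$source_chrom[!map$blocks$is_gap]),
                      c("X", "Y"))
  }
  nrow(.map_runs(map, probes))
}

#' Intact source chromosomes
#'
#' A source chromosome is intact when all of its blocks land on one target
#' chromosome that carries nothing else: no blocks from another source
#' chromosome and no explicit unpainted gaps. Inversions do not break
#' intactness (synteny is conserved). The X chromosome is computed like any
#' other; callers producing autosomal reports exclude it.
#'
#' @param map a `homology_map`.
#' @return character vector of intact source chromosome ids, in natural
#'   order.
#' @export
intact_source_chromosomes <- function(map) {
  stopifnot(inherits(map, "homology_map"))
  b <- map$blocks
  painted <- b[!b$is_gap, , drop = FALSE]
  intact <- character()
  for (sc in unique(painted$source_chrom)) {
    targets <- unique(painted$target_chrom[painted$source_chrom == sc])
    if (length(targets) != 1L) next
    on_target <- b[b$target_chrom == targets, , drop = FALSE]
    if (any(on_target$is_gap)) next
    if (any(on_target$source_chrom != sc)) next
    intact <- c(intact, sc)
  }
  sort_chroms(intact)
}

#' Extract syntenic associations from a homology map
#'
#' For every target chromosome carrying two or more source chromosomes,
#' emits one association per adjacent pair of same-source runs (adjacency =
#' consecutive runs not separated by a gap row), so a chromosome combining
#' three sources yields its chain of pairwise adjacencies, not all pairs.
#' Associations resting on a chromosome-level ambiguous block (an `or`
#' alternative naming a different source chromosome) are reported in the
#' `ambiguous` channel and excluded from shared-association computations.
#'
#' @param map a `homology_map`.
#' @return an object of class `association_profile`: a list with
#'   `species`, `associations` (canonical names, unambiguous), `ambiguous`
#'   (canonical names), `intact` (see [intact_source_chromosomes()]) and
#'   `pairs` (a detail data.frame).
#' @export
extract_syntenic_associations <- function(map) {
  stopifnot(inherits(map, "homology_map"))
  runs <- .map_runs(map)
  pairs <- list()
  for (tc in unique(runs$target_chrom)) {
    rr <- runs[runs$target_chrom == tc, , drop = FALSE]
    if (nrow(rr) < 2L) next
    for (i in seq_len(nrow(rr) - 1L)) {
      if (rr$preceded_by_gap[i + 1L]) next
      a <- rr$source_chrom[i]; bb <- rr$source_chrom[i + 1L]
      if (a == bb) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        target_chrom = tc,
        association = canonical_association(a, bb),
        ambiguous = rr$ambiguous[i] || rr$ambiguous[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(target_chrom = character(), association = character(),
               ambiguous = logical())
  assoc <- sort(unique(pairs$association[!pairs$ambiguous]))
  amb <- setdiff(sort(unique(pairs$association[pairs$ambiguous])), assoc)
  structure(list(species = map$target_species,
                 associations = assoc, ambiguous = amb,
                 intact = intact_source_chromosomes(map),
                 pairs = pairs),
            class = "association_profile")
}

#' @export
print.association_profile <- function(x, ...) {
  cat("<association profile> ", x$species, ": ",
      length(x$associations), " associations",
      if (length(x$ambiguous)) paste0(" (+", length(x$ambiguous),
                                      " ambiguous)") else "",
      "; intact: ", paste(x$intact, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Associations shared by (and absent from) sets of taxa
#'
#' @param profiles list of `association_profile` objects, named by species
#'   (or carrying species codes).
#' @param required taxa in which the association must be unambiguously
#'   present.
#' @param excluded taxa from which it must be absent (default none).
#' @return character vector of canonical association names, sorted.
#' @export
shared_associations <- function(profiles, required, excluded = character()) {
  names(profiles) <- vapply(profiles, function(p) p$species, "")
  unknown <- setdiff(c(required, excluded), names(profiles))
  if (length(unknown)) {
    stop("unknown taxon code: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(required) < 1L) stop("no required taxa", call. = FALSE)
  shared <- Reduce(intersect,
                   lapply(profiles[required], function(p) p$associations))
  for (sp in excluded) {
    absent_from <- union(profiles[[sp]]$associations,
                         profiles[[sp]]$ambiguous)
    shared <- setdiff(shared, absent_from)
  }
  sort(shared)
}

#' Infer plesiomorphic chromosomes
#'
#' Proposes a source chromosome as plesiomorphic (ancestral for the group)
#' when it is intact in the outgroup and in at least one ingroup taxon.
#' Sex chromosomes are excluded from the (autosomal) report by default.
#'
#' @param profiles list of `association_profile` objects (including the
#'   outgroup's, normally an identity profile).
#' @param outgroup outgroup species code.
#' @param include_sex also report intact sex chromosomes?
#' @return character vector of chromosome ids, natural order.
#' @export
infer_plesiomorphic_chromosomes <- function(profiles, outgroup,
                                            include_sex = FALSE) {
  names(profiles) <- vapply(profiles, function(p) p$species, "")
  if (!outgroup %in% names(profiles)) {
    stop("unknown outgroup code: ", outgroup, call. = FALSE)
  }
  ingroup <- setdiff(names(profiles), outgroup)
  in_any <- unique(unlist(lapply(profiles[ingroup],
                                 function(p) p$intact)))
  out <- intersect(profiles[[outgroup]]$intact, in_any)
  if (!include_sex) out <- setdiff(out, c("X", "Y"))
  sort_chroms(out)
}
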