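#' Homology maps
#'
#' A homology map records the result of hybridizing whole-chromosome paints
#' of a source species onto the karyotype of a target species: an ordered
#' list of painted blocks per target chromosome, each labeled with its
#' source region, plus explicit rows for unpainted gaps (heterochromatin,
#' NORs). Coordinates are ordinal: block adjacency means consecutive
#' `order_index` on the same target chromosome.
#'
#' The `blocks` data.frame has columns:
#' \describe{
#'   \item{target_chrom, order_index, target_region}{placement on the target
#'     karyotype, `order_index` contiguous from 1 pter to qter;}
#'   \item{source_chrom, source_region}{the painted source segment (`NA` for
#'     gap rows);}
#'   \item{alternatives}{unresolved `or` placements, `""` when unambiguous;}
#'   \item{flags}{comma-separated subset of
#'     `c("inverted", "bi-armed", "NOR-adjacent", "gap")`;}
#'   \item{is_gap}{`TRUE` for explicit unpainted gap rows.}
#' }
#'
#' @param target_species,source_species species codes.
#' @param blocks data.frame as described above (columns `target_chrom`,
#'   `order_index`, `target_region`, `source_region`, `alternatives`,
#'   `flags`).
#' @param source_kind `"region"` when source labels follow the cytogenetic
#'   grammar, `"content"` when they are opaque content strings (e.g. HSA/ECU
#'   segment compositions).
#' @return an object of class `homology_map`.
#' @export
homology_map <- function(target_species, source_species, blocks,
                         source_kind = c("region", "content")) {
  source_kind <- match.arg(source_kind)
  req <- c("target_chrom", "order_index", "target_region", "source_region",
           "alternatives", "flags")
  miss <- setdiff(req, names(blocks))
  if (length(miss)) {
    stop("homology blocks are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  blocks$target_chrom <- as.character(blocks$target_chrom)
  blocks$order_index <- as.integer(blocks$order_index)
  for (col in c("target_region", "source_region", "alternatives", "flags")) {
    blocks[[col]] <- as.character(blocks[[col]])
    blocks[[col]][is.na(blocks[[col]])] <- ""
  }
  blocks$is_gap <- grepl("\\bgap\\b", blocks$flags) | !nzchar(blocks$source_region)
  blocks <- blocks[order(.chrom_rank(blocks$target_chrom),
                         blocks$order_index), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks$source_chrom <- NA_character_
  if (source_kind == "region") {
    idx <- which(!blocks$is_gap)
    blocks$source_chrom[idx] <- vapply(blocks$source_region[idx], function(s) {
      parse_region_label(s)$blocks[[1]]$chrom
    }, "")
  } else {
    blocks$source_chrom[!blocks$is_gap] <- blocks$source_region[!blocks$is_gap]
  }
  map <- structure(list(target_species = target_species,
                        source_species = source_species,
                        blocks = blocks, source_kind = source_kind),
                   class = "homology_map")
  .check_map_structure(map)
  map
}

.check_map_structure <- function(map) {
  b <- map$blocks
  for (tc in unique(b$target_chrom)) {
    rows <- b[b$target_chrom == tc, , drop = FALSE]
    oi <- sort(rows$order_index)
    if (!identical(oi, seq_along(oi))) {
      stop("target chromosome ", tc, ": order_index must be contiguous ",
           "from 1 (got ", paste(oi, collapse = ","), ")", call. = FALSE)
    }
    if (map$source_kind != "region") next
    # painted blocks must not overlap at label granularity; identical labels
    # are tolerated (repeated interstitial signals are ordered by index)
    painted <- rows[!rows$is_gap | nzchar(rows$target_region), , drop = FALSE]
    labs <- painted$target_region[nzchar(painted$target_region)]
    labs <- labs[grepl("[pq]", labs)]
    if (length(labs) < 2L) next
    parsed <- lapply(labs, function(x) parse_region_label(x)$blocks[[1]])
    for (i in seq_along(parsed)) {
      for (j in seq_along(parsed)) {
        if (i >= j || labs[i] == labs[j]) next
        if (region_covers(parsed[[i]], parsed[[j]]) ||
            region_covers(parsed[[j]], parsed[[i]])) {
          stop("target chromosome ", tc, ": overlapping blocks '",
               labs[i], "' and '", labs[j], "'", call. = FALSE)
        }
      }
    }
  }
  invisible(map)
}

#' Read or write a homology-map TSV
#'
#' Tab-delimited, UTF-8, `#` comments; columns `target_species`,
#' `target_chrom`, `order_index`, `target_region`, `source_species`,
#' `source_region`, `alternatives`, `flags`. Gap rows leave the source
#' columns empty and carry the `gap` flag. Rows may appear in any order;
#' blocks are sorted by `order_index` on read, and gaps in the index are
#' rejected with the offending chromosome named.
#'
#' @param path file path.
#' @param probes optional character vector of source chromosomes that must
#'   each be detected in at least one block (probe-coverage invariant).
#' @param source_kind see [homology_map()].
#' @return `read_homology()` returns a `homology_map`; `write_homology()`
#'   returns `path`, invisibly.
#' @export
read_homology <- function(path, probes = NULL,
                          source_kind = c("region", "content")) {
  source_kind <- match.arg(source_kind)
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  req <- c("target_species", "target_chrom", "order_index", "target_region",
           "source_species", "source_region", "alternatives", "flags")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("homology file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tsp <- unique(tab$target_species)
  if (length(tsp) != 1L) {
    stop("homology file ", path, " mixes target species", call. = FALSE)
  }
  ssp <- unique(tab$source_species[nzchar(tab$source_species)])
  if (length(ssp) != 1L) {
    stop("homology file ", path, " mixes source species", call. = FALSE)
  }
  map <- tryCatch(
    homology_map(tsp, ssp, tab[, setdiff(req, c("target_species",
                                                "source_species"))],
                 source_kind = source_kind),
    error = function(e) stop("in ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (source_kind == "region") {
    bad <- which(!map$blocks$is_gap)
    for (i in bad) {
      parse_region_label(map$blocks$source_region[i])
      if (nzchar(map$blocks$alternatives[i])) {
        parse_region_label(map$blocks$alternatives[i])
      }
    }
  }
  if (!is.null(probes)) validate_probe_coverage(map, probes)
  map
}

#' @rdname read_homology
#' @param map a `homology_map`.
#' @export
write_homology <- function(map, path) {
  stopifnot(inherits(map, "homology_map"))
  b <- map$blocks
  out <- data.frame(target_species = map$target_species,
                    target_chrom = b$target_chrom,
                    order_index = b$order_index,
                    target_region = b$target_region,
                    source_species = ifelse(b$is_gap, "",
                                            map$source_species),
                    source_region = ifelse(b$is_gap, "", b$source_region),
                    alternatives = b$alternatives,
                    flags = b$flags,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Probe-coverage invariant
#'
#' Every probe chromosome must be detected in at least one block of the map
#' (each paint finds at least one homologous region).
#'
#' @param map a `homology_map`.
#' @param probes character vector of source chromosome ids.
#' @return `map`, invisibly; errors when a probe is undetected.
#' @export
validate_probe_coverage <- function(map, probes) {
  found <- unique(map$blocks$source_chrom[!map$blocks$is_gap])
  miss <- setdiff(probes, found)
  if (length(miss)) {
    stop("source chromosome(s) ", paste(miss, collapse = ", "),
         " of ", map$source_species,
         " absent from all blocks of the ", map$target_species,
         " map", call. = FALSE)
  }
  invisible(map)
}

#' @export
print.homology_map <- function(x, ...) {
  b <- x$blocks
  cat("<homology map> ", x$target_species, " painted with ",
      x$source_species, " probes: ", sum(!b$is_gap), " blocks on ",
      length(unique(b$target_chrom)), " chromosomes (",
      sum(b$is_gap), " gap rows)\n", sep = "")
  invisible(x)
}

#' Identity homology map of a karyotype
#'
#' The map a species' own paints produce on its own karyotype: one
#' whole-chromosome block per chromosome. The Y chromosome carries no
#' homology blocks (no Y paint is used in cross-species hybridizations).
#'
#' @param karyotype a [karyotype].
#' @return a `homology_map` with `target_species == source_species`.
#' @export
identity_homology_map <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  k <- karyotype$chromosomes
  k <- k[k$chrom != "Y", , drop = FALSE]
  homology_map(karyotype$species, karyotype$species,
               data.frame(target_chrom = k$chrom, order_index = 1L,
                          target_region = k$chrom,
                          source_region = k$chrom,
                          alternatives = "", flags = "",
                          stringsAsFactors = FALSE))
}

#' Paths to the packaged comparative painting dataset
#'
#' @param file file name within the packaged dataset, e.g.
#'   `"homology_GSO_from_MCA.tsv"`; `NULL` lists all files.
#' @return a file path (or vector of file names).
#' @export
kp_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "karyopaint")))
  }
  path <- system.file("extdata", file, package = "karyopaint")
  if (!nzchar(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}
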