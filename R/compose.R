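#' Compose two homology maps
#'
#' Chains homologies through a pivot species: given a map of species X
#' painted with species S probes, and a map carrying segment content (e.g.
#' HSA/ECU compositions) on the S karyotype, returns the X karyotype
#' annotated with that content. Each X block inherits the content of every
#' content row whose S region overlaps the block's source region at label
#' granularity; a block finer than the content row's resolution is flagged
#' `arm-resolution`. Ambiguity propagates: `or` alternatives compose to
#' alternative content. A source segment absent from the content map yields
#' an `unmapped` flag — the block is reported, never dropped.
#'
#' Content is never invented: every content label in the output occurs in
#' the second map.
#'
#' @param map_x_from_s a region-type `homology_map` (X painted with S).
#' @param map_s_content a `homology_map` whose target is S (region-type for
#'   plain map composition, content-type for HSA/ECU annotation).
#' @return a `homology_map` with `target_species = X` and the source species
#'   of `map_s_content`.
#' @export
compose_homology <- function(map_x_from_s, map_s_content) {
  stopifnot(inherits(map_x_from_s, "homology_map"),
            inherits(map_s_content, "homology_map"))
  if (!identical(map_x_from_s$source_species, map_s_content$target_species)) {
    stop("cannot compose: first map has source species ",
         map_x_from_s$source_species, " but second map's target is ",
         map_s_content$target_species, call. = FALSE)
  }
  lk <- map_s_content$blocks[!map_s_content$blocks$is_gap, , drop = FALSE]
  lk_regions <- lapply(lk$target_region,
                       function(x) parse_region_label(x)$blocks[[1]])
  lookup <- function(region_string) {
    if (!nzchar(region_string)) return(NULL)
    reg <- parse_region_label(region_string)$blocks[[1]]
    hit <- vapply(lk_regions, function(r) region_overlaps(r, reg), TRUE)
    if (!any(hit)) return(NULL)
    finer <- any(vapply(lk_regions[hit],
                        function(r) !region_covers(reg, r), TRUE))
    list(content = lk$source_region[hit], finer = finer)
  }
  b <- map_x_from_s$blocks
  out <- b[, c("target_chrom", "order_index", "target_region"), drop = FALSE]
  out$source_region <- ""
  out$alternatives <- ""
  out$flags <- b$flags
  for (i in seq_len(nrow(b))) {
    if (b$is_gap[i]) next
    hit <- lookup(b$source_region[i])
    fl <- setdiff(strsplit(b$flags[i], ",")[[1]], "")
    if (is.null(hit)) {
      fl <- union(fl, "unmapped")
    } else {
      out$source_region[i] <- paste(unique(hit$content), collapse = "+")
      if (hit$finer) fl <- union(fl, "arm-resolution")
    }
    if (nzchar(b$alternatives[i])) {
      alt_hit <- lookup(b$alternatives[i])
      if (!is.null(alt_hit)) {
        alt <- paste(unique(alt_hit$content), collapse = "+")
        if (!identical(alt, out$source_region[i])) out$alternatives[i] <- alt
      }
    }
    out$flags[i] <- paste(fl, collapse = ",")
  }
  # unmapped painted blocks stay painted: give them an explicit marker so
  # they are not mistaken for gaps
  unmapped <- !b$is_gap & !nzchar(out$source_region)
  out$source_region[unmapped] <- "unmapped"
  homology_map(map_x_from_s$target_species, map_s_content$source_species,
               out, source_kind = map_s_content$source_kind)
}

#' Rebuild the probe-species HSA lookup through the pivot species
#'
#' Comparative painting studies relate probe-species chromosomes to human
#' (HSA) segments indirectly: the probe species is painted onto a pivot
#' species whose HSA homologies are known. This helper performs that chain:
#' each probe-species unit (chromosome arm, or whole chromosome for
#' unsplit probes) collects the HSA content of the pivot regions its paint
#' covers.
#'
#' @param map_pivot_from_probe the pivot karyotype painted with probe
#'   species paints (e.g. GSO painted with MCA probes).
#' @param map_pivot_to_hsa content-type map of HSA segments on the pivot
#'   karyotype.
#' @return a content-type `homology_map`: HSA content on the probe
#'   karyotype, one row per probe unit.
#' @export
build_hsa_lookup <- function(map_pivot_from_probe, map_pivot_to_hsa) {
  stopifnot(inherits(map_pivot_from_probe, "homology_map"),
            inherits(map_pivot_to_hsa, "homology_map"))
  if (!identical(map_pivot_from_probe$target_species,
                 map_pivot_to_hsa$target_species)) {
    stop("both maps must share the pivot target species", call. = FALSE)
  }
  b <- map_pivot_from_probe$blocks
  b <- b[!b$is_gap, , drop = FALSE]
  hsa <- map_pivot_to_hsa$blocks[!map_pivot_to_hsa$blocks$is_gap, ,
                                 drop = FALSE]
  hsa_regions <- lapply(hsa$target_region,
                        function(x) parse_region_label(x)$blocks[[1]])
  # units: p/q arms for probe chromosomes whose source labels ever use an
  # arm, whole chromosome otherwise
  src_regions <- lapply(b$source_region,
                        function(x) parse_region_label(x)$blocks[[1]])
  armed <- vapply(src_regions, function(r) any(r$parts$arm != "whole"), TRUE)
  units <- list()
  for (chrom in sort_chroms(unique(b$source_chrom))) {
    idx <- b$source_chrom == chrom
    if (any(armed[idx])) {
      for (arm in c("p", "q")) {
        units[[length(units) + 1L]] <- c(chrom = chrom, arm = arm)
      }
    } else {
      units[[length(units) + 1L]] <- c(chrom = chrom, arm = "w")
    }
  }
  rows <- list()
  for (u in units) {
    ureg <- parse_region_label(.ecu_unit_region(u[["chrom"]],
                                                u[["arm"]]))$blocks[[1]]
    covered <- which(vapply(src_regions,
                            function(r) region_overlaps(r, ureg), TRUE))
    content <- character()
    for (i in covered) {
      treg <- parse_region_label(b$target_region[i])$blocks[[1]]
      hit <- vapply(hsa_regions, function(r) region_overlaps(r, treg), TRUE)
      content <- c(content, hsa$source_region[hit])
    }
    content <- unique(content)
    if (!length(content)) next
    rows[[length(rows) + 1L]] <- data.frame(
      target_chrom = u[["chrom"]],
      order_index = NA_integer_,
      target_region = .ecu_unit_region(u[["chrom"]], u[["arm"]]),
      source_region = paste(content, collapse = "+"),
      alternatives = "", flags = "", stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, rows)
  blocks$order_index <- stats::ave(seq_len(nrow(blocks)),
                                   blocks$target_chrom, FUN = seq_along)
  homology_map(map_pivot_from_probe$source_species, "HSA", blocks,
               source_kind = "content")
}

#' Count ECUs with disrupted synteny
#'
#' An ECU is disrupted in a species when its content is distributed over
#' two or more chromosomes of that species' karyotype. The count is taken
#' from the unambiguous blocks of the species' homology map (paint blocks
#' whose source region carries an unresolved `or` alternative are excluded:
#' under every consistent resolution of the packaged alternatives each such
#' ECU sits on a single chromosome).
#'
#' @param map a region-type `homology_map` of the species painted with the
#'   probe species carrying the ECUs.
#' @param ecus an `ecu_table` ([read_ecu_table()]).
#' @return a list with `count` (integer) and `disrupted` (data.frame with
#'   `ecu_id`, `unit_region` and the chromosomes involved).
#' @export
ecu_disruption_count <- function(map, ecus) {
  stopifnot(inherits(map, "homology_map"), inherits(ecus, "ecu_table"))
  b <- map$blocks[!map$blocks$is_gap, , drop = FALSE]
  unambiguous <- !nzchar(b$alternatives)
  b <- b[unambiguous, , drop = FALSE]
  src_regions <- lapply(b$source_region,
                        function(x) parse_region_label(x)$blocks[[1]])
  disrupted <- list()
  for (i in seq_len(nrow(ecus))) {
    ureg <- parse_region_label(.ecu_unit_region(ecus$chrom[i],
                                                ecus$arm[i]))$blocks[[1]]
    hit <- vapply(src_regions, function(r) region_overlaps(r, ureg), TRUE)
    chroms <- sort_chroms(unique(b$target_chrom[hit]))
    if (length(chroms) >= 2L) {
      disrupted[[length(disrupted) + 1L]] <- data.frame(
        ecu_id = ecus$ecu_id[i],
        unit_region = .ecu_unit_region(ecus$chrom[i], ecus$arm[i]),
        chromosomes = paste(chroms, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  disrupted <- if (length(disrupted)) do.call(rbind, disrupted) else
    data.frame(ecu_id = character(), unit_region = character(),
               chromosomes = character())
  list(count = nrow(disrupted), disrupted = disrupted)
}
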