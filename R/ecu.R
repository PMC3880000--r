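#' Read a table of Evolutionarily Conserved Units (ECUs)
#'
#' ECUs are chromosomal blocks conserved across chiropteran karyotypes,
#' expressed as human (HSA) chromosome segment compositions. The table has
#' one row per source-species chromosome arm (`arm` is `p`, `q` or `w` for a
#' whole chromosome) with columns `chrom`, `arm`, `ecu_id`, `hsa_segments`.
#' In segment strings, `:` joins segments fused within one unit, `-` marks
#' conserved adjacencies and `+` separates sub-blocks of one unit.
#'
#' @param path file path (tab-delimited, `#` comments).
#' @return a data.frame of class `ecu_table` with the columns above; an
#'   empty file yields a zero-row table.
#' @export
read_ecu_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  req <- c("chrom", "arm", "ecu_id", "hsa_segments")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("ECU file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab)) {
    bad <- !tab$arm %in% c("p", "q", "w")
    if (any(bad)) {
      stop("ECU file ", path, ": unknown arm '",
           paste(unique(tab$arm[bad]), collapse = ", "), "'", call. = FALSE)
    }
    if (anyDuplicated(tab$ecu_id)) {
      stop("ECU file ", path, ": duplicate ecu_id", call. = FALSE)
    }
    bad <- !grepl("^[0-9XY]+[a-z]?([:+-][0-9XY]+[a-z]?)*$", tab$hsa_segments)
    if (any(bad)) {
      stop("unparseable ECU segment token: ",
           paste(tab$hsa_segments[bad], collapse = ", "), call. = FALSE)
    }
  }
  class(tab) <- c("ecu_table", class(tab))
  tab
}

#' Decompose an HSA segment-composition string into atomic segments
#'
#' Splits on the `:` (fusion), `-` (adjacency) and `+` (sub-block)
#' separators of the ECU grammar.
#'
#' @param x character vector of segment-composition strings.
#' @return list of character vectors of atomic HSA segments.
#' @export
hsa_segment_atoms <- function(x) {
  lapply(strsplit(x, "[:+-]"), function(a) a[nzchar(a)])
}

#' Region label of an ECU-table row on the source karyotype
#' @noRd
.ecu_unit_region <- function(chrom, arm) {
  if (arm == "w") chrom else paste0(chrom, arm)
}

#' Express an ECU table as a homology map
#'
#' Rewrites the ECU table as a content-type homology map whose target is the
#' source (probe) species and whose "source" labels are HSA segment
#' compositions, so that ECU content can be carried through
#' [compose_homology()].
#'
#' @param ecus an `ecu_table` (see [read_ecu_table()]).
#' @param species target species code the ECU rows refer to.
#' @return a content-type `homology_map`.
#' @export
ecu_table_as_map <- function(ecus, species = "MCA") {
  blocks <- data.frame(
    target_chrom = ecus$chrom,
    order_index = stats::ave(seq_len(nrow(ecus)), ecus$chrom,
                             FUN = seq_along),
    target_region = mapply(.ecu_unit_region, ecus$chrom, ecus$arm),
    source_region = ecus$hsa_segments,
    alternatives = "", flags = "",
    stringsAsFactors = FALSE)
  homology_map(species, "HSA", blocks, source_kind = "content")
}
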