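#' Configuration for the packaged comparative painting analysis
#'
#' Paths and study constants for the packaged dataset: the probe species
#' (outgroup) MCA and the three nectar-feeding target species GSO, ACU and
#' LCO. Every path can be overridden to analyze other datasets with the
#' same layout.
#'
#' @param extdata directory holding the fixture files (default: the
#'   packaged dataset).
#' @param probe_species probe/outgroup species code.
#' @param target_species painted target species codes.
#' @return a named list of paths and codes, class `painting_config`.
#' @export
painting_config <- function(extdata = system.file("extdata",
                                                  package = "karyopaint"),
                            probe_species = "MCA",
                            target_species = c("GSO", "ACU", "LCO")) {
  cfg <- list(
    probe_species = probe_species,
    target_species = target_species,
    karyotypes = stats::setNames(
      file.path(extdata, paste0("karyotype_",
                                c(probe_species, target_species), ".tsv")),
      c(probe_species, target_species)),
    homologies = stats::setNames(
      file.path(extdata, paste0("homology_", target_species, "_from_",
                                probe_species, ".tsv")),
      target_species),
    gso_to_hsa = file.path(extdata, "homology_GSO_to_HSA.tsv"),
    ecu = file.path(extdata, "ecu.tsv"),
    tree = file.path(extdata, "tree.nwk"))
  class(cfg) <- "painting_config"
  cfg
}

#' Run the full comparative painting analysis
#'
#' Loads and validates the karyotypes, homology maps, ECU table and tree,
#' then computes every statistic of the analysis chain: per-species 2n, FN,
#' conserved-region count, intact probe chromosomes, syntenic associations
#' and disrupted ECUs; cross-species shared associations (for the full
#' ingroup and for each pair excluding the third taxon), the plesiomorphic
#' chromosome set, and the placement report for the association characters.
#' Every number in the report is produced by the underlying operation — no
#' report-local arithmetic. Re-running on identical inputs yields an
#' identical report (stable ordering everywhere); input checksums are
#' embedded for provenance.
#'
#' @param config a [painting_config()].
#' @return a nested list of class `analysis_report`.
#' @export
run_analysis <- function(config = painting_config()) {
  stopifnot(inherits(config, "painting_config"))
  for (p in c(config$karyotypes, config$homologies, config$ecu,
              config$gso_to_hsa, config$tree)) {
    if (!file.exists(p)) stop("fixture path does not resolve: ", p,
                              call. = FALSE)
  }
  probe <- config$probe_species
  karyos <- lapply(config$karyotypes, read_karyotype)
  probes_auto <- autosomes(karyos[[probe]])
  maps <- lapply(config$homologies, read_homology,
                 probes = c(probes_auto, "X"))
  ecus <- read_ecu_table(config$ecu)
  species <- c(probe, config$target_species)
  tree <- read_tree(config$tree, outgroup = probe, species = species)

  profiles <- lapply(maps, extract_syntenic_associations)
  profiles[[probe]] <- extract_syntenic_associations(
    identity_homology_map(karyos[[probe]]))
  profiles <- profiles[species]

  per_species <- lapply(species, function(sp) {
    k <- karyos[[sp]]
    out <- list(`2n` = diploid_number(k),
                FN = compute_fundamental_number(k))
    if (sp == probe) return(out)
    map <- maps[[sp]]
    disr <- ecu_disruption_count(map, ecus)
    prof <- profiles[[sp]]
    c(out, list(
      conserved_regions = count_conserved_regions(map, probes_auto),
      intact = setdiff(prof$intact, c("X", "Y")),
      x_intact = "X" %in% prof$intact,
      associations = prof$associations,
      ambiguous_associations = prof$ambiguous,
      disrupted_ecus = sort(disr$disrupted$ecu_id)))
  })
  names(per_species) <- species

  ingroup <- config$target_species
  shared <- list()
  shared[[paste(sort(ingroup), collapse = "+")]] <-
    shared_associations(profiles, required = ingroup)
  for (i in seq_along(ingroup)) {
    req <- sort(ingroup[-i])
    shared[[paste0(paste(req, collapse = "+"), "-", ingroup[i])]] <-
      shared_associations(profiles, required = req,
                          excluded = ingroup[i])
  }

  cmat <- build_character_matrix(profiles, outgroup = probe)
  placement <- place_rearrangements(tree, cmat)

  report <- list(
    package = "karyopaint",
    version = as.character(utils::packageVersion("karyopaint")),
    inputs = local({
      paths <- unlist(c(config$karyotypes, config$homologies, config$ecu,
                        config$gso_to_hsa, config$tree))
      sums <- tools::md5sum(paths)
      stats::setNames(as.list(unname(sums)), basename(paths))
    }),
    species = per_species,
    shared_associations = shared,
    plesiomorphic = infer_plesiomorphic_chromosomes(profiles, probe),
    placement = lapply(seq_len(nrow(placement)), function(i)
      as.list(placement[i, c("character", "placement_type", "nodes",
                             "implied_changes", "fitch_min", "mpr_count",
                             "unique_mpr")])))
  names(report$placement) <- placement$character
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis report> karyopaint", x$version, "\n")
  for (sp in names(x$species)) {
    s <- x$species[[sp]]
    cat(" ", sp, ": 2n=", s$`2n`, " FN=", s$FN, sep = "")
    if (!is.null(s$conserved_regions)) {
      cat("  regions=", s$conserved_regions,
          "  intact={", paste(s$intact, collapse = ","), "}",
          "  disrupted ECUs=", length(s$disrupted_ecus), sep = "")
    }
    cat("\n")
  }
  for (nm in names(x$shared_associations)) {
    cat("  shared ", nm, ": {",
        paste(x$shared_associations[[nm]], collapse = ", "), "}\n",
        sep = "")
  }
  cat("  plesiomorphic: {", paste(x$plesiomorphic, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Byte-stable output: fixed key ordering, unboxed scalars, no number
#' rounding.
#'
#' @param report an `analysis_report` (or any list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}
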