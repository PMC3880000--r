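# Shared fixture loaders and independent oracles used across test files.

ext_path <- function(file) {
  p <- system.file("extdata", file, package = "karyopaint")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", file)
  p
}

load_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    karyos <- lapply(c(MCA = "karyotype_MCA.tsv", GSO = "karyotype_GSO.tsv",
                       ACU = "karyotype_ACU.tsv", LCO = "karyotype_LCO.tsv"),
                     function(f) read_karyotype(ext_path(f)))
    probes <- autosomes(karyos$MCA)
    maps <- lapply(c(GSO = "homology_GSO_from_MCA.tsv",
                     ACU = "homology_ACU_from_MCA.tsv",
                     LCO = "homology_LCO_from_MCA.tsv"),
                   function(f) read_homology(ext_path(f),
                                             probes = c(probes, "X")))
    profiles <- lapply(maps, extract_syntenic_associations)
    profiles$MCA <- extract_syntenic_associations(
      identity_homology_map(karyos$MCA))
    cache <<- list(karyos = karyos, probes = probes, maps = maps,
                   profiles = profiles,
                   ecus = read_ecu_table(ext_path("ecu.tsv")),
                   gso_hsa = read_homology(ext_path("homology_GSO_to_HSA.tsv"),
                                           source_kind = "content"),
                   tree = read_tree(ext_path("tree.nwk"), outgroup = "MCA"))
    cache
  }
})

# --- independent newick oracle (recursive descent, no ape) ------------------

oracle_parse_newick <- function(text) {
  text <- sub(";\\s*$", "", trimws(text))
  pos <- 1L
  chars <- strsplit(text, "")[[1]]
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() pos <<- pos + 1L
  read_label <- function() {
    out <- character()
    while (pos <= length(chars) && !peek() %in% c(",", ")", "(", ":")) {
      out <- c(out, peek()); advance()
    }
    paste(out, collapse = "")
  }
  skip_length <- function() {
    if (peek() == ":") { advance(); read_label() }
  }
  parse_clade <- function() {
    if (peek() == "(") {
      advance()
      kids <- list(parse_clade())
      while (peek() == ",") { advance(); kids <- c(kids, list(parse_clade())) }
      stopifnot(peek() == ")")
      advance()
      read_label(); skip_length()
      list(children = kids)
    } else {
      lab <- read_label(); skip_length()
      list(label = lab)
    }
  }
  parse_clade()
}

# set of leaf-sets of all internal nodes (including the root clade)
oracle_internal_clades <- function(node) {
  acc <- list()
  walk <- function(n) {
    if (!is.null(n$label)) return(n$label)
    leaves <- sort(unlist(lapply(n$children, walk)))
    acc[[length(acc) + 1L]] <<- leaves
    leaves
  }
  walk(node)
  acc
}

# random binary topology over labels, emitted as newick (no ape involved)
random_newick <- function(labels) {
  build <- function(labs) {
    if (length(labs) == 1L) return(labs)
    k <- sample(seq_len(length(labs) - 1L), 1L)
    left <- build(labs[seq_len(k)])
    right <- build(labs[-seq_len(k)])
    paste0("(", left, ",", right, ")")
  }
  paste0(build(sample(labels)), ";")
}

ape_internal_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  lapply(ntip + seq_len(tree$Nnode), function(n) clade_leaves(tree, n))
}

clade_set_equal <- function(a, b) {
  key <- function(x) sort(vapply(x, paste, "", collapse = "|"))
  identical(key(a), key(b))
}

# --- brute-force fundamental number oracle ----------------------------------

oracle_fn <- function(karyo) {
  total <- 0L
  for (i in seq_len(nrow(karyo$chromosomes))) {
    row <- karyo$chromosomes[i, ]
    if (row$is_sex) next
    arms <- if (row$morphology == "acrocentric") 1L else 2L
    total <- total + arms + arms  # both homologs of the pair
  }
  total
}

random_karyotype <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:30, 1)
  karyotype(species = "RND", data.frame(
    chrom = c(as.character(seq_len(n)), "X"),
    morphology = c(sample(MORPHOLOGIES, n, replace = TRUE),
                   "submetacentric"),
    is_sex = c(rep(FALSE, n), TRUE),
    stringsAsFactors = FALSE))
}

# --- run-length oracle for conserved-region counting ------------------------

oracle_region_count <- function(map, probes) {
  total <- 0L
  b <- map$blocks
  for (tc in unique(b$target_chrom)) {
    rows <- b[b$target_chrom == tc, , drop = FALSE]
    rows <- rows[order(rows$order_index), , drop = FALSE]
    seq_sources <- ifelse(rows$is_gap | !(rows$source_chrom %in% probes),
                          paste0(".break", seq_len(nrow(rows))),
                          rows$source_chrom)
    runs <- rle(seq_sources)$values
    total <- total + sum(runs %in% probes)
  }
  total
}

write_temp_tsv <- function(df, comment = NULL) {
  f <- tempfile(fileext = ".tsv")
  if (!is.null(comment)) writeLines(paste0("# ", comment), f)
  suppressWarnings(utils::write.table(df, f, sep = "\t", quote = FALSE,
                                      row.names = FALSE,
                                      append = !is.null(comment)))
  f
}
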