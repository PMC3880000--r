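#' Build a binary character matrix from association profiles
#'
#' One binary character per distinct unambiguous syntenic association
#' observed across the taxa; state 1 = association present. The outgroup is
#' forced to state 0 for every fusion-association character (the outgroup
#' karyotype defines absence), and characters that would be all-zero are
#' dropped. Characters involving the source chromosomes for which an
#' acrocentric ancestral condition is assumed (13, 17, 18) carry an
#' annotation recording that convention.
#'
#' @param profiles list of `association_profile` objects covering every
#'   taxon of the study tree, including the outgroup.
#' @param outgroup outgroup species code.
#' @return an object of class `character_matrix`: a 0/1 integer matrix
#'   (taxa x characters) with attributes `outgroup`, `annotations` (named
#'   character vector) and `ambiguous_excluded` (associations observed only
#'   ambiguously).
#' @export
build_character_matrix <- function(profiles, outgroup) {
  names(profiles) <- vapply(profiles, function(p) p$species, "")
  if (!outgroup %in% names(profiles)) {
    stop("missing taxon profile for outgroup '", outgroup, "'",
         call. = FALSE)
  }
  taxa <- names(profiles)
  chars <- sort(unique(unlist(lapply(profiles,
                                     function(p) p$associations))))
  # deterministic ordering by the numeric pair, then name
  if (length(chars)) {
    key <- vapply(strsplit(chars, "/", fixed = TRUE), function(p) {
      r <- sort(.chrom_rank(p))
      r[1] * 1e3 + r[2]
    }, 0)
    chars <- chars[order(key, chars)]
  }
  states <- matrix(0L, nrow = length(taxa), ncol = length(chars),
                   dimnames = list(taxa, chars))
  for (sp in taxa) {
    states[sp, intersect(chars, profiles[[sp]]$associations)] <- 1L
  }
  states[outgroup, ] <- 0L
  keep <- colSums(states) > 0L
  states <- states[, keep, drop = FALSE]
  ann <- vapply(colnames(states), function(ch) {
    members <- strsplit(ch, "/", fixed = TRUE)[[1]]
    if (any(members %in% c("13", "17", "18"))) {
      "assumed-acrocentric-ancestor"
    } else ""
  }, "")
  ambiguous <- sort(unique(unlist(lapply(profiles,
                                         function(p) p$ambiguous))))
  structure(states, class = c("character_matrix", class(states)),
            outgroup = outgroup, annotations = ann[nzchar(ann)],
            ambiguous_excluded = setdiff(ambiguous, colnames(states)))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("<character matrix> ", ncol(x), " binary characters x ", nrow(x),
      " taxa (outgroup ", attr(x, "outgroup"), ")\n", sep = "")
  print(unclass(x)[, seq_len(min(ncol(x), 10L)), drop = FALSE])
  if (ncol(x) > 10L) cat("... and", ncol(x) - 10L, "more characters\n")
  invisible(x)
}
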