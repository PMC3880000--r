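#' Karyotype objects
#'
#' A karyotype is the haploid chromosome complement of a species: one row per
#' chromosome pair, with a morphology class from the closed set
#' \{acrocentric, subtelocentric, submetacentric, metacentric\} and a sex
#' flag. Acrocentric chromosomes have one arm; the three bi-armed classes
#' have two. Sex chromosomes are represented singly (an X row and, for
#' males, a Y row).
#'
#' @param species species code (e.g. `"MCA"`).
#' @param chromosomes data.frame with columns `chrom`, `morphology`,
#'   `is_sex`.
#' @return an object of class `karyotype`.
#' @export
karyotype <- function(species, chromosomes) {
  stopifnot(is.character(species), length(species) == 1L)
  req <- c("chrom", "morphology", "is_sex")
  if (!all(req %in% names(chromosomes))) {
    stop("karyotype table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(chromosomes) == 0L) stop("no chromosomes", call. = FALSE)
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$is_sex <- as.logical(chromosomes$is_sex)
  bad <- !chromosomes$morphology %in% MORPHOLOGIES
  if (any(bad)) {
    stop("unknown morphology: ",
         paste(unique(chromosomes$morphology[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(chromosomes$chrom)) {
    stop("duplicate chromosome id: ",
         paste(unique(chromosomes$chrom[duplicated(chromosomes$chrom)]),
               collapse = ", "), call. = FALSE)
  }
  if (sum(chromosomes$is_sex & chromosomes$chrom == "X") > 1L) {
    stop("more than one X chromosome", call. = FALSE)
  }
  chromosomes <- chromosomes[order(.chrom_rank(chromosomes$chrom)),
                             req, drop = FALSE]
  rownames(chromosomes) <- NULL
  structure(list(species = species, chromosomes = chromosomes),
            class = "karyotype")
}

#' @rdname karyotype
#' @export
MORPHOLOGIES <- c("acrocentric", "subtelocentric", "submetacentric",
                  "metacentric")

#' Read or write a karyotype TSV
#'
#' The karyotype format is a UTF-8 tab-delimited table with `#` comment
#' lines and columns `species`, `chrom`, `morphology`, `is_sex`, one row per
#' chromosome pair (haploid representation).
#'
#' @param path file path.
#' @return `read_karyotype()` returns a [karyotype];
#'   `write_karyotype()` returns `path`, invisibly.
#' @export
read_karyotype <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  req <- c("species", "chrom", "morphology", "is_sex")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("karyotype file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("no chromosomes in ", path, call. = FALSE)
  sp <- unique(tab$species)
  if (length(sp) != 1L) {
    stop("karyotype file ", path, " mixes species: ",
         paste(sp, collapse = ", "), call. = FALSE)
  }
  karyotype(sp, tab[, c("chrom", "morphology", "is_sex")])
}

#' @rdname read_karyotype
#' @param karyotype a [karyotype] object.
#' @export
write_karyotype <- function(karyotype, path) {
  stopifnot(inherits(karyotype, "karyotype"))
  tab <- cbind(species = karyotype$species, karyotype$chromosomes)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Diploid number (2n)
#'
#' Twice the autosome count plus one sex-chromosome pair when sex
#' chromosomes are present, so a male fixture (X + Y rows) and a female one
#' (a single X row representing XX) both give the conventional 2n.
#'
#' @param karyotype a [karyotype].
#' @return integer scalar.
#' @export
diploid_number <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  k <- karyotype$chromosomes
  as.integer(2L * sum(!k$is_sex) + 2L * any(k$is_sex))
}

#' Fundamental number (FN) of autosomal arms
#'
#' The diploid count of autosomal chromosome arms: acrocentric chromosomes
#' contribute one arm per copy, the bi-armed classes two. Sex chromosomes
#' are excluded.
#'
#' @param karyotype a [karyotype].
#' @return integer scalar.
#' @export
compute_fundamental_number <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  k <- karyotype$chromosomes[!karyotype$chromosomes$is_sex, , drop = FALSE]
  arms <- ifelse(k$morphology == "acrocentric", 1L, 2L)
  as.integer(2L * sum(arms))
}

#' @rdname karyotype
#' @param x,... print method arguments.
#' @export
print.karyotype <- function(x, ...) {
  k <- x$chromosomes
  cat("<karyotype> ", x$species, ": 2n = ", diploid_number(x),
      ", FN = ", compute_fundamental_number(x),
      " (", sum(!k$is_sex), " autosome pairs)\n", sep = "")
  invisible(x)
}

#' Autosome ids of a karyotype
#' @param karyotype a [karyotype].
#' @return character vector of autosome ids in natural order.
#' @export
autosomes <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  k <- karyotype$chromosomes
  sort_chroms(k$chrom[!k$is_sex])
}
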