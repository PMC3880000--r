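#' Cytogenetic region labels
#'
#' A region label addresses a painted block on a chromosome in ordinal
#' cytogenetic coordinates: a chromosome id (digits, `"X"` or `"Y"`), an
#' optional arm (`p`/`q`) and an optional positional qualifier. Qualifier
#' letters follow the conventions of comparative painting tables:
#' `t` = terminal, `p` = proximal, `i` = interstitial, `d` = distal.
#' Composite labels such as `"12p/qp"` describe one contiguous block spanning
#' the centromere. Coordinates are ordinal (block order pter to qter), never
#' base pairs.
#'
#' @param chrom chromosome id (e.g. `"5"`, `"X"`).
#' @param parts data.frame with columns `arm` (`"p"`, `"q"` or `"whole"`) and
#'   `qualifier` (`"whole-arm"`, `"proximal"`, `"interstitial"`, `"distal"`,
#'   `"terminal"`). One row for simple labels, two for centromere-spanning
#'   composites.
#' @return an object of class `region_label`.
#' @seealso [parse_region_label()]
#' @export
region_label <- function(chrom, parts) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  stopifnot(is.data.frame(parts), nrow(parts) >= 1L, nrow(parts) <= 2L)
  ok_arm <- parts$arm %in% c("p", "q", "whole")
  ok_q <- parts$qualifier %in% c("whole-arm", "proximal", "interstitial",
                                 "distal", "terminal")
  if (!all(ok_arm) || !all(ok_q)) {
    stop("invalid region parts for chromosome ", chrom, call. = FALSE)
  }
  if (any(parts$arm == "whole") &&
      (nrow(parts) > 1L || parts$qualifier[1] != "whole-arm")) {
    stop("whole-chromosome labels carry no arm qualifier (chromosome ",
         chrom, ")", call. = FALSE)
  }
  structure(list(chrom = chrom, parts = parts,
                 spans_centromere = nrow(parts) > 1L),
            class = "region_label")
}

.QUAL_CODE <- c(t = "terminal", p = "proximal", i = "interstitial", d = "distal")
.QUAL_LETTER <- stats::setNames(names(.QUAL_CODE), .QUAL_CODE)

.parse_simple <- function(token, original) {
  m <- regmatches(token,
                  regexec("^([0-9]+|X|Y)\\s*(?:([pq])([a-z]?)(?:/([pq])([a-z]?))?)?$",
                          token))[[1]]
  if (length(m) == 0L) {
    stop("malformed region label: '", original, "'", call. = FALSE)
  }
  chrom <- m[2]
  if (!nzchar(m[3])) {
    return(region_label(chrom, data.frame(arm = "whole",
                                          qualifier = "whole-arm")))
  }
  decode <- function(arm, qual) {
    if (!nzchar(qual)) return(c(arm, "whole-arm"))
    if (!qual %in% names(.QUAL_CODE)) {
      stop("unknown qualifier letter '", qual, "' in region label '",
           original, "'", call. = FALSE)
    }
    c(arm, .QUAL_CODE[[qual]])
  }
  p1 <- decode(m[3], m[4])
  if (!nzchar(m[5])) {
    return(region_label(chrom, data.frame(arm = p1[1], qualifier = p1[2])))
  }
  p2 <- decode(m[5], m[6])
  if (!(p1[1] == "p" && p2[1] == "q")) {
    stop("malformed centromere-spanning label '", original,
         "': expected p-part/q-part", call. = FALSE)
  }
  region_label(chrom, data.frame(arm = c(p1[1], p2[1]),
                                 qualifier = c(p1[2], p2[2])))
}

#' Parse a region-label token
#'
#' Parses one token of the painting-table grammar
#' `<chrom>[<arm>[<qualifier>]]`, with separators `+` (two separate blocks),
#' `/` (a contiguous centromere-spanning block) and `or` (unresolved
#' alternative placements), and the trailing flag words `Inv` and `bi-armed`.
#' Internal whitespace is ignored; parsing is deterministic and idempotent
#' under whitespace normalization.
#'
#' @param text a single raw token, e.g. `"8 qt"`, `"1qp + 6 pt"`,
#'   `"5q or 2qd"`, `"9 Inv"`.
#' @return an object of class `region_spec`: a list with elements
#'   \describe{
#'     \item{blocks}{list of [region_label] objects, one per `+`-separated
#'       block;}
#'     \item{alternatives}{list of [region_label] objects named by the `or`
#'       channel (empty when the token is unambiguous);}
#'     \item{flags}{character vector, subset of `c("inverted", "bi-armed")`.}
#'   }
#' @examples
#' parse_region_label("8 qt")
#' parse_region_label("1qp + 6 pt")
#' parse_region_label("12p/qp")
#' @export
parse_region_label <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty region label token", call. = FALSE)
  }
  original <- text
  tok <- trimws(text)
  flags <- character()
  repeat {
    if (grepl("\\bInv\\b", tok)) {
      flags <- union(flags, "inverted")
      tok <- trimws(sub("\\bInv\\b", "", tok))
    } else if (grepl("\\bbi-armed\\b", tok)) {
      flags <- union(flags, "bi-armed")
      tok <- trimws(sub("\\bbi-armed\\b", "", tok))
    } else break
  }
  if (!nzchar(tok)) stop("empty region label token: '", original, "'",
                         call. = FALSE)
  if (grepl("^\\s*\\+|\\+\\s*$", tok)) {
    stop("malformed composite region label: '", original, "'", call. = FALSE)
  }
  block_toks <- trimws(strsplit(tok, "+", fixed = TRUE)[[1]])
  if (any(!nzchar(block_toks))) {
    stop("malformed composite region label: '", original, "'", call. = FALSE)
  }
  blocks <- list()
  alternatives <- list()
  for (bt in block_toks) {
    alts <- trimws(strsplit(bt, "\\bor\\b")[[1]])
    if (any(!nzchar(alts))) {
      stop("malformed alternative in region label: '", original, "'",
           call. = FALSE)
    }
    alts <- lapply(alts, function(x) .parse_simple(gsub("\\s+", "", x),
                                                   original))
    blocks <- c(blocks, alts[1])
    if (length(alts) > 1L) alternatives <- c(alternatives, alts[-1])
  }
  structure(list(blocks = blocks, alternatives = alternatives, flags = flags),
            class = "region_spec")
}

#' @export
format.region_label <- function(x, ...) {
  if (x$parts$arm[1] == "whole") return(x$chrom)
  fmt <- function(i) {
    q <- x$parts$qualifier[i]
    paste0(x$parts$arm[i], if (q == "whole-arm") "" else .QUAL_LETTER[[q]])
  }
  paste0(x$chrom, paste(vapply(seq_len(nrow(x$parts)), fmt, ""),
                        collapse = "/"))
}

#' @export
print.region_label <- function(x, ...) {
  cat("<region>", format(x), "\n")
  invisible(x)
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region spec>", paste(vapply(x$blocks, format, ""), collapse = " + "))
  if (length(x$alternatives)) {
    cat(" or", paste(vapply(x$alternatives, format, ""), collapse = " or "))
  }
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ","), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.character.region_label <- function(x, ...) format(x)

# expand a region label into atomic (arm, qualifier) part rows
.region_parts <- function(x) {
  stopifnot(inherits(x, "region_label"))
  cbind(chrom = x$chrom, x$parts)
}

.parts_overlap <- function(a, b) {
  # two (arm, qualifier) parts on the same chromosome overlap if either is
  # whole-chromosome, or same arm with either side unqualified or equal
  if (a["arm"] == "whole" || b["arm"] == "whole") return(TRUE)
  if (a["arm"] != b["arm"]) return(FALSE)
  a["qualifier"] == "whole-arm" || b["qualifier"] == "whole-arm" ||
    a["qualifier"] == b["qualifier"]
}

#' Do two region labels overlap?
#'
#' Overlap is decided at label granularity: whole-chromosome labels overlap
#' everything on the chromosome, unqualified arms overlap any label on that
#' arm, and qualified labels overlap only identically qualified ones.
#'
#' @param a,b [region_label] objects or label strings.
#' @return logical scalar.
#' @export
region_overlaps <- function(a, b) {
  if (is.character(a)) a <- parse_region_label(a)$blocks[[1]]
  if (is.character(b)) b <- parse_region_label(b)$blocks[[1]]
  if (a$chrom != b$chrom) return(FALSE)
  pa <- .region_parts(a); pb <- .region_parts(b)
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      if (.parts_overlap(unlist(pa[i, ]), unlist(pb[j, ]))) return(TRUE)
    }
  }
  FALSE
}

#' Does region `a` cover region `b`?
#'
#' `a` covers `b` when every part of `b` lies within some part of `a`
#' (same chromosome; a whole-chromosome label covers everything, an
#' unqualified arm covers all qualified labels on that arm).
#'
#' @param a,b [region_label] objects or label strings.
#' @return logical scalar.
#' @export
region_covers <- function(a, b) {
  if (is.character(a)) a <- parse_region_label(a)$blocks[[1]]
  if (is.character(b)) b <- parse_region_label(b)$blocks[[1]]
  if (a$chrom != b$chrom) return(FALSE)
  pa <- .region_parts(a); pb <- .region_parts(b)
  covers_part <- function(ai, bj) {
    if (ai["arm"] == "whole") return(TRUE)
    if (bj["arm"] == "whole") return(FALSE)
    ai["arm"] == bj["arm"] &&
      (ai["qualifier"] == "whole-arm" || ai["qualifier"] == bj["qualifier"])
  }
  all(vapply(seq_len(nrow(pb)), function(j) {
    any(vapply(seq_len(nrow(pa)), function(i) {
      covers_part(unlist(pa[i, ]), unlist(pb[j, ]))
    }, TRUE))
  }, TRUE))
}

# natural ordering for chromosome ids: 1..n numerically, then X, then Y
.chrom_rank <- function(ids) {
  n <- suppressWarnings(as.numeric(ids))
  n[ids == "X"] <- 1e6
  n[ids == "Y"] <- 1e6 + 1
  if (anyNA(n)) n[is.na(n)] <- 2e6 + order(ids[is.na(n)])
  n
}

#' @rdname region_label
#' @param ids character vector of chromosome ids.
#' @return `sort_chroms()`: `ids` in natural karyotype order (numeric
#'   ascending, then X, then Y).
#' @export
sort_chroms <- function(ids) ids[order(.chrom_rank(ids))]
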