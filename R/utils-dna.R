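## Shared DNA string helpers. All sequence work in the package is on plain
## uppercase character vectors; Biostrings is used for reverse complements.

#' Validate DNA sequences
#'
#' Checks that every element of `x` is a non-empty uppercase-able string over
#' the alphabet {A, C, G, T}. Names (or `ids`) are used in error messages so
#' the offending record can be identified.
#'
#' @param x Character vector of sequences.
#' @param ids Optional identifiers parallel to `x`, used in error messages.
#' @param what Label describing what is being validated (e.g. "protospacer").
#' @param lengths Optional integer vector of permitted lengths.
#' @return `x`, uppercased, invisibly usable.
#' @export
validate_dna <- function(x, ids = NULL, what = "sequence", lengths = NULL) {
  if (!is.character(x)) stop(what, " must be a character vector")
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x) | nchar(x) == 0L
  if (any(bad)) {
    lab <- if (!is.null(ids)) ids[bad] else which(bad)
    stop("invalid ", what, " (non-ACGT or empty): ",
         paste(utils::head(lab, 5L), collapse = ", "))
  }
  if (!is.null(lengths) && !all(nchar(x) %in% lengths)) {
    bad <- !(nchar(x) %in% lengths)
    lab <- if (!is.null(ids)) ids[bad] else which(bad)
    stop(what, " has disallowed length (expected ",
         paste(lengths, collapse = "/"), "): ",
         paste(utils::head(lab, 5L), collapse = ", "))
  }
  x
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' GC fraction of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of G+C fractions in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  x <- toupper(x)
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) mean(s %in% c("G", "C")), numeric(1))
}

#' Hamming distance between equal-length strings
#'
#' Elementwise Hamming distance; one of `a`/`b` may be a scalar, which is
#' recycled against the other.
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b)))
    stop("hamming: sequences must have equal lengths")
  if (n == 0L) return(integer(0))
  sa <- strsplit(a, "", fixed = TRUE)
  sb <- strsplit(b, "", fixed = TRUE)
  mapply(function(u, v) sum(u != v), sa, sb)
}
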