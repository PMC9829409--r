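## Integration barcode (IBC) design. IBCs are short barcodes placed between
## the tandem sgRNA cassettes so that each lentiviral integration lineage is
## marked; they are designed as a minimum-Hamming-distance code so that
## sequencing errors cannot convert one barcode into another.

IBC_DONOR_ARM5 <- "CTCTTCCTGCCCGACCTTGGGG"
IBC_DONOR_ARM3 <- "CAGCGCCATAGCTGAGTGTAGATTCGAGC"

## BsmBI recognition site and its reverse complement; IBC donors are cloned
## via BsmBI, so these are excluded from barcodes by default.
BSMBI_SITES <- c("CGTCTC", "GAGACG")

#' Generate an integration-barcode set
#'
#' Greedy lexicographic scan over all `4^length` sequences (A < C < G < T).
#' A candidate is accepted iff its GC fraction lies within `gc_bounds`
#' (inclusive), it contains no forbidden substring, and its Hamming distance
#' to every previously accepted barcode is at least `min_dist`. The scan is
#' fully deterministic: identical parameters always give a byte-identical
#' set.
#'
#' With the defaults (8-mers, distance >= 4, GC between 25% and 75%) the scan
#' yields a set comfortably larger than the 215 barcodes used in published
#' dual-sgRNA CRISPRi libraries.
#'
#' @param length Barcode length in nucleotides.
#' @param min_dist Minimum pairwise Hamming distance within the set.
#' @param gc_bounds Length-2 numeric, inclusive GC-fraction bounds.
#' @param forbidden Character vector of substrings to exclude (default the
#'   BsmBI site and its reverse complement).
#' @param max_n Optional cap on the number of barcodes; the scan stops early
#'   once reached.
#' @return Character vector of barcodes, in order of acceptance.
#' @export
generate_ibcs <- function(length = 8L, min_dist = 4L,
                          gc_bounds = c(0.25, 0.75),
                          forbidden = BSMBI_SITES, max_n = NULL) {
  length <- as.integer(length); min_dist <- as.integer(min_dist)
  if (length < 1L) stop("length must be >= 1")
  if (min_dist > length)
    stop("infeasible constraints: min_dist (", min_dist,
         ") exceeds barcode length (", length, ")")
  if (!is.null(max_n) && max_n < 1L) stop("max_n must be >= 1")

  alphabet <- c("A", "C", "G", "T")
  n_total <- 4L^length
  ## enumerate as base-4 digit matrix, most significant position first, so
  ## row order is lexicographic
  digits <- matrix(0L, nrow = n_total, ncol = length)
  idx <- seq_len(n_total) - 1L
  for (j in length:1L) {
    digits[, j] <- idx %% 4L
    idx <- idx %/% 4L
  }
  gc_count <- rowSums(digits == 1L | digits == 2L)  # C=1, G=2
  lo <- gc_bounds[1] * length - 1e-9
  hi <- gc_bounds[2] * length + 1e-9
  keep <- gc_count >= lo & gc_count <= hi
  digits <- digits[keep, , drop = FALSE]

  if (length(forbidden) > 0) {
    seqs <- apply(digits, 1L, function(d) paste(alphabet[d + 1L], collapse = ""))
    hit <- rep(FALSE, length(seqs))
    for (f in toupper(forbidden)) hit <- hit | grepl(f, seqs, fixed = TRUE)
    digits <- digits[!hit, , drop = FALSE]
    seqs <- seqs[!hit]
  } else {
    seqs <- apply(digits, 1L, function(d) paste(alphabet[d + 1L], collapse = ""))
  }

  ## greedy accept; accepted set held transposed so each candidate check is
  ## one recycled comparison + colSums
  acc_t <- matrix(0L, nrow = length, ncol = 0L)
  out <- character(0)
  for (i in seq_len(nrow(digits))) {
    cand <- digits[i, ]
    if (ncol(acc_t) == 0L || min(colSums(acc_t != cand)) >= min_dist) {
      acc_t <- cbind(acc_t, cand)
      out <- c(out, seqs[i])
      if (!is.null(max_n) && length(out) >= max_n) break
    }
  }
  out
}

#' Validate an integration-barcode set
#'
#' Report-only check of a barcode set against the design constraints:
#' equal lengths, no duplicates, minimum pairwise Hamming distance, GC range,
#' and absence of forbidden substrings.
#'
#' @param ibcs Character vector of barcodes.
#' @inheritParams generate_ibcs
#' @return A list with class `"ibc_report"`: fields `n`, `length`,
#'   `min_pairwise_dist`, `gc_range`, `duplicates`, `forbidden_hits`, `pass`.
#' @export
validate_ibcs <- function(ibcs, min_dist = 4L, gc_bounds = c(0.25, 0.75),
                          forbidden = BSMBI_SITES) {
  ibcs <- validate_dna(ibcs, what = "IBC")
  n <- length(ibcs)
  lens <- unique(nchar(ibcs))
  dup <- unique(ibcs[duplicated(ibcs)])
  gc <- gc_fraction(ibcs)
  fhit <- character(0)
  for (f in toupper(forbidden))
    fhit <- c(fhit, ibcs[grepl(f, ibcs, fixed = TRUE)])
  mind <- NA_integer_
  if (n >= 2L && length(lens) == 1L) {
    m <- do.call(rbind, strsplit(ibcs, "", fixed = TRUE))
    mind <- lens
    for (i in seq_len(n - 1L)) {
      d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                     matrix(m[i, ], n - i, lens[1], byrow = TRUE))
      mind <- min(mind, d)
    }
  }
  rep <- list(
    n = n, length = lens, min_pairwise_dist = mind,
    gc_range = range(gc), duplicates = dup, forbidden_hits = unique(fhit),
    pass = length(lens) == 1L && length(dup) == 0L && length(fhit) == 0L &&
      (n < 2L || mind >= min_dist) &&
      all(gc >= gc_bounds[1] - 1e-9) && all(gc <= gc_bounds[2] + 1e-9)
  )
  class(rep) <- "ibc_report"
  rep
}

#' @export
print.ibc_report <- function(x, ...) {
  cat("IBC set report\n",
      "  barcodes:          ", x$n, "\n",
      "  length(s):         ", paste(x$length, collapse = ", "), "\n",
      "  min pairwise dist: ", x$min_pairwise_dist, "\n",
      "  GC range:          ", paste(signif(x$gc_range, 3), collapse = " - "), "\n",
      "  duplicates:        ", length(x$duplicates), "\n",
      "  forbidden hits:    ", length(x$forbidden_hits), "\n",
      "  PASS:              ", x$pass, "\n", sep = "")
  invisible(x)
}

#' Assemble an IBC cloning donor oligo
#'
#' The single-stranded donor carries the reverse complement of the barcode
#' between two constant homology arms:
#' 5'-`CTCTTCCTGCCCGACCTTGGGG` - revcomp(IBC) - `CAGCGCCATAGCTGAGTGTAGATTCGAGC`-3'
#' (59 nt total for an 8-nt barcode).
#'
#' @param ibc Character vector of 8-nt barcodes.
#' @return Character vector of donor oligo sequences.
#' @seealso [parse_ibc_donor()] for the inverse.
#' @export
assemble_ibc_donor <- function(ibc) {
  ibc <- validate_dna(ibc, what = "IBC", lengths = 8L)
  paste0(IBC_DONOR_ARM5, revcomp(ibc), IBC_DONOR_ARM3)
}

#' Recover the IBC from a donor oligo
#'
#' @param donor Character vector of donor oligos as produced by
#'   [assemble_ibc_donor()].
#' @return Character vector of barcodes.
#' @export
parse_ibc_donor <- function(donor) {
  donor <- toupper(donor)
  n5 <- nchar(IBC_DONOR_ARM5); n3 <- nchar(IBC_DONOR_ARM3)
  ok <- startsWith(donor, IBC_DONOR_ARM5) & endsWith(donor, IBC_DONOR_ARM3)
  if (!all(ok)) stop("donor lacks the constant homology arms at: ",
                     paste(utils::head(which(!ok), 5L), collapse = ", "))
  mid <- substr(donor, n5 + 1L, nchar(donor) - n3)
  revcomp(mid)
}
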