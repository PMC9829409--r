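## Recombination-aware counting of paired-end screen sequencing.
##
## The sequencing layout is a 19 bp Read 1 (guide A), 19 bp Read 2 (guide B),
## an 8 bp sample index (Index 1) and an 8 bp integration barcode (Index 2).
## Reads are matched to the library by exact 19-nt lookup with no mismatches.
## A read pair whose two guides belong to different genes arose from
## lentiviral template switching between co-packaged genomes; such pairs are
## excluded from counts but tallied for QC.

#' Read a FASTQ file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] (handles gzip).
#' Read ids are truncated at the first whitespace.
#'
#' @param path FASTQ file, optionally gzipped.
#' @return List with character vectors `id` and `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(list(id = character(0), seq = character(0)))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(id = sub("\\s.*$", "", names(x)), seq = as.character(unname(x)))
}

#' Write a FASTQ file
#'
#' @param id,seq Read identifiers and sequences.
#' @param path Output file; gzipped if it ends in `.gz`.
#' @param qual_char Constant per-base quality character (default "I", Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(id, seq, path, qual_char = "I") {
  stopifnot(length(id) == length(seq))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seq) > 0L)
    writeLines(paste0("@", id, "\n", seq, "\n+\n",
                      strrep(qual_char, nchar(seq))), con)
  invisible(path)
}

#' Build an exact-match library reference
#'
#' Lookup keys are the first 19 nt of each protospacer (reads are 19 bp).
#' Two distinct guides sharing a 19-nt prefix on the same side would make
#' matching ambiguous and are a hard error.
#'
#' @param elements Data frame of dual elements: `element_id`, `gene`,
#'   `protospacer_a`, `protospacer_b`.
#' @param control_label Gene label identifying non-targeting controls.
#' @return Object of class `"library_reference"`.
#' @export
build_reference <- function(elements, control_label = "non-targeting") {
  stopifnot(all(c("element_id", "gene", "protospacer_a", "protospacer_b") %in%
                  names(elements)))
  if (anyDuplicated(elements$element_id))
    stop("duplicate element_id: ",
         paste(unique(elements$element_id[duplicated(elements$element_id)]),
               collapse = ", "))
  pa <- validate_dna(elements$protospacer_a, ids = elements$element_id,
                     what = "protospacer A", lengths = c(19L, 20L))
  pb <- validate_dna(elements$protospacer_b, ids = elements$element_id,
                     what = "protospacer B", lengths = c(19L, 20L))
  ka <- substr(pa, 1L, 19L)
  kb <- substr(pb, 1L, 19L)
  for (side in list(list(k = ka, p = pa, lab = "A"),
                    list(k = kb, p = pb, lab = "B"))) {
    dup <- duplicated(side$k)
    if (any(dup)) {
      coll <- unique(side$k[dup])
      ## distinct guides vs the same guide reused across elements: both are
      ## ambiguous within one reference
      stop("19-nt prefix collision on side ", side$lab, ": ",
           paste(utils::head(coll, 5L), collapse = ", "))
    }
  }
  ref <- list(
    elements = as.data.frame(elements),
    key_a = stats::setNames(seq_along(ka), ka),
    key_b = stats::setNames(seq_along(kb), kb),
    gene = elements$gene,
    control_label = control_label)
  class(ref) <- "library_reference"
  ref
}

#' Classify read pairs as matched, recombined or unmapped
#'
#' Read 1 is looked up among guide-A keys and (oriented) Read 2 among
#' guide-B keys, exactly and without mismatches. Both found and same gene:
#' `matched` (attributed to guide A's element). Both found but different
#' genes — or different elements when both are non-targeting controls, which
#' all share the control gene label: `recombined`. Anything else (including
#' reads containing N): `unmapped`.
#'
#' @param r1,r2 Character vectors of read sequences (19 bp used).
#' @param ref A [build_reference()] object.
#' @param read2_revcomp Whether Read 2 must be reverse-complemented before
#'   lookup (default TRUE; the cassette's second guide is read in the
#'   opposite orientation on typical paired-end runs).
#' @return Data frame: `element_a`, `element_b` (integer row indices into
#'   `ref$elements`, NA if unmapped) and `category` (factor matched /
#'   recombined / unmapped).
#' @export
classify_pairs <- function(r1, r2, ref, read2_revcomp = TRUE) {
  stopifnot(inherits(ref, "library_reference"), length(r1) == length(r2))
  r1 <- substr(toupper(r1), 1L, 19L)
  r2 <- toupper(r2)
  if (read2_revcomp && length(r2) > 0L) {
    ok <- !grepl("[^ACGT]", r2)
    r2[ok] <- revcomp(r2[ok])          # non-ACGT stays unmapped anyway
  }
  r2 <- substr(r2, 1L, 19L)
  ia <- unname(ref$key_a[r1])
  ib <- unname(ref$key_b[r2])
  both <- !is.na(ia) & !is.na(ib)
  same_gene <- both & ref$gene[ia] == ref$gene[ib]
  is_ctrl <- both & ref$gene[ia] == ref$control_label &
    ref$gene[ib] == ref$control_label
  matched <- (same_gene & !is_ctrl) | (is_ctrl & ia == ib)
  matched[is.na(matched)] <- FALSE
  cat_ <- ifelse(matched, "matched", ifelse(both, "recombined", "unmapped"))
  data.frame(element_a = ia, element_b = ib,
             category = factor(cat_, levels = c("matched", "recombined",
                                                "unmapped")))
}

## nearest-whitelist match with a mismatch budget; x and whitelist are
## equal-length barcodes. Returns whitelist entry or NA.
.barcode_rescue <- function(x, whitelist, max_mismatch = 1L) {
  out <- whitelist[match(x, whitelist)]
  todo <- which(is.na(out) & !is.na(x))
  if (length(todo) > 0L && max_mismatch > 0L) {
    ux <- unique(x[todo])
    ux <- ux[nchar(ux) == nchar(whitelist[1])]
    if (length(ux) > 0L) {
      wl_m <- do.call(rbind, strsplit(whitelist, "", fixed = TRUE))
      res <- vapply(ux, function(s) {
        d <- rowSums(wl_m != matrix(strsplit(s, "", fixed = TRUE)[[1]],
                                    nrow(wl_m), ncol(wl_m), byrow = TRUE))
        i <- which(d <= max_mismatch)
        if (length(i) == 1L) whitelist[i] else NA_character_
      }, character(1))
      hit <- match(x[todo], names(res))
      out[todo] <- unname(res[hit])
    }
  }
  out
}

#' Count a paired-end screen sequencing run
#'
#' Streams synchronized FASTQ files (or pre-read character vectors) through
#' [classify_pairs()], demultiplexes samples on Index 1 and extracts
#' integration barcodes from Index 2. Matched reads are counted per
#' (element, sample); recombined and unmapped reads are tallied for QC.
#' IBCs are assigned by exact match to the whitelist with a one-mismatch
#' rescue (safe because the whitelist is a distance-4 code).
#'
#' @param r1,r2 FASTQ paths or character vectors of read sequences.
#' @param i1,i2 Optional FASTQ paths/vectors for the sample index and IBC
#'   reads.
#' @param ref A [build_reference()] object.
#' @param sample_sheet Optional data frame `sample`, `index` mapping Index-1
#'   sequences to sample names; reads beyond `index_mismatch` of every index
#'   fall in sample `"undetermined"`. Without a sheet all reads are one
#'   sample `"all"`.
#' @param ibc_whitelist Optional character vector of valid IBCs.
#' @param read2_revcomp Passed to [classify_pairs()].
#' @param index_mismatch Mismatch tolerance for sample demultiplexing.
#' @return Object of class `"count_table"`: `counts` (element x sample
#'   matrix of matched reads), `totals` (per-sample matched / recombined /
#'   unmapped), `element_recomb` and `element_mapped` (per-element x sample
#'   tallies of recombined involvement and of all mapped reads containing
#'   one of the element's guides), `recombined_pairs` (element-pair side
#'   table), `ibc_counts` (per sample x IBC, matched reads only, if `i2`
#'   given).
#' @export
count_run <- function(r1, r2, i1 = NULL, i2 = NULL, ref,
                      sample_sheet = NULL, ibc_whitelist = NULL,
                      read2_revcomp = TRUE, index_mismatch = 1L) {
  rd <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1L && file.exists(x)) read_fastq(x)
    else list(id = NULL, seq = toupper(as.character(x)))
  }
  f1 <- rd(r1); f2 <- rd(r2); fi1 <- rd(i1); fi2 <- rd(i2)
  n <- length(f1$seq)
  for (f in list(f2, fi1, fi2)) {
    if (!is.null(f) && length(f$seq) != n)
      stop("desynchronized FASTQ streams: read counts differ")
  }
  if (!is.null(f1$id) && !is.null(f2$id) && n > 0L) {
    bad <- which(f1$id != f2$id)
    if (length(bad) > 0L)
      stop("desynchronized FASTQ streams: first offending read id ",
           f1$id[bad[1]], " vs ", f2$id[bad[1]])
  }

  cls <- classify_pairs(f1$seq, f2$seq, ref, read2_revcomp = read2_revcomp)

  ## sample demultiplexing
  if (!is.null(sample_sheet) && !is.null(fi1)) {
    idx <- toupper(sample_sheet$index)
    assigned <- .barcode_rescue(fi1$seq, idx, max_mismatch = index_mismatch)
    sample <- sample_sheet$sample[match(assigned, idx)]
    sample[is.na(sample)] <- "undetermined"
    sample_levels <- c(sample_sheet$sample,
                       if (any(sample == "undetermined")) "undetermined")
  } else {
    sample <- rep("all", n)
    sample_levels <- "all"
  }
  sample <- factor(sample, levels = sample_levels)

  nel <- nrow(ref$elements)
  el_ids <- ref$elements$element_id
  dims <- list(el_ids, sample_levels)
  zero <- function() matrix(0L, nel, length(sample_levels), dimnames = dims)

  counts <- zero(); el_rec <- zero(); el_map <- zero()
  is_m <- cls$category == "matched"
  is_r <- cls$category == "recombined"
  if (any(is_m)) {
    t_m <- table(factor(cls$element_a[is_m], levels = seq_len(nel)),
                 sample[is_m])
    counts[, colnames(t_m)] <- counts[, colnames(t_m)] + as.integer(t_m)
    el_map <- el_map + counts
  }
  if (any(is_r)) {
    ta <- table(factor(cls$element_a[is_r], levels = seq_len(nel)), sample[is_r])
    tb <- table(factor(cls$element_b[is_r], levels = seq_len(nel)), sample[is_r])
    el_rec[, colnames(ta)] <- el_rec[, colnames(ta)] +
      as.integer(ta) + as.integer(tb)
    el_map <- el_map + el_rec
  }

  totals <- data.frame(
    sample = sample_levels,
    matched = as.integer(tapply(is_m, sample, sum, default = 0L)),
    recombined = as.integer(tapply(is_r, sample, sum, default = 0L)),
    unmapped = as.integer(tapply(cls$category == "unmapped", sample, sum,
                                 default = 0L)),
    stringsAsFactors = FALSE)

  rp <- NULL
  if (any(is_r)) {
    rp <- stats::aggregate(
      list(n = rep(1L, sum(is_r))),
      by = list(sample = as.character(sample[is_r]),
                element_a = el_ids[cls$element_a[is_r]],
                element_b = el_ids[cls$element_b[is_r]]),
      FUN = sum)
  }

  ibc_counts <- NULL
  if (!is.null(fi2)) {
    ibc <- if (!is.null(ibc_whitelist))
      .barcode_rescue(fi2$seq, toupper(ibc_whitelist)) else fi2$seq
    keep <- is_m & !is.na(ibc)
    if (any(keep)) {
      ibc_counts <- stats::aggregate(
        list(n = rep(1L, sum(keep))),
        by = list(sample = as.character(sample[keep]), ibc = ibc[keep]),
        FUN = sum)
    }
  }

  out <- list(counts = counts, totals = totals,
              element_recomb = el_rec, element_mapped = el_map,
              recombined_pairs = rp, ibc_counts = ibc_counts,
              elements = ref$elements)
  class(out) <- "count_table"
  out
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " elements x ", ncol(x$counts),
      " sample(s)\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' Recombination rate from a count table
#'
#' Overall rate is `recombined / (matched + recombined)` over mapped pairs,
#' pooled across samples. Per element, the rate is the fraction of mapped
#' reads containing either of the element's guides that are recombined.
#'
#' @param ct A [count_run()] result.
#' @param scope `"overall"` or `"per_element"`.
#' @return A single number, or a named numeric vector per element (NA where
#'   the element has no mapped reads).
#' @export
recombination_rate <- function(ct, scope = c("overall", "per_element")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ct, "count_table"))
  if (scope == "overall") {
    m <- sum(ct$totals$matched); r <- sum(ct$totals$recombined)
    if (m + r == 0L) {
      warning("no mapped reads; recombination rate undefined")
      return(NA_real_)
    }
    return(r / (m + r))
  }
  rec <- rowSums(ct$element_recomb)
  mapped <- rowSums(ct$element_mapped)
  rate <- ifelse(mapped > 0L, rec / mapped, NA_real_)
  stats::setNames(rate, rownames(ct$counts))
}
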