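## Delimited-text readers/writers for the tables the tools exchange.

.read_tsv <- function(path, required = character(0)) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L)
    stop(path, " lacks required column(s): ", paste(miss, collapse = ", "))
  x
}

#' Read input tables
#'
#' TSV readers with column checks for the tables used across the package:
#' guide candidates (`guide_id`, `gene`, `protospacer`, `predicted_score`),
#' per-screen guide stats (`screen_id`, `guide_id`, `phenotype`,
#' `guide_fdr`), per-screen gene stats (`screen_id`, `gene`, `p_value`,
#' `gene_fdr`), library elements (`element_id`, `gene`, `protospacer_a`,
#' `protospacer_b`) and replicate sheets (`replicate_id`, `t0_sample`,
#' `tfinal_sample`, `doublings`).
#'
#' @param path TSV file path.
#' @return Data frame.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_guide_table <- function(path)
  .read_tsv(path, c("guide_id", "gene", "protospacer", "predicted_score"))

#' @rdname read_tables
#' @export
read_guide_stats <- function(path)
  .read_tsv(path, c("screen_id", "guide_id", "phenotype", "guide_fdr"))

#' @rdname read_tables
#' @export
read_gene_stats <- function(path)
  .read_tsv(path, c("screen_id", "gene", "p_value", "gene_fdr"))

#' @rdname read_tables
#' @export
read_element_table <- function(path)
  .read_tsv(path, c("element_id", "gene", "protospacer_a", "protospacer_b"))

#' @rdname read_tables
#' @export
read_replicate_sheet <- function(path)
  .read_tsv(path, c("replicate_id", "t0_sample", "tfinal_sample",
                    "doublings"))

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write count-table outputs
#'
#' Writes `<prefix>_counts.tsv` (element x sample matched counts),
#' `<prefix>_qc.tsv` (per-sample totals plus the overall recombination
#' rate), `<prefix>_element_recombination.tsv`, and, when present,
#' `<prefix>_recombined_pairs.tsv` and `<prefix>_ibc_counts.tsv`.
#'
#' @param ct A [count_run()] result.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_count_outputs <- function(ct, prefix) {
  stopifnot(inherits(ct, "count_table"))
  paths <- character(0)
  cnt <- data.frame(element_id = rownames(ct$counts), ct$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  paths <- c(paths, write_tsv(cnt, paste0(prefix, "_counts.tsv")))
  qc <- ct$totals
  qc$recombination_rate <- ifelse(
    qc$matched + qc$recombined > 0,
    qc$recombined / (qc$matched + qc$recombined), NA_real_)
  paths <- c(paths, write_tsv(qc, paste0(prefix, "_qc.tsv")))
  per_el <- data.frame(element_id = rownames(ct$counts),
                       recombined = rowSums(ct$element_recomb),
                       mapped = rowSums(ct$element_mapped),
                       rate = recombination_rate(ct, "per_element"),
                       stringsAsFactors = FALSE)
  paths <- c(paths,
             write_tsv(per_el, paste0(prefix, "_element_recombination.tsv")))
  if (!is.null(ct$recombined_pairs))
    paths <- c(paths, write_tsv(ct$recombined_pairs,
                                paste0(prefix, "_recombined_pairs.tsv")))
  if (!is.null(ct$ibc_counts))
    paths <- c(paths, write_tsv(ct$ibc_counts,
                                paste0(prefix, "_ibc_counts.tsv")))
  invisible(paths)
}

#' Write a designed library and its synthesis oligos
#'
#' One TSV per sublibrary (`<prefix>_<rank_pair>.tsv`) plus a combined oligo
#' TSV with the assembled synthesis sequence per element.
#'
#' @param lib Named list of sublibrary data frames from [build_library()].
#' @param prefix Output path prefix.
#' @param adaptor_5,adaptor_3 PCR adaptors passed to
#'   [assemble_dual_oligo()].
#' @return Character vector of written paths, invisibly.
#' @export
write_library_outputs <- function(lib, prefix, adaptor_5 = "",
                                  adaptor_3 = "") {
  paths <- character(0)
  oligos <- list()
  for (rp in names(lib)) {
    el <- lib[[rp]]
    paths <- c(paths, write_tsv(el, paste0(prefix, "_", rp, ".tsv")))
    oligos[[rp]] <- data.frame(
      element_id = el$element_id, rank_pair = rp,
      oligo = assemble_dual_oligo(el$protospacer_a, el$protospacer_b,
                                  adaptor_5, adaptor_3),
      stringsAsFactors = FALSE)
  }
  paths <- c(paths, write_tsv(do.call(rbind, oligos),
                              paste0(prefix, "_oligos.tsv")))
  invisible(paths)
}
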