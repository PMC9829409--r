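## Knockdown quantification from single-cell expression (Perturb-seq style)
## and flow-cytometry median intensities. Knockdown is reported as the
## fraction of target mRNA (or protein signal) remaining relative to cells
## carrying non-targeting control guides.

#' On-target knockdown from single-cell expression
#'
#' Each cell's counts are first normalised to a common total
#' (`scale_factor`, counts per 10,000 by default). For every targeting
#' element, the fraction of mRNA remaining is the mean normalised expression
#' of the target gene over the element's cells divided by the mean over NTC
#' cells (ratio of means, which is robust to zeros in sparse single cells).
#' Cells with ambiguous (multiple) guide assignments must be excluded
#' upstream; assignments here are one element per cell.
#'
#' @param expr Gene x cell numeric matrix of UMI counts (dense or any
#'   matrix-like supporting `[`, `colSums`, `rowMeans`).
#' @param assignments Data frame: `cell` (column name of `expr`), `element`.
#' @param elements Data frame: `element_id`, `gene` (target gene; the
#'   control label for NTC elements).
#' @param ntc_elements Character vector of NTC element ids.
#' @param scale_factor Per-cell normalisation total (default 1e4).
#' @return Data frame: `element_id`, `gene`, `fraction_remaining`,
#'   `knockdown_percent` (= 100 * (1 - fraction_remaining)), `n_cells`.
#'   Elements whose target gene is absent from `expr` are skipped with a
#'   warning; zero NTC mean yields NA with a warning.
#' @export
perturbseq_knockdown <- function(expr, assignments, elements, ntc_elements,
                                 scale_factor = 1e4) {
  stopifnot(all(c("cell", "element") %in% names(assignments)),
            all(c("element_id", "gene") %in% names(elements)))
  absent <- !(assignments$cell %in% colnames(expr))
  if (any(absent))
    warning(sum(absent), " assigned cell(s) absent from the expression matrix")
  assignments <- assignments[!absent, , drop = FALSE]
  norm <- sweep(as.matrix(expr), 2L, colSums(expr), "/") * scale_factor

  ntc_cells <- assignments$cell[assignments$element %in% ntc_elements]
  if (length(ntc_cells) == 0L) stop("no cells assigned to an NTC element")

  targ <- elements[!(elements$element_id %in% ntc_elements) &
                     elements$element_id %in% assignments$element, ,
                   drop = FALSE]
  recs <- lapply(seq_len(nrow(targ)), function(i) {
    el <- targ$element_id[i]; gene <- targ$gene[i]
    if (!(gene %in% rownames(norm))) {
      warning("target gene ", gene, " absent from the matrix; element ",
              el, " skipped")
      return(NULL)
    }
    cl <- assignments$cell[assignments$element == el]
    m_t <- mean(norm[gene, cl])
    m_0 <- mean(norm[gene, ntc_cells])
    fr <- if (m_0 > 0) m_t / m_0 else {
      warning("zero NTC mean for gene ", gene); NA_real_
    }
    data.frame(element_id = el, gene = gene, fraction_remaining = fr,
               knockdown_percent = 100 * (1 - fr), n_cells = length(cl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Per-gene knockdown summaries
#'
#' With multiple elements per gene (typically three), reports the mean
#' knockdown across a gene's elements and the best (largest) knockdown, plus
#' library-level medians of each summary across genes.
#'
#' @param records Data frame from [perturbseq_knockdown()].
#' @return List: `per_gene` (data frame `gene`, `n_elements`, `mean_kd`,
#'   `best_kd`) and `median_mean_kd` / `median_best_kd` across genes.
#' @export
summarize_per_gene <- function(records) {
  stopifnot(all(c("gene", "knockdown_percent") %in% names(records)))
  sp <- split(records$knockdown_percent, records$gene)
  per_gene <- data.frame(
    gene = names(sp),
    n_elements = vapply(sp, length, integer(1)),
    mean_kd = vapply(sp, mean, numeric(1)),
    best_kd = vapply(sp, max, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       median_mean_kd = stats::median(per_gene$mean_kd),
       median_best_kd = stats::median(per_gene$best_kd))
}

#' Knockdown from flow-cytometry median intensities
#'
#' `100 * (1 - (median_target - background) / (median_ntc - background))`.
#' Negative values (up-regulation) are permitted and reported as-is.
#'
#' @param median_target Median stain signal in sgRNA-expressing cells.
#' @param median_ntc Median signal in non-targeting control cells.
#' @param background Background signal (unstained / isotype control).
#' @return Knockdown percent.
#' @export
flow_knockdown <- function(median_target, median_ntc, background = 0) {
  if (any(median_ntc <= background))
    stop("NTC median must exceed background")
  100 * (1 - (median_target - background) / (median_ntc - background))
}

#' Fraction of cells without evidence of knockdown
#'
#' Thresholds at a low quantile of the reference (NTC) intensity
#' distribution and reports the percent of target cells at or above it —
#' cells indistinguishable from unperturbed cells despite the guide.
#'
#' @param intensities_target Intensities of cells expressing the guide.
#' @param intensities_reference Intensities of NTC cells.
#' @param quantile_cut Reference quantile defining "no knockdown"
#'   (default 0.05).
#' @return Percent of target cells at or above the threshold.
#' @export
no_knockdown_fraction <- function(intensities_target, intensities_reference,
                                  quantile_cut = 0.05) {
  stopifnot(length(intensities_target) > 0L,
            length(intensities_reference) > 0L)
  thr <- stats::quantile(intensities_reference, quantile_cut, names = FALSE)
  100 * mean(intensities_target >= thr)
}
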