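## Growth phenotype (gamma) statistics. gamma is the log2 fold-enrichment of
## an element from T0 to Tfinal per population doubling, centered on the
## median of the non-targeting controls so that the null phenotype is 0.

#' Apply count filters before phenotype calculation
#'
#' Two rules, evaluated on raw counts: (i) an element is excluded if, in any
#' replicate, it has fewer than `min_reads` reads at **both** T0 and Tfinal;
#' (ii) remaining zero counts are then replaced by `pseudocount`.
#'
#' @param counts Element x sample integer matrix of matched read counts (as
#'   in `count_table$counts`).
#' @param replicates Data frame: `replicate_id`, `t0_sample`,
#'   `tfinal_sample`, `doublings` (> 0). Sample names must be columns of
#'   `counts`.
#' @param pseudocount Value substituted for zero counts (default 1).
#' @param min_reads Read-count floor (default 50).
#' @return List: `counts` (pseudocounted numeric matrix), `excluded`
#'   (logical per element), `raw` (the input).
#' @export
apply_filters <- function(counts, replicates, pseudocount = 1L,
                          min_reads = 50L) {
  stopifnot(is.matrix(counts), pseudocount >= 0, min_reads >= 0)
  need <- unique(c(replicates$t0_sample, replicates$tfinal_sample))
  miss <- setdiff(need, colnames(counts))
  if (length(miss) > 0L) stop("sample(s) missing from counts: ",
                              paste(miss, collapse = ", "))
  if (any(!is.finite(replicates$doublings) | replicates$doublings <= 0))
    stop("doublings must be finite and positive")
  excluded <- rep(FALSE, nrow(counts))
  for (i in seq_len(nrow(replicates))) {
    excluded <- excluded |
      (counts[, replicates$t0_sample[i]] < min_reads &
         counts[, replicates$tfinal_sample[i]] < min_reads)
  }
  ps <- counts
  ps[ps == 0L] <- pseudocount
  list(counts = ps, excluded = stats::setNames(excluded, rownames(counts)),
       raw = counts)
}

#' Growth phenotypes (gamma) for one replicate
#'
#' Counts are depth-normalised to reads per million within each sample; for
#' each element, `gamma = (log2(rpm_Tfinal / rpm_T0) - median NTC log2
#' ratio) / doublings`. By construction the median gamma of the surviving
#' non-targeting controls is exactly 0 in every replicate. gamma is
#' invariant to any uniform rescaling of either sample's depth.
#'
#' @param counts Pseudocounted numeric matrix from [apply_filters()].
#' @param replicate One row of the replicate sheet (list or 1-row data
#'   frame with `t0_sample`, `tfinal_sample`, `doublings`).
#' @param ntc_ids Character vector of non-targeting element ids (rownames).
#' @param excluded Optional logical vector of filtered elements; their gamma
#'   is NA and they do not enter the NTC median.
#' @return Named numeric vector of gamma per element (NA for excluded).
#' @export
gamma_scores <- function(counts, replicate, ntc_ids,
                         excluded = rep(FALSE, nrow(counts))) {
  t0 <- counts[, replicate$t0_sample]
  tf <- counts[, replicate$tfinal_sample]
  rpm0 <- t0 * 1e6 / sum(t0)
  rpmf <- tf * 1e6 / sum(tf)
  lr <- log2(rpmf / rpm0)
  is_ntc <- rownames(counts) %in% ntc_ids & !excluded
  if (!any(is_ntc))
    stop("no unfiltered non-targeting control element; cannot center gamma")
  g <- (lr - stats::median(lr[is_ntc])) / replicate$doublings
  g[excluded] <- NA_real_
  stats::setNames(g, rownames(counts))
}

#' Average gammas over replicates and elements
#'
#' Per element, the unweighted mean over replicates in which the element
#' survived filtering (elements filtered in some replicates contribute their
#' remaining replicates and are flagged). Per gene, the mean over that
#' gene's unfiltered elements.
#'
#' @param gamma_mat Element x replicate matrix of gammas (NA = filtered).
#' @param gene_of Optional named character vector mapping element id to
#'   gene; when given, per-gene means are returned too.
#' @return List: `element` (data frame `element_id`, `gamma`,
#'   `n_replicates`, `partial`), and `gene` (data frame `gene`, `gamma`) if
#'   `gene_of` was supplied.
#' @export
aggregate_replicates <- function(gamma_mat, gene_of = NULL) {
  stopifnot(is.matrix(gamma_mat))
  n_rep <- rowSums(!is.na(gamma_mat))
  g <- rowMeans(gamma_mat, na.rm = TRUE)
  g[n_rep == 0L] <- NA_real_
  el <- data.frame(element_id = rownames(gamma_mat), gamma = g,
                   n_replicates = n_rep,
                   partial = n_rep > 0L & n_rep < ncol(gamma_mat),
                   stringsAsFactors = FALSE)
  rownames(el) <- NULL
  out <- list(element = el)
  if (!is.null(gene_of)) {
    gene <- unname(gene_of[el$element_id])
    ok <- !is.na(el$gamma) & !is.na(gene)
    gg <- tapply(el$gamma[ok], gene[ok], mean)
    out$gene <- data.frame(gene = names(gg), gamma = as.numeric(gg),
                           stringsAsFactors = FALSE)
  }
  out
}

#' Bias summary for simulated gamma recovery
#'
#' Compares estimated against true gammas on simulator output. Because every
#' element's gamma shares the non-targeting-control median centering term,
#' per-element errors are correlated: the Monte-Carlo standard error of the
#' mean error is `sqrt(var_indep / n + var_offset)`, where `var_offset` (the
#' sampling variance of the NTC median) is estimated by bootstrap over the
#' NTC gammas. Using the naive independent-errors SE would overstate the
#' precision of the mean-error statistic.
#'
#' @param gamma_est Named numeric vector of estimated gammas.
#' @param gamma_true Named numeric vector of true gammas (simulator truth).
#' @param ntc_ids Character vector of NTC element ids.
#' @param n_boot Bootstrap replicates for the NTC-median variance.
#' @return List: `n`, `mean_error`, `se_naive`, `se_offset`, `se_total`,
#'   `unbiased` (|mean_error| < 2 * se_total).
#' @export
gamma_bias_summary <- function(gamma_est, gamma_true, ntc_ids,
                               n_boot = 2000L) {
  common <- intersect(names(gamma_est), names(gamma_true))
  err <- gamma_est[common] - gamma_true[common]
  err <- err[!is.na(err)]
  n <- length(err)
  se_naive <- stats::sd(err) / sqrt(n)
  ntc_g <- gamma_est[intersect(ntc_ids, names(err))]
  ntc_g <- ntc_g[!is.na(ntc_g)]
  meds <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(ntc_g, replace = TRUE)), numeric(1))
  se_offset <- stats::sd(meds)
  se_total <- sqrt(se_naive^2 + se_offset^2)
  list(n = n, mean_error = mean(err), se_naive = se_naive,
       se_offset = se_offset, se_total = se_total,
       unbiased = abs(mean(err)) < 2 * se_total)
}

#' Essential-gene recall AUC
#'
#' Area under the ROC curve for separating depleted positives from
#' non-targeting negatives, scoring items by `-gamma` (stronger depletion
#' ranks higher). Computed by the rank-sum (Mann-Whitney U) identity with
#' midranks, which handles ties exactly.
#'
#' @param gammas Named numeric vector of gammas over genes and NTC elements.
#' @param positives Names of true positives (e.g. essential genes).
#' @param negatives Names of negatives (e.g. NTC element ids).
#' @return AUC in `[0, 1]`.
#' @export
essential_recall_auc <- function(gammas, positives, negatives) {
  pos <- gammas[intersect(positives, names(gammas))]
  neg <- gammas[intersect(negatives, names(gammas))]
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("positives and negatives must both be non-empty after ",
         "intersection with measured items")
  sc <- -c(pos, neg)
  r <- rank(sc)
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Compare gene-level phenotypes between two libraries
#'
#' Restricts both libraries to a common gene set, reports the two means, a
#' two-sided Mann-Whitney test (normal approximation with continuity and
#' tie correction, appropriate at the thousands-of-genes scale), and the
#' percent change of library 2 relative to the magnitude of library 1.
#'
#' @param gammas1,gammas2 Named numeric vectors of per-gene gammas.
#' @param gene_set Character vector of genes to compare on.
#' @return List: `n`, `mean1`, `mean2`, `mannwhitney_p`, `percent_change`.
#' @export
compare_gene_sets <- function(gammas1, gammas2, gene_set) {
  genes <- intersect(gene_set, intersect(names(gammas1), names(gammas2)))
  x1 <- gammas1[genes]; x2 <- gammas2[genes]
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) == 0L) stop("empty gene-set intersection")
  m1 <- mean(x1); m2 <- mean(x2)
  p <- stats::wilcox.test(x1, x2, exact = FALSE, correct = TRUE)$p.value
  list(n = length(x1), mean1 = m1, mean2 = m2, mannwhitney_p = p,
       percent_change = 100 * (m2 - m1) / abs(m1))
}

#' Competitive growth defect from a marker-ratio timecourse
#'
#' For an internally normalised competition assay (e.g. effector-expressing,
#' marker-negative cells mixed with marker-positive reference cells), the
#' log2 of the cell ratio on each day is normalised to the day-0 ratio; the
#' average percent growth defect per day is the log2 value at the horizon
#' divided by the number of days, times 100.
#'
#' @param day Numeric vector of measurement days (must include 0).
#' @param ratio Positive ratios of test to reference cells, parallel to
#'   `day`.
#' @param horizon_day Day used for the per-day summary (default: last day).
#' @return List: `course` (data frame `day`, `log2_normalized`) and
#'   `percent_per_day`.
#' @export
competitive_growth_defect <- function(day, ratio, horizon_day = max(day)) {
  stopifnot(length(day) == length(ratio))
  i0 <- which(day == 0)
  if (length(i0) != 1L || !is.finite(ratio[i0]) || ratio[i0] <= 0)
    stop("a single positive day-0 ratio is required")
  l2 <- log2(ratio / ratio[i0])
  ih <- which(day == horizon_day)
  if (length(ih) != 1L) stop("horizon_day not present in the timecourse")
  list(course = data.frame(day = day, log2_normalized = l2),
       percent_per_day = 100 * l2[ih] / horizon_day)
}
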