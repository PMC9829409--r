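## Empirical tiered guide selection and dual-element library construction.
##
## Genes fall into three tiers. Tier 1: essential in the K562 reference
## growth screen (p < 0.001 and gamma < -0.2); guides ranked by growth
## phenotypes relative to the best guide per hit screen. Tier 2: hit in >= 5
## aggregated CRISPRi screens, or hit in 1-4 screens with a discriminant
## score exceeding a null threshold derived from olfactory-receptor genes;
## guides ranked by mean relative phenotype over hit screens, restricted to
## guides that themselves scored (guide FDR < 0.01) in at least one screen.
## Tier 3: everything else, ranked by predicted activity score.

OLIGO_SPACER_5 <- "CCACCTTGTTG"
OLIGO_LINKER   <- "GTTTCAGAGCGAGACGTGCCTGCAGGATACGTCTCAGAAACATG"
OLIGO_SPACER_3 <- "GTTTAAGAGCTAAGCTG"

#' Remove guides containing a BsmBI site
#'
#' Dual-guide cassettes are cloned with BsmBI, so protospacers containing the
#' recognition sequence `CGTCTC` or its reverse complement `GAGACG` drop out
#' during cloning and are removed up front. Only the protospacer itself is
#' scanned; the constant flanks are validated once at the oligo level.
#'
#' @param guides Data frame with at least columns `guide_id` and
#'   `protospacer` (19-20 nt, A/C/G/T).
#' @return The input rows whose protospacer contains neither site, original
#'   order preserved.
#' @export
filter_bsmbi <- function(guides) {
  stopifnot(is.data.frame(guides),
            all(c("guide_id", "protospacer") %in% names(guides)))
  ps <- validate_dna(guides$protospacer, ids = guides$guide_id,
                     what = "protospacer", lengths = c(19L, 20L))
  hit <- grepl(BSMBI_SITES[1], ps, fixed = TRUE) |
    grepl(BSMBI_SITES[2], ps, fixed = TRUE)
  guides[!hit, , drop = FALSE]
}

#' Phenotypes relative to the best guide of a gene
#'
#' Within one screen, each guide phenotype for a gene is divided by the
#' phenotype of largest absolute value among that gene's guides, so the best
#' guide maps to 1 and guides of opposite sign map to negative values.
#'
#' @param phenotypes Named numeric vector (names are guide ids) of one
#'   gene's guide phenotypes in one screen.
#' @return Named numeric vector of relative phenotypes.
#' @export
relative_phenotypes <- function(phenotypes) {
  if (length(phenotypes) == 0L || !any(is.finite(phenotypes)))
    stop("relative_phenotypes: need at least one finite phenotype")
  best <- phenotypes[which.max(abs(phenotypes))]
  if (best == 0) {
    warning("all phenotypes are zero; relative phenotypes set to 0")
    return(phenotypes * 0)
  }
  phenotypes / best
}

#' Per-screen z-scores of guide phenotypes
#'
#' Standardises guide phenotypes within each screen (mean 0, sd 1 across all
#' guides measured in that screen), so screens with different effect-size
#' scales become comparable.
#'
#' @param guide_stats Data frame with columns `screen_id`, `guide_id`,
#'   `phenotype` (and any others, preserved).
#' @return `guide_stats` with an added numeric column `z`.
#' @export
zscore_phenotypes <- function(guide_stats) {
  stopifnot(all(c("screen_id", "guide_id", "phenotype") %in% names(guide_stats)))
  z <- stats::ave(guide_stats$phenotype, guide_stats$screen_id,
                  FUN = function(x) {
                    s <- stats::sd(x)
                    if (!is.finite(s) || s == 0) return(x * 0)
                    (x - mean(x)) / s
                  })
  guide_stats$z <- z
  guide_stats
}

#' Cross-screen discriminant scores for genes hit in few screens
#'
#' For each screen in which a gene is a significant hit (gene FDR <=
#' `hit_fdr`), the per-screen discriminant is
#' `d = -log10(p) * mean(z of the top three guides)`, where "top three" are
#' the guides of largest absolute z-scored phenotype in that screen (signed
#' mean; if fewer than three guides were measured, all available are used).
#' When a screen carries several records for the gene (e.g. per transcript),
#' the record maximising `|d|` is taken. The gene score is the sum of `|d|`
#' over hit screens.
#'
#' @param gene_stats Data frame: `screen_id`, `gene`, `p_value`, `gene_fdr`.
#' @param guide_stats Data frame: `screen_id`, `guide_id`, `phenotype`
#'   (z-scores computed internally via [zscore_phenotypes()]).
#' @param guide_gene Named character vector mapping guide_id to gene.
#' @param hit_fdr Gene-level FDR cut defining a hit screen.
#' @return Data frame: `gene`, `n_hit_screens`, `score` (NA when
#'   `n_hit_screens` is 0).
#' @export
discriminant_scores <- function(gene_stats, guide_stats, guide_gene,
                                hit_fdr = 0.05) {
  stopifnot(all(c("screen_id", "gene", "p_value", "gene_fdr") %in%
                  names(gene_stats)))
  if (any(gene_stats$p_value <= 0)) stop("p_value must be > 0")
  gs <- zscore_phenotypes(guide_stats)
  gs$gene <- unname(guide_gene[gs$guide_id])

  hits <- gene_stats[gene_stats$gene_fdr <= hit_fdr, , drop = FALSE]
  genes <- unique(gene_stats$gene)
  out <- data.frame(gene = genes, n_hit_screens = 0L, score = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)

  top3_mean <- function(z) {
    k <- min(3L, length(z))
    mean(z[order(-abs(z))][seq_len(k)])
  }
  ## per (screen, gene): |d| of the record maximising |d|
  key <- interaction(hits$screen_id, hits$gene, drop = TRUE)
  per_screen <- vapply(split(seq_len(nrow(hits)), key), function(ii) {
    sc <- hits$screen_id[ii[1]]; g <- hits$gene[ii[1]]
    z <- gs$z[gs$screen_id == sc & !is.na(gs$gene) & gs$gene == g]
    if (length(z) == 0L) return(NA_real_)
    m <- top3_mean(z)
    d <- -log10(hits$p_value[ii]) * m
    max(abs(d))
  }, numeric(1))
  gene_of_key <- vapply(split(hits$gene, key), `[`, character(1), 1L)

  ## every hit screen counts toward n_hit_screens; only screens with
  ## measured guide phenotypes contribute to the score
  agg_n <- table(gene_of_key)
  agg_s <- tapply(per_screen, gene_of_key,
                  function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))
  m <- match(out$gene, names(agg_n))
  out$n_hit_screens <- ifelse(is.na(m), 0L, as.integer(agg_n[m]))
  ms <- match(out$gene, names(agg_s))
  out$score <- ifelse(out$n_hit_screens > 0L, as.numeric(agg_s[ms]), NA_real_)
  out
}

#' Null thresholds from olfactory-receptor gene scores
#'
#' Olfactory receptor genes are not expected to affect growth in any screen,
#' so their discriminant scores form an empirical null. The threshold for
#' genes hit in exactly `k` screens is the maximum olfactory score at `k`
#' hit screens; if no olfactory gene has exactly `k` hits the maximum over
#' olfactory genes with `<= k` hits is used; if none exist at all the
#' threshold is `+Inf` (no gene can pass via score).
#'
#' @param olfactory_scores Data frame as returned by [discriminant_scores()]
#'   restricted to the olfactory gene set: `gene`, `n_hit_screens`, `score`.
#' @param k_max Largest hit-screen count thresholded (genes with more hits
#'   enter tier 2 unconditionally).
#' @return Named numeric vector `threshold[k]` for `k = 1..k_max`.
#' @export
olfactory_thresholds <- function(olfactory_scores, k_max = 4L) {
  stopifnot(all(c("n_hit_screens", "score") %in% names(olfactory_scores)))
  sc <- olfactory_scores[olfactory_scores$n_hit_screens >= 1L &
                           !is.na(olfactory_scores$score), , drop = FALSE]
  thr <- rep(Inf, k_max)
  names(thr) <- as.character(seq_len(k_max))
  for (k in seq_len(k_max)) {
    at_k <- sc$score[sc$n_hit_screens == k]
    if (length(at_k) > 0L) thr[k] <- max(at_k)
    else {
      le_k <- sc$score[sc$n_hit_screens <= k]
      if (length(le_k) > 0L) thr[k] <- max(le_k)
    }
  }
  thr
}

#' Assign genes to selection tiers
#'
#' Precedence is strictly tier 1 > 2 > 3 and every gene receives exactly one
#' tier. Tier 1: K562 reference screen `p_value < k562_p` and gene-level
#' gamma `< k562_gamma`. Tier 2: hit in `>= min_hit_screens` screens, or hit
#' in 1 to `k_max` screens with discriminant score strictly above the
#' olfactory threshold for that hit count. Tier 3: all other genes.
#'
#' @param genes Character vector of genes to assign.
#' @param k562_stats Data frame for the K562 reference screen: `gene`,
#'   `p_value`, `k562_gamma`. Genes absent from it simply fail tier 1.
#' @param scores Data frame from [discriminant_scores()] over the aggregated
#'   screens: `gene`, `n_hit_screens`, `score`.
#' @param thresholds Named vector from [olfactory_thresholds()].
#' @param k562_p,k562_gamma Tier-1 cutoffs.
#' @param min_hit_screens Unconditional tier-2 hit count.
#' @return Data frame: `gene`, `tier` (integer 1/2/3), `n_hit_screens`,
#'   `discriminant_score`, `threshold_used`.
#' @export
assign_tiers <- function(genes, k562_stats, scores, thresholds,
                         k562_p = 0.001, k562_gamma = -0.2,
                         min_hit_screens = 5L) {
  mk <- match(genes, k562_stats$gene)
  tier1 <- !is.na(mk) &
    k562_stats$p_value[mk] < k562_p &
    k562_stats$k562_gamma[mk] < k562_gamma
  tier1[is.na(tier1)] <- FALSE
  if (any(is.na(mk)))
    message(sum(is.na(mk)), " gene(s) absent from the K562 reference table; ",
            "treated as not meeting tier-1 criteria")

  ms <- match(genes, scores$gene)
  nh <- ifelse(is.na(ms), 0L, scores$n_hit_screens[ms])
  sc <- ifelse(is.na(ms), NA_real_, scores$score[ms])
  k_max <- length(thresholds)
  thr <- rep(NA_real_, length(genes))
  in_range <- nh >= 1L & nh <= k_max
  thr[in_range] <- thresholds[as.character(nh[in_range])]
  tier2 <- nh >= min_hit_screens |
    (in_range & !is.na(sc) & sc > thr)

  tier <- ifelse(tier1, 1L, ifelse(tier2, 2L, 3L))
  data.frame(gene = genes, tier = tier, n_hit_screens = as.integer(nh),
             discriminant_score = ifelse(in_range & !tier1, sc, NA_real_),
             threshold_used = ifelse(in_range & !tier1, thr, NA_real_),
             stringsAsFactors = FALSE)
}

#' Rank the guides of one gene according to its tier
#'
#' Tier 1 and tier 2 rank by the mean of relative phenotypes (see
#' [relative_phenotypes()]) across the screens in which the gene was a hit;
#' tier 2 additionally requires a guide to have scored at guide-level FDR
#' `< guide_fdr_max` in at least one hit screen — guides that never scored
#' are placed after all scoring guides, ordered by predicted activity.
#' Guides without any phenotype measurement in the hit screens are likewise
#' placed last by predicted score. Tier 3 ranks purely by predicted
#' activity. All ties break by ascending protospacer lexicographic order so
#' output is byte-stable.
#'
#' @param guides Data frame (one gene, BsmBI-filtered): `guide_id`, `gene`,
#'   `protospacer`, `predicted_score`.
#' @param tier Integer 1, 2 or 3.
#' @param guide_stats Data frame: `screen_id`, `guide_id`, `phenotype`,
#'   `guide_fdr`. Only rows for this gene's guides are used.
#' @param hit_screens Character vector of screens in which the gene was a
#'   hit (ignored for tier 3).
#' @param guide_fdr_max Tier-2 guide eligibility cut.
#' @return `guides` reordered, with added columns `rank` and
#'   `mean_rel_phenotype` (NA where not applicable).
#' @export
rank_guides <- function(guides, tier, guide_stats = NULL,
                        hit_screens = character(0), guide_fdr_max = 0.01) {
  stopifnot(tier %in% 1:3, nrow(guides) >= 1L)
  n <- nrow(guides)
  mean_rel <- rep(NA_real_, n)
  eligible <- rep(TRUE, n)

  if (tier %in% c(1L, 2L) && length(hit_screens) > 0L && !is.null(guide_stats)) {
    st <- guide_stats[guide_stats$screen_id %in% hit_screens &
                        guide_stats$guide_id %in% guides$guide_id, , drop = FALSE]
    rel <- matrix(NA_real_, n, length(hit_screens),
                  dimnames = list(guides$guide_id, hit_screens))
    for (sc in unique(st$screen_id)) {
      ss <- st[st$screen_id == sc, , drop = FALSE]
      ph <- stats::setNames(ss$phenotype, ss$guide_id)
      ph <- ph[is.finite(ph)]
      if (length(ph) == 0L) next
      r <- relative_phenotypes(ph)
      rel[names(r), sc] <- r
    }
    meas <- rowSums(!is.na(rel)) > 0L
    mean_rel[meas] <- rowMeans(rel[meas, , drop = FALSE], na.rm = TRUE)
    if (tier == 2L) {
      scored <- tapply(st$guide_fdr < guide_fdr_max, st$guide_id, any)
      eligible <- guides$guide_id %in% names(scored)[unlist(scored)]
    }
    eligible <- eligible & meas
  } else if (tier %in% c(1L, 2L)) {
    eligible <- rep(FALSE, n)
  }

  if (tier == 3L) {
    ord <- order(-guides$predicted_score, guides$protospacer)
  } else {
    key1 <- !eligible                       # eligible first
    key2 <- ifelse(eligible, -mean_rel, -guides$predicted_score)
    ord <- order(key1, key2, guides$protospacer)
  }
  out <- guides[ord, , drop = FALSE]
  out$mean_rel_phenotype <- mean_rel[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build dual-sgRNA sublibraries from ranked guides
#'
#' Pairs consecutive ranks into elements: ranks (1,2) form sublibrary
#' `"1_2"`, (3,4) form `"3_4"`, (5,6) form `"5_6"`. A gene appears in a
#' sublibrary iff it has enough ranked guides for that pair. Each sublibrary
#' is topped up with non-targeting control pairs so that controls make up
#' `control_fraction` of the total: `n_ctrl = ceiling(T * f / (1 - f))` for
#' `T` targeting elements. Controls are taken in input order from
#' `control_pairs`, so designs are reproducible without a seed.
#'
#' @param ranked Named list (gene -> data frame from [rank_guides()]).
#' @param control_pairs Data frame with columns `protospacer_a`,
#'   `protospacer_b` supplying the non-targeting pairs.
#' @param control_fraction Fraction of each sublibrary that is controls.
#' @param n_pairs Number of rank pairs / sublibraries (default 3).
#' @param control_label Gene label used for control elements.
#' @return Named list of data frames (one per sublibrary, names `"1_2"`,
#'   `"3_4"`, `"5_6"`), each with columns `element_id`, `gene`, `rank_pair`,
#'   `protospacer_a`, `protospacer_b`, `ibc`.
#' @export
build_library <- function(ranked, control_pairs, control_fraction = 0.05,
                          n_pairs = 3L, control_label = "non-targeting") {
  stopifnot(is.list(ranked), length(ranked) > 0L,
            control_fraction >= 0, control_fraction < 1)
  genes <- names(ranked)
  n_guides <- vapply(ranked, nrow, integer(1))
  out <- list()
  for (p in seq_len(n_pairs)) {
    rp <- paste0(2L * p - 1L, "_", 2L * p)
    has <- n_guides >= 2L * p
    gsel <- genes[has]
    if (length(gsel) == 0L) {
      out[[rp]] <- NULL
      next
    }
    a <- vapply(ranked[gsel], function(g) g$protospacer[2L * p - 1L], character(1))
    b <- vapply(ranked[gsel], function(g) g$protospacer[2L * p], character(1))
    if (any(a == b)) stop("identical protospacers paired for gene(s): ",
                          paste(gsel[a == b], collapse = ", "))
    targ <- data.frame(element_id = paste0(gsel, "_", rp), gene = gsel,
                       rank_pair = rp, protospacer_a = unname(a),
                       protospacer_b = unname(b), ibc = NA_character_,
                       stringsAsFactors = FALSE)
    n_ctrl <- ceiling(nrow(targ) * control_fraction / (1 - control_fraction))
    if (n_ctrl > 0L) {
      if (nrow(control_pairs) < n_ctrl)
        stop("need ", n_ctrl, " control pairs for sublibrary ", rp,
             " but only ", nrow(control_pairs), " supplied")
      ctrl <- data.frame(
        element_id = sprintf("%s_%04d", control_label, seq_len(n_ctrl)),
        gene = control_label, rank_pair = "control",
        protospacer_a = toupper(control_pairs$protospacer_a[seq_len(n_ctrl)]),
        protospacer_b = toupper(control_pairs$protospacer_b[seq_len(n_ctrl)]),
        ibc = NA_character_, stringsAsFactors = FALSE)
      targ <- rbind(targ, ctrl)
    }
    rownames(targ) <- NULL
    out[[rp]] <- targ
  }
  out
}

#' Assemble the synthesis oligo for a dual-sgRNA element
#'
#' Concatenates, 5' to 3': PCR adaptor, `CCACCTTGTTG`, protospacer A, the
#' 44-nt constant linker carrying the BsmBI sites used to insert the second
#' promoter, protospacer B, `GTTTAAGAGCTAAGCTG`, PCR adaptor. The assembly
#' is bit-exact and invertible: [parse_dual_oligo()] recovers both guides by
#' splitting on the constant regions. A warning is raised if a protospacer
#' would make the split ambiguous.
#'
#' @param protospacer_a,protospacer_b Guide targeting sequences (19-20 nt).
#' @param adaptor_5,adaptor_3 PCR adaptor sequences (may be empty).
#' @return Character vector of uppercase oligo sequences.
#' @export
assemble_dual_oligo <- function(protospacer_a, protospacer_b,
                                adaptor_5 = "", adaptor_3 = "") {
  a <- validate_dna(protospacer_a, what = "protospacer A", lengths = c(19L, 20L))
  b <- validate_dna(protospacer_b, what = "protospacer B", lengths = c(19L, 20L))
  oligo <- paste0(toupper(adaptor_5), OLIGO_SPACER_5, a, OLIGO_LINKER, b,
                  OLIGO_SPACER_3, toupper(adaptor_3))
  chk <- tryCatch(parse_dual_oligo(oligo, nchar(adaptor_5), nchar(adaptor_3)),
                  error = function(e) NULL)
  if (is.null(chk) || !all(chk$protospacer_a == a & chk$protospacer_b == b))
    warning("a protospacer collides with a constant region; ",
            "oligo is not cleanly invertible")
  oligo
}

#' Recover the guide pair from a synthesis oligo
#'
#' @param oligo Character vector of oligos from [assemble_dual_oligo()].
#' @param n_adaptor_5,n_adaptor_3 Adaptor lengths to strip.
#' @return Data frame with columns `protospacer_a`, `protospacer_b`.
#' @export
parse_dual_oligo <- function(oligo, n_adaptor_5 = 0L, n_adaptor_3 = 0L) {
  core <- substr(toupper(oligo), n_adaptor_5 + 1L,
                 nchar(oligo) - n_adaptor_3)
  if (!all(startsWith(core, OLIGO_SPACER_5) & endsWith(core, OLIGO_SPACER_3)))
    stop("oligo lacks the constant flanking regions")
  core <- substr(core, nchar(OLIGO_SPACER_5) + 1L,
                 nchar(core) - nchar(OLIGO_SPACER_3))
  pos <- regexpr(OLIGO_LINKER, core, fixed = TRUE)
  if (any(pos < 0L)) stop("constant linker not found in oligo")
  data.frame(
    protospacer_a = substr(core, 1L, pos - 1L),
    protospacer_b = substr(core, pos + nchar(OLIGO_LINKER), nchar(core)),
    stringsAsFactors = FALSE)
}
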