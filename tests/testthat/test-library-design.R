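test_that("BsmBI filtering removes both site orientations and preserves order", {
  guides <- data.frame(
    guide_id = c("g1", "g2", "g3"),
    protospacer = c("ACGTCTCAACGGTTAACCGG",   # contains CGTCTC
                    "AAAAAAAAAAAAAAAAAAAA",
                    "TTGAGACGTTAACCGGTTAA"),  # contains GAGACG
    stringsAsFactors = FALSE)
  expect_equal(filter_bsmbi(guides)$guide_id, "g2")

  set.seed(42)
  rnd <- data.frame(guide_id = paste0("r", 1:400),
                    protospacer = random_protospacer(400))
  kept <- filter_bsmbi(rnd)
  expect_false(any(grepl("CGTCTC", kept$protospacer, fixed = TRUE)))
  expect_false(any(grepl("GAGACG", kept$protospacer, fixed = TRUE)))
  expect_false(is.unsorted(match(kept$guide_id, rnd$guide_id)))

  expect_error(
    filter_bsmbi(data.frame(guide_id = "bad",
                            protospacer = "ACGTACGTACGTACGTACGN")),
    "bad")
})

test_that("relative phenotypes scale to the strongest guide, keeping sign", {
  expect_equal(relative_phenotypes(c(g1 = -0.5, g2 = -0.25)),
               c(g1 = 1.0, g2 = 0.5))
  expect_equal(relative_phenotypes(c(g1 = -0.4, g2 = 0.1)),
               c(g1 = 1.0, g2 = -0.25))
  expect_equal(relative_phenotypes(c(g1 = -0.9)), c(g1 = 1.0))
  expect_warning(z <- relative_phenotypes(c(a = 0, b = 0)), "zero")
  expect_equal(unname(z), c(0, 0))
})

# independent oracle: explicit loops over screens, records and guide triples
brute_discriminant <- function(gene_stats, guide_stats, guide_gene,
                               hit_fdr = 0.05) {
  genes <- unique(gene_stats$gene)
  res <- data.frame(gene = genes, n_hit_screens = 0L, score = NA_real_)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    total <- NA_real_
    nh <- 0L
    for (sc in unique(gene_stats$screen_id)) {
      recs <- gene_stats[gene_stats$screen_id == sc & gene_stats$gene == g &
                           gene_stats$gene_fdr <= hit_fdr, , drop = FALSE]
      if (nrow(recs) == 0L) next
      nh <- nh + 1L
      ss <- guide_stats[guide_stats$screen_id == sc, , drop = FALSE]
      z <- (ss$phenotype - mean(ss$phenotype)) / sd(ss$phenotype)
      z <- z[guide_gene[ss$guide_id] == g]
      if (length(z) == 0L) next
      z_top <- z[order(-abs(z))][seq_len(min(3L, length(z)))]
      best <- 0
      for (ri in seq_len(nrow(recs))) {
        d <- -log10(recs$p_value[ri]) * mean(z_top)
        if (abs(d) > abs(best)) best <- d
      }
      total <- sum(c(total, abs(best)), na.rm = TRUE)
    }
    res$n_hit_screens[gi] <- nh
    res$score[gi] <- if (nh > 0L) total else NA_real_
  }
  res
}

test_that("discriminant scores match a brute-force oracle on random inputs", {
  set.seed(7)
  for (rep in 1:5) {
    screens <- paste0("S", 1:4)
    genes <- paste0("G", 1:6)
    guides <- expand.grid(gene = genes, k = 1:4, stringsAsFactors = FALSE)
    guides$guide_id <- paste0(guides$gene, "_", guides$k)
    guide_gene <- setNames(guides$gene, guides$guide_id)
    guide_stats <- do.call(rbind, lapply(screens, function(sc) {
      keep <- sample(nrow(guides), sample(12:24, 1))  # some guides unmeasured
      data.frame(screen_id = sc, guide_id = guides$guide_id[keep],
                 phenotype = rnorm(length(keep), sd = 0.3),
                 guide_fdr = runif(length(keep)), stringsAsFactors = FALSE)
    }))
    gene_stats <- expand.grid(screen_id = screens, gene = genes,
                              stringsAsFactors = FALSE)
    gene_stats$p_value <- 10^runif(nrow(gene_stats), -6, -0.01)
    gene_stats$gene_fdr <- runif(nrow(gene_stats), 0, 0.15)
    # a per-transcript duplicate record in one screen
    gene_stats <- rbind(gene_stats,
                        data.frame(screen_id = "S1", gene = "G1",
                                   p_value = 1e-5, gene_fdr = 0.01))

    got <- discriminant_scores(gene_stats, guide_stats, guide_gene)
    want <- brute_discriminant(gene_stats, guide_stats, guide_gene)
    got <- got[order(got$gene), ]; want <- want[order(want$gene), ]
    expect_equal(got$n_hit_screens, want$n_hit_screens)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("discriminant score arithmetic on forced cases", {
  # one hit screen, p = 1e-4, top-3 mean z = -2 -> |d| = 8
  gg <- setNames(rep("G1", 3), paste0("g", 1:3))
  gene_stats <- data.frame(screen_id = "S1", gene = "G1", p_value = 1e-4,
                           gene_fdr = 0.01)
  # 9 guides in the screen set the z-scale; G1's three guides at z ~ -2
  ph <- c(-2, -2, -2, rep(0, 5), 6) / 1  # mean 0 after centering? no - compute
  guide_stats <- data.frame(screen_id = "S1",
                            guide_id = c(paste0("g", 1:3), paste0("x", 1:6)),
                            phenotype = ph, guide_fdr = 0.5)
  got <- discriminant_scores(gene_stats, guide_stats, gg)
  z <- (ph - mean(ph)) / sd(ph)
  expect_equal(got$score[got$gene == "G1"], 4 * abs(mean(z[1:3])))
  # sum rule over two hit screens
  gene_stats2 <- rbind(gene_stats,
                       data.frame(screen_id = "S2", gene = "G1",
                                  p_value = 1e-2, gene_fdr = 0.04))
  guide_stats2 <- rbind(guide_stats,
                        transform(guide_stats, screen_id = "S2"))
  got2 <- discriminant_scores(gene_stats2, guide_stats2, gg)
  expect_equal(got2$score, got$score * (1 + 2 / 4))  # -log10 p: 4 then 2
  expect_equal(got2$n_hit_screens, 2L)
})

test_that("olfactory thresholds use the max with fallback to fewer hits", {
  olf <- data.frame(gene = c("o1", "o2", "o3"),
                    n_hit_screens = c(1L, 1L, 2L),
                    score = c(2.0, 3.1, 4.0))
  thr <- olfactory_thresholds(olf)
  expect_equal(unname(thr["1"]), 3.1)
  expect_equal(unname(thr["2"]), 4.0)
  expect_equal(unname(thr["3"]), 4.0)   # fallback: max over <= 3 hits
  expect_equal(unname(thr["4"]), 4.0)
  empty <- olfactory_thresholds(data.frame(gene = character(0),
                                           n_hit_screens = integer(0),
                                           score = numeric(0)))
  expect_true(all(is.infinite(empty)))
})

test_that("tier assignment follows the precedence rules and partitions genes", {
  genes <- c("ESS", "MULTI", "SCORED", "WEAK", "NONE", "UNKNOWN")
  k562 <- data.frame(gene = c("ESS", "MULTI", "SCORED", "WEAK", "NONE"),
                     p_value = c(1e-5, 1e-5, 0.5, 0.5, 0.5),
                     k562_gamma = c(-0.5, -0.1, 0, 0, 0))
  scores <- data.frame(gene = c("MULTI", "SCORED", "WEAK"),
                       n_hit_screens = c(6L, 2L, 2L),
                       score = c(NA, 9.0, 3.0))
  thr <- c("1" = 5, "2" = 5, "3" = 5, "4" = 5)
  tiers <- suppressMessages(assign_tiers(genes, k562, scores, thr))
  expect_equal(tiers$tier[match(c("ESS", "MULTI", "SCORED", "WEAK", "NONE",
                                  "UNKNOWN"), tiers$gene)],
               c(1L, 2L, 2L, 3L, 3L, 3L))
  # every gene gets exactly one tier
  expect_equal(sort(tiers$gene), sort(genes))
  expect_true(all(tiers$tier %in% 1:3))
  # tier-1 precedence: an essential gene hit in 6 screens is still tier 1
  k562b <- transform(k562, p_value = ifelse(gene == "MULTI", 1e-6, p_value),
                     k562_gamma = ifelse(gene == "MULTI", -0.4, k562_gamma))
  t2 <- suppressMessages(assign_tiers("MULTI", k562b, scores, thr))
  expect_equal(t2$tier, 1L)
})

test_that("guide ranking follows tier rules with lexicographic tie-break", {
  guides <- data.frame(
    guide_id = c("g1", "g2", "g3"), gene = "G",
    protospacer = c("CCCCCCCCCCCCCCCCCCCC", "AAAAAAAAAAAAAAAAAAAA",
                    "ACACACACACACACACACAC"),
    predicted_score = c(0.9, 0.7, 0.8), stringsAsFactors = FALSE)
  r3 <- rank_guides(guides, 3L)
  expect_equal(r3$guide_id, c("g1", "g3", "g2"))

  # equal predicted scores -> ascending protospacer
  gt <- transform(guides, predicted_score = 0.5)
  expect_equal(rank_guides(gt, 3L)$guide_id, c("g2", "g3", "g1"))

  # tier 2: a guide that scored (fdr < 0.01) outranks one that never did,
  # regardless of phenotype
  st <- data.frame(screen_id = "S1", guide_id = c("g1", "g2"),
                   phenotype = c(-0.1, -0.9), guide_fdr = c(0.005, 0.5))
  r2 <- rank_guides(guides, 2L, guide_stats = st, hit_screens = "S1")
  expect_equal(r2$guide_id[1], "g1")

  # tier 1: ranked by mean relative phenotype across hit screens
  st1 <- data.frame(screen_id = c("S1", "S1"), guide_id = c("g1", "g2"),
                    phenotype = c(-0.5, -0.25), guide_fdr = 0.5)
  r1 <- rank_guides(guides, 1L, guide_stats = st1, hit_screens = "S1")
  expect_equal(r1$guide_id[1:2], c("g1", "g2"))
  expect_equal(r1$mean_rel_phenotype[1:2], c(1.0, 0.5))
})

test_that("library construction pairs ranks and tops up controls to 5%", {
  mk_ranked <- function(n_genes, n_guides) {
    ps <- toy_guide_seq(seq_len(n_genes * n_guides))
    setNames(lapply(seq_len(n_genes), function(i) {
      data.frame(guide_id = paste0("G", i, "_", seq_len(n_guides)),
                 gene = paste0("G", i),
                 protospacer = ps[(i - 1) * n_guides + seq_len(n_guides)],
                 stringsAsFactors = FALSE)
    }), paste0("G", seq_len(n_genes)))
  }
  ctrl <- data.frame(protospacer_a = toy_guide_seq(3001:3100),
                     protospacer_b = toy_guide_seq(3101:3200))

  lib <- build_library(mk_ranked(950, 2), ctrl)
  el <- lib[["1_2"]]
  expect_equal(sum(el$rank_pair == "control"), 50L)
  expect_equal(nrow(el), 1000L)
  expect_equal(mean(el$rank_pair == "control"), 0.05)       # exactly 5%
  expect_null(lib[["3_4"]])

  # ceil arithmetic: 1000 targeting -> 53 controls
  lib2 <- build_library(mk_ranked(1000, 2), ctrl)
  expect_equal(sum(lib2[["1_2"]]$rank_pair == "control"), 53L)

  # a gene with exactly 4 guides is in 1_2 and 3_4, absent from 5_6
  r <- mk_ranked(20, 6)
  r[["G1"]] <- r[["G1"]][1:4, ]
  lib3 <- build_library(r, ctrl)
  expect_true("G1" %in% lib3[["1_2"]]$gene)
  expect_true("G1" %in% lib3[["3_4"]]$gene)
  expect_false("G1" %in% lib3[["5_6"]]$gene)
  # element counts: genes with enough guides + controls
  expect_equal(nrow(lib3[["5_6"]]), 19L + ceiling(19 * 0.05 / 0.95))

  expect_error(build_library(mk_ranked(950, 2), ctrl[1:10, ]), "50")
})

test_that("dual-oligo assembly is bit-exact and invertible", {
  o <- assemble_dual_oligo(strrep("A", 20), strrep("C", 20))
  expect_equal(nchar(o), 112L)
  expect_true(startsWith(o, "CCACCTTGTTGAAAA"))
  expect_equal(o, paste0("CCACCTTGTTG", strrep("A", 20),
                         "GTTTCAGAGCGAGACGTGCCTGCAGGATACGTCTCAGAAACATG",
                         strrep("C", 20), "GTTTAAGAGCTAAGCTG"))

  # differing 15-nt adaptors -> length 142
  o2 <- assemble_dual_oligo(strrep("A", 20), strrep("C", 20),
                            adaptor_5 = strrep("G", 15),
                            adaptor_3 = strrep("T", 15))
  expect_equal(nchar(o2), 142L)
  p2 <- parse_dual_oligo(o2, 15L, 15L)
  expect_equal(p2$protospacer_a, strrep("A", 20))

  # round-trip property on random guide pairs
  set.seed(11)
  a <- random_protospacer(200); b <- random_protospacer(200)
  oo <- suppressWarnings(assemble_dual_oligo(a, b))
  pp <- parse_dual_oligo(oo)
  expect_equal(pp$protospacer_a, a)
  expect_equal(pp$protospacer_b, b)
})
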