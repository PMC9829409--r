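toy_counts <- function() {
  m <- matrix(
    c(100, 100,    # E1
       49,  30,    # E2: < 50 at both timepoints -> excluded
       49, 200,    # E3: low only at T0 -> kept
        0, 120,    # E4: zero -> pseudocount
      100, 100,    # NTC1
      100, 100,    # NTC2
      100, 100),   # NTC3
    ncol = 2, byrow = TRUE,
    dimnames = list(c("E1", "E2", "E3", "E4", paste0("NTC", 1:3)),
                    c("s_t0", "s_tf")))
  storage.mode(m) <- "integer"
  m
}

toy_reps <- function() data.frame(replicate_id = "r1", t0_sample = "s_t0",
                                  tfinal_sample = "s_tf", doublings = 10)

test_that("count filters follow the pseudocount and <50-read rules", {
  fl <- apply_filters(toy_counts(), toy_reps())
  expect_true(fl$excluded[["E2"]])                 # (49, 30): both below 50
  expect_false(fl$excluded[["E3"]])                # (49, 200): one side ok
  expect_equal(fl$counts["E4", "s_t0"], 1)         # 0 -> pseudocount 1
  expect_equal(fl$counts["E3", "s_t0"], 49)        # non-zero counts untouched
  expect_error(apply_filters(toy_counts(), data.frame(
    replicate_id = "r", t0_sample = "nope", tfinal_sample = "s_tf",
    doublings = 10)), "nope")
  # exclusion is OR over replicates
  reps2 <- rbind(toy_reps(),
                 data.frame(replicate_id = "r2", t0_sample = "s_tf",
                            tfinal_sample = "s_t0", doublings = 10))
  fl2 <- apply_filters(toy_counts(), reps2)
  expect_true(fl2$excluded[["E2"]])
})

test_that("gamma centers NTCs at zero and matches forced arithmetic", {
  cnt <- matrix(c(100, 25,
                  100, 100, 100, 100, 100, 100),
                ncol = 2, byrow = TRUE,
                dimnames = list(c("E", paste0("N", 1:3)), c("t0", "tf")))
  reps <- data.frame(t0_sample = "t0", tfinal_sample = "tf", doublings = 10)
  g <- gamma_scores(cnt, reps, paste0("N", 1:3))
  expect_equal(unname(g["E"]), log2(0.25) / 10)    # depth scale cancels
  expect_equal(unname(g["N1"]), 0)                 # element at the NTC median
  expect_equal(median(g[paste0("N", 1:3)]), 0)

  expect_error(gamma_scores(cnt, reps, "absent"), "non-targeting")
})

test_that("gamma equals a brute-force recomputation and is depth-invariant", {
  set.seed(9)
  for (rep in 1:3) {
    n <- 30
    ids <- c(paste0("E", 1:(n - 6)), paste0("NTC", 1:6))
    cnt <- matrix(rpois(2 * n, 500) + 1, ncol = 2,
                  dimnames = list(ids, c("t0", "tf")))
    reps <- data.frame(t0_sample = "t0", tfinal_sample = "tf",
                       doublings = 7.3)
    g <- gamma_scores(cnt, reps, paste0("NTC", 1:6))

    # oracle: explicit loops
    tot0 <- sum(cnt[, 1]); totf <- sum(cnt[, 2])
    lr <- numeric(n)
    for (i in 1:n)
      lr[i] <- log2((cnt[i, 2] * 1e6 / totf) / (cnt[i, 1] * 1e6 / tot0))
    med <- median(lr[grepl("NTC", ids)])
    expect_equal(unname(g), (lr - med) / 7.3, tolerance = 1e-12)

    # RPM property: uniform depth rescaling of one sample changes nothing
    cnt2 <- cnt; cnt2[, 2] <- cnt2[, 2] * 7
    g2 <- gamma_scores(cnt2, reps, paste0("NTC", 1:6))
    expect_equal(g2, g, tolerance = 1e-12)
    expect_equal(median(g[grepl("NTC", ids)]), 0)
  }
})

test_that("replicate aggregation averages surviving replicates and flags partials", {
  gm <- matrix(c(-0.2, -0.3,
                 -0.4, NA,
                 NA, NA),
               ncol = 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("r1", "r2")))
  ag <- aggregate_replicates(gm, gene_of = c(a = "G1", b = "G1", c = "G2"))
  expect_equal(ag$element$gamma, c(-0.25, -0.4, NA))
  expect_equal(ag$element$partial, c(FALSE, TRUE, FALSE))
  expect_equal(ag$gene$gamma[ag$gene$gene == "G1"], mean(c(-0.25, -0.4)))
  # a gene with one element inherits its gamma
  ag2 <- aggregate_replicates(gm[1, , drop = FALSE], gene_of = c(a = "G1"))
  expect_equal(ag2$gene$gamma, -0.25)
})

test_that("recall AUC matches the exhaustive concordant-pair fraction", {
  g <- c(p1 = -0.5, p2 = -0.5, n1 = 0, n2 = 0)
  expect_equal(essential_recall_auc(g, c("p1", "p2"), c("n1", "n2")), 1)
  gid <- c(p1 = -0.1, p2 = -0.1, n1 = -0.1, n2 = -0.1)
  expect_equal(essential_recall_auc(gid, c("p1", "p2"), c("n1", "n2")), 0.5)

  # 5-item toy and random inputs vs explicit pair counting with ties = 1/2
  pair_auc <- function(pos, neg) {
    s <- 0
    for (p in pos) for (q in neg)
      s <- s + (if (-p > -q) 1 else if (-p == -q) 0.5 else 0)
    s / (length(pos) * length(neg))
  }
  g5 <- c(a = -0.4, b = -0.1, c = 0.0, d = -0.2, e = 0.1)
  expect_equal(essential_recall_auc(g5, c("a", "b"), c("c", "d", "e")),
               pair_auc(g5[c("a", "b")], g5[c("c", "d", "e")]))
  set.seed(13)
  for (rep in 1:5) {
    vals <- round(rnorm(40), 1)              # many ties
    names(vals) <- paste0("x", 1:40)
    pos <- names(vals)[1:15]; neg <- names(vals)[16:40]
    expect_equal(essential_recall_auc(vals, pos, neg),
                 pair_auc(vals[pos], vals[neg]))
  }
  expect_error(essential_recall_auc(g5, "nonexistent", c("c")), "non-empty")
})

test_that("library comparison reports means, Mann-Whitney p and percent change", {
  set.seed(21)
  genes <- paste0("G", 1:500)
  g1 <- setNames(rnorm(500, -0.20, 0.05), genes)
  same <- compare_gene_sets(g1, g1, genes)
  expect_equal(same$percent_change, 0)
  expect_gt(same$mannwhitney_p, 0.9)

  g2 <- setNames(rnorm(500, -0.26, 0.05), genes)
  cmp <- compare_gene_sets(g1, g2, genes)
  expect_equal(cmp$n, 500)
  # forced arithmetic on the means themselves
  expect_equal(cmp$percent_change,
               100 * (cmp$mean2 - cmp$mean1) / abs(cmp$mean1))
  expect_lt(cmp$mannwhitney_p, 1e-10)
  # mean -0.20 vs -0.26 gives a 30% change in magnitude
  expect_equal(abs(100 * (-0.26 - -0.20) / abs(-0.20)), 30)
  expect_error(compare_gene_sets(g1, g2, "absent"), "empty")
})

test_that("competitive growth defect normalizes to day 0", {
  # ratio halves by day 19
  cg <- competitive_growth_defect(c(0, 10, 19), c(0.8, 0.6, 0.4))
  expect_equal(cg$course$log2_normalized[1], 0)
  expect_equal(cg$course$log2_normalized[3], -1)
  expect_equal(cg$percent_per_day, 100 * (-1) / 19)

  flat <- competitive_growth_defect(c(0, 19), c(1.3, 1.3))
  expect_equal(flat$percent_per_day, 0)

  # three-point course vs hand computation
  cg3 <- competitive_growth_defect(c(0, 7, 14), c(1.0, 0.7, 0.45),
                                   horizon_day = 14)
  expect_equal(cg3$course$log2_normalized, log2(c(1, 0.7, 0.45)))
  expect_equal(cg3$percent_per_day, 100 * log2(0.45) / 14)

  expect_error(competitive_growth_defect(c(1, 19), c(1, 0.5)), "day-0")
})
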