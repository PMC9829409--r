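## Seeded simulator for dual-sgRNA growth screens: synthetic library,
## lentiviral co-packaging with template switching, fitness-driven growth
## and multinomial sequencing, with complete ground truth so the counting
## and gamma machinery can be validated end to end.
##
## The packaging model: each virion carries two genomes drawn i.i.d. from
## the element pool; with probability p_switch the reverse transcriptase
## switches templates in the long invariant region between the two guide
## cassettes, so the integrated cassette carries guide A of genome 1 and
## guide B of genome 2. A switch is *detectable* only when the two genomes
## target different genes (or are different control elements), so the
## expected detectable fraction is p_switch * (1 - sum(f_g^2)) for pool
## frequencies f. One integration per cell (low-MOI regime).

#' Simulation configuration
#'
#' All randomness flows from `seed`; identical configurations produce
#' byte-identical simulated reads.
#'
#' @param n_genes Number of targeting genes (one dual element each).
#' @param seed Integer seed (mandatory; keep below 2^31 - 2).
#' @param ntc_fraction Fraction of library elements that are non-targeting
#'   controls (default 0.05).
#' @param p_switch Per-integration template-switch probability (default 0.3,
#'   the regime observed in K562/RPE1/Jurkat screens).
#' @param fitness Named numeric vector of true gamma per gene (growth effect
#'   per doubling); genes omitted default to 0; controls are always 0.
#' @param doublings Population doublings between T0 and Tfinal.
#' @param depth Sequencing reads per sample.
#' @param n_cells Number of transduced cells (integrations).
#' @param read2_revcomp Emit Read 2 as the reverse complement of the guide-B
#'   key (default TRUE, matching the counter's default orientation).
#' @param chimera_fitness How a switched cassette grows: `"guide_a"` (the
#'   guide-A gene's gamma; single-guide knockdown still occurs — the
#'   default), `"mean"` of the two genes, or `"zero"`.
#' @param pool Optional element frequency vector (default uniform).
#' @param control_label Gene label for control elements.
#' @param ibc_whitelist Optional IBC set tagging integrations; default is the
#'   first 16 barcodes of [generate_ibcs()].
#' @param sample_index Named character vector of 8-nt Index-1 sequences for
#'   the two samples (names `T0`, `Tfinal`).
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_genes, seed, ntc_fraction = 0.05, p_switch = 0.3,
                       fitness = NULL, doublings = 10, depth = 1e6,
                       n_cells = 1e5, read2_revcomp = TRUE,
                       chimera_fitness = c("guide_a", "mean", "zero"),
                       pool = NULL, control_label = "non-targeting",
                       ibc_whitelist = NULL,
                       sample_index = c(T0 = "AAAAAAAA",
                                        Tfinal = "CCCCCCCC")) {
  stopifnot(n_genes >= 1L, p_switch >= 0, p_switch <= 1,
            ntc_fraction >= 0, ntc_fraction < 1,
            depth > 0, n_cells > 0, doublings > 0)
  if (missing(seed)) stop("seed is mandatory")
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  fit <- stats::setNames(rep(0, n_genes), genes)
  if (!is.null(fitness)) {
    unknown <- setdiff(names(fitness), genes)
    if (length(unknown) > 0L) stop("fitness names not in gene set: ",
                                   paste(utils::head(unknown, 5), collapse = ", "))
    fit[names(fitness)] <- fitness
  }
  cfg <- list(n_genes = as.integer(n_genes), genes = genes,
              seed = as.integer(seed), ntc_fraction = ntc_fraction,
              p_switch = p_switch, fitness = fit, doublings = doublings,
              depth = as.integer(depth), n_cells = as.integer(n_cells),
              read2_revcomp = isTRUE(read2_revcomp),
              chimera_fitness = match.arg(chimera_fitness),
              pool = pool, control_label = control_label,
              ibc_whitelist = ibc_whitelist, sample_index = sample_index)
  class(cfg) <- "sim_config"
  cfg
}

#' Deterministic synthetic dual-sgRNA library
#'
#' Guide sequences encode their index in binary over the alphabet {A, C} in
#' the first positions and are padded to 20 nt, so (i) all 19-nt prefixes
#' are pairwise distinct, (ii) no guide can contain a BsmBI site (which
#' requires G/T), and (iii) [build_reference()] always succeeds. Control
#' elements number `ceiling(T * f / (1 - f))` for `T` targeting elements at
#' control fraction `f`.
#'
#' @param cfg A [sim_config()].
#' @return Data frame of elements: `element_id`, `gene`, `protospacer_a`,
#'   `protospacer_b`, `ibc` (NA).
#' @export
sim_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_t <- cfg$n_genes
  n_c <- as.integer(ceiling(n_t * cfg$ntc_fraction / (1 - cfg$ntc_fraction)))
  n_guides <- 2L * (n_t + n_c)
  width <- max(12L, ceiling(log2(n_guides + 1L)))
  if (width > 19L) stop("library too large for distinct 19-nt prefixes")
  enc <- function(idx) {     # idx 1-based -> {A,C}^width + pad to 20
    bits <- matrix("A", length(idx), width)
    v <- idx
    for (j in width:1L) {
      bits[, j] <- ifelse(v %% 2L == 1L, "C", "A")
      v <- v %/% 2L
    }
    pad <- strrep("AC", 10L)
    paste0(apply(bits, 1L, paste, collapse = ""),
           substr(pad, 1L, 20L - width))
  }
  ids <- seq_len(n_t + n_c)
  pa <- enc(2L * ids - 1L)
  pb <- enc(2L * ids)
  data.frame(
    element_id = c(cfg$genes, sprintf("%s_%02d", cfg$control_label,
                                      seq_len(n_c))),
    gene = c(cfg$genes, rep(cfg$control_label, n_c)),
    protospacer_a = pa, protospacer_b = pb, ibc = NA_character_,
    stringsAsFactors = FALSE)
}

#' Simulate lentiviral integrations with template switching
#'
#' @param cfg A [sim_config()].
#' @param library Element table from [sim_library()] (or any table with the
#'   same columns).
#' @return Object of class `"sim_truth"`: `integrations` (data frame `cell`,
#'   `elem_a`, `elem_b`, `switched`, `detectable`, `ibc`), `true_gamma`
#'   (named per element), `realized_recomb_fraction`, and the library.
#' @export
simulate_integrations <- function(cfg, library) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nel <- nrow(library)
  pool <- if (is.null(cfg$pool)) rep(1 / nel, nel) else cfg$pool / sum(cfg$pool)
  n <- cfg$n_cells
  g1 <- sample.int(nel, n, replace = TRUE, prob = pool)
  g2 <- sample.int(nel, n, replace = TRUE, prob = pool)
  sw <- stats::runif(n) < cfg$p_switch
  elem_b <- ifelse(sw, g2, g1)
  is_ctrl <- library$gene == cfg$control_label
  detectable <- sw & (library$gene[g1] != library$gene[g2] |
                        (is_ctrl[g1] & is_ctrl[g2] & g1 != g2))
  ibc <- cfg$ibc_whitelist
  if (is.null(ibc)) ibc <- generate_ibcs(max_n = 16L)
  cell_ibc <- ibc[sample.int(length(ibc), n, replace = TRUE)]

  true_gamma <- ifelse(is_ctrl, 0, cfg$fitness[library$gene])
  truth <- list(
    integrations = data.frame(cell = seq_len(n), elem_a = g1,
                              elem_b = elem_b, switched = sw,
                              detectable = detectable, ibc = cell_ibc,
                              stringsAsFactors = FALSE),
    true_gamma = stats::setNames(as.numeric(true_gamma), library$element_id),
    realized_recomb_fraction = mean(detectable),
    library = library)
  class(truth) <- "sim_truth"
  truth
}

#' Simulate growth and multinomial sequencing
#'
#' T0 reads are drawn uniformly over integrations; each integration's
#' Tfinal weight is `2^(gamma * doublings)` with gamma determined by its
#' cassette (see `chimera_fitness` in [sim_config()]), and Tfinal reads are
#' drawn multinomially at the configured depth. Read 1 is the 19-nt guide-A
#' key of the cassette, Read 2 the guide-B key (reverse-complemented if
#' configured), Index 1 the sample index and Index 2 the integration's IBC.
#'
#' @param cfg A [sim_config()].
#' @param truth A [simulate_integrations()] result.
#' @return Object of class `"sim_run"`: `reads` (data frame `id`, `r1`,
#'   `r2`, `i1`, `i2`, `sample`), `counts` (element x sample matrix of
#'   matched-by-construction read counts — what an error-free counter must
#'   reproduce exactly), `totals` (expected per-sample matched / recombined
#'   / unmapped), `sample_sheet`, and `library`.
#' @export
simulate_growth_and_sequencing <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(cfg$seed + 1L)
  lib <- truth$library
  it <- truth$integrations
  nel <- nrow(lib)
  n <- nrow(it)

  gene_gamma <- truth$true_gamma                     # per element
  g_a <- unname(gene_gamma[it$elem_a])
  g_b <- unname(gene_gamma[it$elem_b])
  cas_gamma <- switch(cfg$chimera_fitness,
                      guide_a = g_a,
                      mean = ifelse(it$switched, (g_a + g_b) / 2, g_a),
                      zero = ifelse(it$detectable, 0, g_a))
  w_final <- 2 ^ (cas_gamma * cfg$doublings)

  ka <- substr(lib$protospacer_a, 1L, 19L)
  kb <- substr(lib$protospacer_b, 1L, 19L)
  r2_of_elem <- if (cfg$read2_revcomp) revcomp(kb) else kb
  matched_cell <- !it$switched |
    (lib$gene[it$elem_a] == lib$gene[it$elem_b] & !it$detectable)

  samples <- names(cfg$sample_index)
  counts <- matrix(0L, nel, length(samples),
                   dimnames = list(lib$element_id, samples))
  totals <- data.frame(sample = samples, matched = 0L, recombined = 0L,
                       unmapped = 0L, stringsAsFactors = FALSE)
  reads <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    prob <- if (s == 1L) rep(1, n) else w_final   # first sample is T0
    per_cell <- as.vector(stats::rmultinom(1L, cfg$depth, prob))
    cell <- rep.int(seq_len(n), per_cell)
    ea <- it$elem_a[cell]; eb <- it$elem_b[cell]
    m <- matched_cell[cell]
    counts[, s] <- tabulate(ea[m], nbins = nel)
    totals$matched[s] <- sum(m)
    totals$recombined[s] <- sum(!m)
    reads[[s]] <- data.frame(
      id = sprintf("%s_%07d", samples[s], seq_along(cell)),
      r1 = ka[ea], r2 = r2_of_elem[eb],
      i1 = unname(cfg$sample_index[samples[s]]),
      i2 = it$ibc[cell], sample = samples[s],
      stringsAsFactors = FALSE)
  }
  out <- list(reads = do.call(rbind, reads), counts = counts,
              totals = totals,
              sample_sheet = data.frame(sample = samples,
                                        index = unname(cfg$sample_index),
                                        stringsAsFactors = FALSE),
              library = lib)
  class(out) <- "sim_run"
  out
}

#' Write simulated reads as a four-file FASTQ set
#'
#' @param run A [simulate_growth_and_sequencing()] result.
#' @param prefix Output path prefix; files `<prefix>_R1.fastq`, `_R2`,
#'   `_I1`, `_I2` are written (add `.gz` to `suffix` to compress).
#' @param suffix File suffix (default `".fastq"`).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_sim_fastq <- function(run, prefix, suffix = ".fastq") {
  stopifnot(inherits(run, "sim_run"))
  paths <- stats::setNames(paste0(prefix, "_", c("R1", "R2", "I1", "I2"),
                                  suffix), c("r1", "r2", "i1", "i2"))
  write_fastq(run$reads$id, run$reads$r1, paths["r1"])
  write_fastq(run$reads$id, run$reads$r2, paths["r2"])
  write_fastq(run$reads$id, run$reads$i1, paths["i1"])
  write_fastq(run$reads$id, run$reads$i2, paths["i2"])
  invisible(paths)
}

#' Simulate a Perturb-seq readout with programmed knockdown
#'
#' Every targeting element gets `cells_per_element` cells whose target-gene
#' Poisson mean is scaled by the element's programmed fraction of mRNA
#' remaining (except a `nonresponder_fraction` of cells, which stay at the
#' unperturbed mean); NTC cells are unscaled. Background genes pad the
#' per-cell totals so depth normalisation behaves realistically.
#'
#' @param elements Element table (`element_id`, `gene`).
#' @param fraction_remaining Named numeric (by element id) of programmed
#'   fractions of target mRNA remaining; NTC elements are ignored.
#' @param ntc_elements Character vector of NTC element ids.
#' @param seed Integer seed.
#' @param cells_per_element Cells per targeting element.
#' @param ntc_cells Number of NTC cells.
#' @param base_expression Poisson mean per gene (scalar or named by gene).
#' @param n_background_genes Untargeted genes added to the matrix (default
#'   200, so a single target gene is a small share of each cell's total and
#'   per-cell depth normalisation behaves as it does on real transcriptomes).
#' @param nonresponder_fraction Per-element fraction of cells with no
#'   knockdown.
#' @return List: `expr` (gene x cell count matrix), `assignments` (data
#'   frame `cell`, `element`), `nonresponder` (logical per cell).
#' @export
simulate_perturbseq <- function(elements, fraction_remaining, ntc_elements,
                                seed, cells_per_element = 50L,
                                ntc_cells = 200L, base_expression = 10,
                                n_background_genes = 200L,
                                nonresponder_fraction = 0) {
  set.seed(seed)
  targ <- elements[!(elements$element_id %in% ntc_elements), , drop = FALSE]
  genes <- unique(c(targ$gene,
                    sprintf("BG%04d", seq_len(n_background_genes))))
  base <- if (length(base_expression) == 1L)
    stats::setNames(rep(base_expression, length(genes)), genes)
  else base_expression[genes]

  cell_elem <- c(rep(targ$element_id, each = cells_per_element),
                 rep(ntc_elements[1], ntc_cells))
  n_cells <- length(cell_elem)
  cell_ids <- sprintf("CELL%05d", seq_len(n_cells))
  nonresp <- stats::runif(n_cells) < nonresponder_fraction &
    cell_elem %in% targ$element_id

  mu <- matrix(base, length(genes), n_cells,
               dimnames = list(genes, cell_ids))
  for (i in seq_len(nrow(targ))) {
    el <- targ$element_id[i]
    fr <- fraction_remaining[[el]]
    cl <- which(cell_elem == el & !nonresp)
    mu[targ$gene[i], cl] <- mu[targ$gene[i], cl] * fr
  }
  expr <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
                 dimnames = dimnames(mu))
  list(expr = expr,
       assignments = data.frame(cell = cell_ids, element = cell_elem,
                                stringsAsFactors = FALSE),
       nonresponder = stats::setNames(nonresp, cell_ids))
}
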