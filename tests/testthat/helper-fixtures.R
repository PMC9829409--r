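# Shared in-code fixtures. Guides use an {A,C} binary index encoding (as the
# simulator does) so 19-nt prefixes are distinct and no BsmBI site can occur.

toy_guide_seq <- function(idx, len = 20L) {
  vapply(idx, function(i) {
    bits <- character(12L)
    for (j in 12L:1L) { bits[j] <- if (i %% 2L == 1L) "C" else "A"; i <- i %/% 2L }
    paste0(paste(bits, collapse = ""), substr(strrep("AC", 10L), 1L, len - 12L))
  }, character(1))
}

# small dual-element reference: 3 targeting genes + 2 NTC pairs
toy_elements <- function() {
  data.frame(
    element_id = c("GENE1", "GENE2", "GENE3", "non-targeting_01",
                   "non-targeting_02"),
    gene = c("GENE1", "GENE2", "GENE3", "non-targeting", "non-targeting"),
    protospacer_a = toy_guide_seq(c(1L, 3L, 5L, 7L, 9L)),
    protospacer_b = toy_guide_seq(c(2L, 4L, 6L, 8L, 10L)),
    ibc = NA_character_,
    stringsAsFactors = FALSE)
}

# read pair (r1, r2) for a given element pair of a reference, honouring the
# counter's default read-2 orientation
toy_read_pair <- function(el, elem_a, elem_b, read2_revcomp = TRUE) {
  r1 <- substr(el$protospacer_a[elem_a], 1L, 19L)
  r2 <- substr(el$protospacer_b[elem_b], 1L, 19L)
  if (read2_revcomp) r2 <- revcomp(r2)
  list(r1 = r1, r2 = r2)
}

random_protospacer <- function(n, len = 20L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
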