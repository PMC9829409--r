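---
title: "Methods: dual-sgRNA CRISPRi screen design and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-sgRNA CRISPRi screen design and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualguide)
```

This vignette documents the statistical and sequence-design methods
implemented in **dualguide**, with the reasoning behind each modelling
choice. The package covers the full lifecycle of a compact dual-sgRNA CRISPRi
screen: selecting guides, assembling the library, barcoding clonal reporter
lines, counting sequencing reads in the presence of lentiviral
recombination, estimating growth phenotypes, quantifying knockdown, and
simulating the whole pipeline against known ground truth.

## 1. The dual-sgRNA design

Each library element expresses two sgRNAs against the same gene from tandem
U6 cassettes on one lentiviral vector. Pairing guides raises effective
knockdown (the element is as good as its better guide, often better) and
halves the number of elements needed per gene, so a genome-scale library fits
in a few sublibraries. The cost is a more complex molecule: two variable
regions per element, and vulnerability to lentiviral template switching
(section 4).

Elements are synthesized as single oligos:

```
[adaptor5] [11-nt spacer] [guide A, 20 nt] [44-nt linker with BsmBI sites]
[guide B, 20 nt] [17-nt scaffold start] [adaptor3]
```

`assemble_dual_oligo()` produces this layout (112 nt without adaptors) and
`parse_dual_oligo()` inverts it exactly. The internal linker carries two
BsmBI recognition sites for two-step Golden-Gate insertion of the constant
region between the guides; consequently any protospacer containing a BsmBI
site (`GAGACG`/`CGTCTC`) would be mis-cut and is removed up front by
`filter_bsmbi()`.

## 2. Guide selection: the three-tier system

Genes are assigned to tiers by the strength of empirical evidence
(`assign_tiers()`):

- **Tier 1** — the gene scored in a high-coverage K562 CRISPRi growth
  screen with p < 0.001 and gamma < −0.2. These genes have directly measured,
  strong guides.
- **Tier 2** — evidence aggregated across a panel of published screens:
  either the gene is a hit (gene-level FDR ≤ 0.05) in at least five screens,
  or its *discriminant score* exceeds a null threshold. The score
  (`discriminant_scores()`) is, per hit screen,
  −log10(p) × mean z-score of the three guides with largest |z|, taking the
  maximum over multiple records of the same gene within a screen (e.g.
  per-transcript entries), then summed over hit screens.
- **Tier 3** — everything else; guides fall back to predicted activity
  scores.

The Tier-2 threshold is calibrated on olfactory receptor genes
(`olfactory_thresholds()`), which are transcriptionally silent in screening
cell lines and so act as a biological null: the threshold at *k* hit screens
is the maximum olfactory discriminant score observed at exactly *k* hits
(falling back to ≤ *k*, or +Inf when no olfactory gene reached *k* hits).
This makes the cutoff an empirical false-positive bound rather than a tuned
constant.

Within a gene, a guide is *empirically eligible* if its guide-level FDR is
below 0.01 in at least one hit screen. Eligible guides are ranked by mean
**relative phenotype** — each guide's phenotype divided by the phenotype of
the strongest guide in that screen, so the best guide scores 1.0 and the
scale is comparable across screens of different effect sizes
(`relative_phenotypes()`). Ineligible or unmeasured guides are appended,
ranked by predicted score; all ties break lexicographically on the
protospacer so the ranking is fully deterministic (`rank_guides()`).

`build_library()` pairs ranked guides (1st+2nd, 3rd+4th, 5th+6th) into up to
three elements per gene and pads each sublibrary with non-targeting control
pairs. For a control fraction *f* of the final library,
`n_controls = ceiling(T f / (1 − f))` targeting elements *T*; a 950-gene
sublibrary (950 elements per rank pair) therefore gets exactly 50 controls —
5% of 1000.

## 3. Internal barcodes (IBCs)

Clonal reporter lines are tagged with an 8-nt barcode knocked into a fixed
locus, read out as index read 2. Requirements: enough barcodes for hundreds
of lines, robustness to sequencing errors, and compatibility with the
cloning enzymes. `generate_ibcs()` scans all 4^8 = 65,536 8-mers in
lexicographic order, keeps those with GC between 25% and 75% (inclusive) and
no BsmBI site, and greedily accepts any candidate at Hamming distance ≥ 4
from every accepted barcode.

Minimum distance 4 means any single sequencing error is *correctable* (the
read is still uniquely nearest to its true barcode) and any double error is
*detectable*. The demultiplexer (`count_run()`, `ibc_whitelist`) exploits
exactly the correction radius: it rescues reads at Hamming distance ≤ 1 from
a whitelisted barcode and discards anything farther.

The full scan yields **234** barcodes — this is the package's headline design
result, recomputed from scratch by `scripts/acceptance.R`. Greedy
lexicographic selection is deterministic and, at these sizes, within a few
percent of the best known packings; determinism matters more here than
squeezing out extra codes, since 234 comfortably exceeds the ~215 needed.

`assemble_ibc_donor()` embeds the reverse complement of a barcode between
fixed homology arms, giving the 59-nt single-stranded donor used for
knock-in; `parse_ibc_donor()` inverts it.

## 4. Template switching and recombination-aware counting

Lentiviral particles package two genome copies, and reverse transcriptase
switches templates between them. When a cell's virion carries genomes from
two different library elements, the integrated provirus can end up with
guide A from one element and guide B from another. With switching probability
$p$ and element frequencies $f_g$ (by gene), the expected *detectable*
recombinant fraction is

$$ p \left(1 - \sum_g f_g^2 \right), $$

since a switch between two copies of the same gene's element is invisible.
For a uniform library of $n$ genes this is $p(1 - 1/n)$, essentially $p$
itself at screen scale — observed rates around 25–30% of mapped reads are
expected behaviour, not a failed prep.

`count_run()` therefore never assumes concordance. Both reads are matched
exactly against 19-nt guide prefixes (read 2 is reverse-complemented by
default); a pair is **matched** when both guides belong to the same gene
(same *element* for non-targeting controls, whose "gene" label is shared),
**recombined** when both sides map but disagree, and **unmapped** otherwise.
Recombined reads are excluded from the count matrix but tallied per
contributing element and per observed element pair, because they carry
signal: an element whose intact copies drop out of the population retains
its chimeric copies (which grow at the partner's rate under the default
model), so its *apparent* per-element recombination rate rises. The
simulator reproduces this confound, and the test suite asserts the
anticorrelation between fitness and apparent rate.

Exact matching is a deliberate choice: with 19-nt prefixes the library is
constructed collision-free (`build_reference()` errors on any prefix
collision), mismatch tolerance on the protospacer would risk crediting
recombinants or sequencing errors to the wrong element, and index reads —
where error tolerance is safe by code design — get a 1-mismatch rescue
instead.

## 5. Growth phenotypes (gamma)

For element $i$ with reads-per-million $r_i(t)$:

$$ \gamma_i = \frac{\log_2 \frac{r_i(T_f)}{r_i(T_0)} - \mathrm{median}_{\mathrm{NTC}} \log_2 \frac{r(T_f)}{r(T_0)}}{\text{doublings}} $$

Centring on the non-targeting-control median anchors "no phenotype" at zero
regardless of how much of the library depletes; dividing by population
doublings puts screens of different lengths on one scale (gamma = −0.3 means
the knockdown population doubles 0.7× for every control doubling).

Count filters (`apply_filters()`) run on **raw** counts before any
pseudocount: an element is excluded if it has fewer than 50 reads at both
T0 *and* T-final in **any** replicate (an element lost in one replicate
cannot be averaged honestly), and zero counts then receive a pseudocount of
1 so log-ratios stay finite. `aggregate_replicates()` averages surviving
replicates per element (flagging partial coverage) and averages elements per
gene.

### Calibrated Monte-Carlo error for validation

When validating estimated gammas against simulator ground truth, the errors
of all elements share one component: the NTC-median offset, a single random
quantity (the median of a few dozen noisy control log-ratios) subtracted
from every element. The naive standard error of the mean error,
$\mathrm{sd}(e_i)/\sqrt{n}$, ignores this correlation and is far too small —
at scale, a mean error of ~0.0014 gamma units sits several naive SEs from
zero while being entirely explained by the offset. `gamma_bias_summary()`
therefore reports

$$ \mathrm{SE}_\text{total}^2 = \mathrm{Var}_\text{boot}\!\left(\mathrm{median}_\mathrm{NTC}\right) + \frac{\mathrm{sd}(e_i)^2}{n}, $$

with the first term bootstrapped over the control gammas. This is the
statistically correct yardstick for "unbiased", not a widened tolerance: the
estimator has no systematic bias, only a shared draw.

`essential_recall_auc()` computes the area under the recall curve for known
essentials against controls via the rank-sum identity with midranks
(ties count ½), and `compare_gene_sets()` uses the normal-approximation
Mann–Whitney test (`stats::wilcox.test`) with percent change defined as
$100\,(m_2 - m_1)/|m_1|$.

## 6. Knockdown metrics

`perturbseq_knockdown()` estimates the fraction of target expression
remaining from single-cell data: each cell is depth-normalized to 10,000
counts, then the ratio of mean normalized target expression in the
element's cells to that in NTC cells is the fraction remaining (ratio of
means, not mean of ratios — robust to cells with zero counts).
`summarize_per_gene()` reports mean-of-elements and best-of-elements per
gene. `flow_knockdown()` is the background-subtracted median ratio from
flow cytometry, $100(1 - (t - b)/(c - b))$. `no_knockdown_fraction()`
reports the percentage of target cells at or above a low quantile (default
5%) of the NTC distribution — by construction, a fully non-responding
population scores ~95 and a fully responding one ~0; a mixture with
non-responder fraction $q$ scores approximately $95q$.

## 7. The simulator

The simulator exists to validate every analysis step against ground truth,
so its design favours provable cleanliness and exact bookkeeping:

- **Library**: protospacers are 20-mers over the alphabet {A, C}, encoding
  the guide's index in "binary". This guarantees no BsmBI site (which
  requires G), pairwise-distinct 19-nt prefixes, and valid DNA — the
  synthetic library passes the same `filter_bsmbi()` and
  `build_reference()` checks as a real one.
- **Integration**: each of `n_cells` cells draws two genomes i.i.d. from the
  library; with probability `p_switch` the provirus is chimeric (guide A
  from genome 1, guide B from genome 2). The realized detectable fraction
  converges on the closed form of section 4, and the tests check it at 3
  binomial standard errors.
- **Growth**: cell lineages are reweighted by $2^{\gamma \cdot
  \text{doublings}}$; the first sample in `sample_index` is T0 (uniform
  weights), later samples use grown weights. Chimeric integrations grow at
  the guide-A gene's rate by default (`chimera_fitness = "guide_a"`),
  reflecting that a chimera still expresses both guides; `"mean"` and
  `"zero"` are available for sensitivity analysis.
- **Sequencing**: reads are multinomial draws over integrations, error-free.
  The realized draw is also returned as a count matrix, so
  `count_run()` on the simulator's FASTQ output must reproduce it
  *identically* — the round trip is tested byte-exactly, separating counting
  bugs from sampling noise.
- **Perturb-seq** (`simulate_perturbseq()`): Poisson expression with a
  programmed fraction remaining for target cells, 200 background genes by
  default (so per-cell depth normalization does not visibly inflate the
  measured fraction when the target drops — with few genes the target is a
  large share of the cell's counts and knocking it down deflates the
  denominator), and an optional non-responder fraction whose cells keep full
  expression.
- **Determinism**: `simulate_integrations()` seeds from `cfg$seed` and
  `simulate_growth_and_sequencing()` from `cfg$seed + 1`, so the same
  configuration reproduces byte-identical reads and counts while the two
  stages stay independently seeded.

Simulator defaults are the study conditions they represent; the test suite's
tolerances are derived from the sampling distributions (binomial or
bootstrap standard errors) rather than fitted to observed outcomes.

## 8. Limitations

- Protospacer alignment is exact-match; sequencing errors inside the guide
  make a read unmapped rather than rescued. This undercounts uniformly and
  does not bias gamma.
- The simulator models no PCR amplification bias, no sequencing errors in
  the guide reads, and i.i.d. genome packaging (no co-packaging bias).
- The discriminant-score null depends on olfactory receptor genes being
  phenotypically silent in the screened lines; in unusual cell types another
  null set may be needed.
- Per-element recombination rates are descriptive QC, not estimates of
  per-element switching probability — they confound switching with fitness,
  as discussed in section 4.
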