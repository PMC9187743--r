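---
title: "riboshift: methods and design notes"
author: "riboshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboshift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboshift)
```

# Scope and scientific background

`riboshift` implements the downstream computational analysis used to
characterise a length-dependent imbalance in neuronal translation. The
biological setting is cell-type-specific translatome profiling (TRAP-seq:
pulldown of tagged ribosome-bound mRNA from a defined neuron population,
followed by RNA-seq) together with a synapse-enriched proteome, in a mouse
model of Fragile X Syndrome and under pharmacological induction of
mGluR-dependent long-term depression (LTD). The analyses the package covers
are those that act *downstream* of read alignment and per-gene model
fitting: the inputs are differential-expression tables (gene id, moderated
log2 fold change, test statistic, nominal and adjusted p), gene-model
annotation, transcript abundances, gene-set collections, and strand-specific
CAGE 5'-end pileups. Alignment, counting, DESeq2/limma fitting and
proteomics preprocessing are deliberately out of scope; their outputs are
ingested as tables.

Four statistical ideas are central:

1. **Gene-set shift statistics.** Whether a named set of genes (for
   example, the 80 ribosomal proteins of the eukaryotic ribosome) moves
   together in a ranked differential-expression list. Implemented as an
   unweighted running-sum enrichment score (ES) with a permutation null,
   and as a mean-rank statistic (GSA) with a random-same-size-set null,
   plus large-sample two-sample z tests of a set's fold changes against the
   whole detected population or against size-matched random sets.
2. **CDS-length translation bias.** Whether fold change depends on coding
   sequence length: length bins (<1 kb, 1–2 kb, 2–4 kb, >4 kb) compared by
   two-sample Kolmogorov–Smirnov tests; the top-N most up- and
   downregulated genes compared on log2 CDS length with z tests; a
   gene-set analysis ranked by CDS length itself; and a 2×2 classification
   against fixed CDS-length (2^11 nt) and gene-length (2^16 nt) thresholds.
3. **Term-level sign imbalance.** For a functional term with `n_total`
   detected genes of which `n_up` go up and `n_down` go down,
   `z = (n_up - n_down) / sqrt(n_total)`; term families (e.g. the
   LTD-downregulated terms) are compared against the distribution of z over
   all detected terms with a two-sample z test. Term similarity networks
   weight edges by shared-gene counts, prune terms sharing ≥90% of their
   genes, and cluster by Girvan–Newman edge betweenness.
4. **CAGE-based TSS calling.** Each protein-coding gene is scanned from
   1000 bases upstream of its earliest annotated transcript start; the
   position with the greatest 5'-end read pile-up is the TSS. The 5'UTR is
   assigned to the transcript whose coding start is the smallest strictly
   positive distance downstream; genes with a 5'UTR over 500 nt, or a TSS
   at or downstream of any coding start, are excluded.

# The model behind the synthetic data

Because the original sequencing depositions cannot be re-processed at desk
scale, the package ships a first-class generator whose defaults define the
study-like conditions every test runs under:

* 12000 detected genes; CDS lengths lognormal with `meanlog 7.2`,
  `sdlog 0.6` (median ≈ 1.3 kb, right-skewed as in mammalian annotation);
  5'UTRs lognormal (`4.7`, `0.6`, capped at 500 nt except where a long UTR
  is planted), 3'UTRs lognormal (`6.5`, `0.8`).
* An 80-gene RP-like set drawn from the shortest CDS tercile, mirroring
  the real ribosomal-protein set's short lengths.
* True log2 fold change `beta_len * centred log2(CDS) + gamma_rp * I(RP)`
  with defaults `beta_len = -0.05` and `gamma_rp = +0.3` — a mild negative
  length trend plus an RP-specific upregulation.
* Observed tables: each gene draws a standard error from a scaled
  inverse-chi distribution with `n_replicates = 4` degrees of freedom at
  scale `sigma_noise = 0.15`, then an observed fold change
  `true + Normal(0, se)`; the Wald statistic `obs/se` is exactly standard
  normal under the null given `se`, so null p-values are uniform by
  construction — this is what makes the calibration checks meaningful.
* Paired TRAP/total counts: negative binomial (dispersion 0.05) around a
  lognormal baseline, TRAP mean multiplied by `2^true_log2fc`.
* CAGE pileups: Poisson(50) signal at the true TSS, Poisson(0.05)/base
  background over the scan window; ~10% of genes carry a decoy pileup
  downstream of a coding start (two-transcript genes) and ~5% a true 5'UTR
  longer than 500 nt, so both exclusion rules are exercised with known
  ground truth.

What the generator does *not* emulate: read-level errors, mappability and
3'-bias artefacts, correlated gene-gene expression, isoform switching, and
the empirical-Bayes shrinkage structure of real moderated fold changes.
Passing tests therefore demonstrate the statistics and algorithms are
implemented correctly and calibrated under their assumptions — not that any
particular biological dataset will meet those assumptions.

# Worked example

```{r example, eval = FALSE}
library(riboshift)

cfg <- simulationConfig(n_genes = 4000, seed = 1)
uni <- generateUniverse(cfg)
de  <- generateDeTable(uni)

# is the RP-like set shifted up?
metric <- setNames(de$log2fc, de$gene_id)
gsaMeanRank(metric, uni$sets$rp_like, nPerm = 1000, seed = 2)

# is fold change length-dependent?
topNLengthComparison(de, uni$annotation, n = 500)
lengthBinReport(de, uni$annotation)

# call TSS from the CAGE pileup
cage <- generateCage(uni)
tss <- callAllTss(cage$models, cage$track)
tss$summary
```

Or run everything from one config:

```{r pipeline, eval = FALSE}
runPipeline(list(seed = 1, output_dir = "out", n_perm = 1000,
    simulate = list(n_genes = 4000)))
```

# Numerical and design choices

These points were genuinely open in the methods as described and were fixed
once, as package policy:

* **ES step weights.** The running sum uses the classic unweighted
  Kolmogorov–Smirnov-style increments `+sqrt((N-G)/G)` per hit and
  `-sqrt(G/(N-G))` per miss. No fold-change weighting is applied; a
  weighted mode could be added without changing the interface.
* **ES sign on an exact excursion tie.** If the extreme positive and
  negative excursions of the running sum tie exactly in magnitude, the ES
  is reported as 0. This is the only convention (for a score determined by
  the two extrema) under which reversing the ranked list always negates
  the score; ties of this kind are measure-zero for continuous metrics but
  occur structurally for the rational step ratios of the unweighted walk.
  A 1e-9 relative slack absorbs accumulation-order floating-point
  differences.
* **Permutation p-values** use the add-one estimator
  `(1 + #{|null| >= |obs|}) / (nPerm + 1)`, which cannot return 0 and is
  exactly uniform on its grid under exchangeability. The mean-rank test
  centres two-sided deviations on the exact exchangeable expectation
  `(N+1)/2` rather than the sampled null mean, which keeps the test
  deterministic given the null draws and exactly calibrated; the sampled
  null mean and sd are still reported for interpretation.
* **Rank ties.** Midranks for the mean-rank statistic (standard
  nonparametric practice); ordering-based statistics break metric ties by
  gene id, so every ranking is deterministic.
* **Principal transcript ties** (equal TPM, including all-zero genes)
  resolve to the lexicographically smallest transcript id; all-zero genes
  are kept, since the expression filter is a separate explicit step.
* **Significance thresholds are strict** (`padj < 0.1`, `p < 0.05`),
  matching the conventions of the upstream differential-expression tools,
  and the expression filter is a strict `> 2 FPKM`.
* **TSS scan window.** The scan starts 1000 nt upstream of the earliest
  transcript start (in transcription order) and ends just before the
  gene's most downstream coding start. Ending at the most upstream coding
  start instead would make the downstream-TSS exclusion rule unreachable —
  every scanned position would already be upstream of all coding starts —
  so the wider window is used and the exclusion rule performs the pruning
  it is stated to perform; for single-transcript genes the two choices
  coincide. Pileup ties resolve to the position closest to the coding
  start (the shortest-5'UTR, most conservative call), and a TSS exactly at
  a coding start (0-nt 5'UTR) is treated as excluded, reading "upstream"
  strictly.
* **Pileups are single-base 5'-end anchors**; no smoothing window is
  applied, since none is described.
* **Term pruning** reads "share 90% of genes" against the smaller set
  (`|A∩B| / min(|A|,|B|) >= 0.9`), scans offending pairs by descending
  overlap fraction (ties by term id), and greedily removes the smaller
  (tie: lexicographically later) term. The result is deterministic and
  idempotent.
* **Eq-style term classification.** Whether the up/down counts of the
  sign-imbalance z include all detected term genes (by fold-change sign;
  zero-change genes count in neither) or only significantly regulated ones
  is not derivable from the description; the sign mode is the default and
  a significance-gated mode (`padj < alpha`) is provided.
* **Edge-betweenness clustering** cuts the Girvan–Newman hierarchy at
  maximal modularity; isolated terms form singletons.
* **Top-N "all" reference** includes the selected tails (reference = whole
  detected universe), and lengths are compared on the log2 scale, which is
  how length distributions are usually displayed; a raw-scale option
  exists. `pvalue_signed` ranking takes the `n` smallest nominal p-values
  separately within each fold-change sign.
* **Length bins are half-open** `[lo, hi)`, so a 1000-nt CDS falls in the
  1–2 kb bin; the threshold cells of the CDS/gene-length 2×2 table use
  `>=` on the high side.
* **Seeding.** Every stochastic entry point takes a seed; collection-level
  drivers derive an independent child seed per set from one master seed,
  so any single result can be regenerated without re-running the rest.
  When measuring calibration across many replicate sets, the replicate
  sets are drawn up front from their own stream so they stay independent
  of the per-test permutation streams.

# Problem sizes used by the checks

The package's own verification runs at sizes chosen to make the statistical
properties sharp: calibration uses one 12000-gene null universe, 2000
replicate 80-gene sets and 499 permutations per set (the add-one estimator
then rejects at exactly 24/500 = 0.048 under exchangeability); effect
recovery uses 100 independent 12000-gene universes at the default effect
sizes; oracle-equivalence checks use 100 random small instances per
statistic; the TSS checks use a 600-gene noiseless universe plus noisy
variants. The full-scale defaults (n_perm = 1000, as in the methods the
package follows) remain the package defaults.

# Known limitations

* The GSEA mode reports the raw ES and its permutation p; no normalized
  enrichment score across set sizes is computed.
* The hypergeometric enrichment helper replaces web-service GO enrichment;
  it conditions on the detected-gene universe, which is the defensible
  choice here but differs from tools that use a whole-genome background.
* `trapOverTotal` produces descriptive per-pair ratios; it does not refit
  a differential model on the ratios.
* The TSS caller takes single-base maxima; CAGE data with broad promoters
  would favour a windowed pile-up, which is not implemented because the
  procedure being reproduced does not describe one.
* Network edge weights (shared-gene counts) are passed to igraph's
  edge-betweenness routine as-is, matching how the original tooling was
  driven; igraph treats weights as distances in betweenness computation,
  so heavily overlapping terms are, if anything, separated earlier rather
  than later.
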