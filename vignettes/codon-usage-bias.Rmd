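---
title: "Codon usage bias analysis with cubtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubtools)
```

## The analysis

Synonymous codons are not used at random. In bacterial genomes two forces
dominate the departures: mutational pressure (a genome- or gene-wide bias in
the G+C content of point mutations, felt most clearly at silent third codon
positions) and natural selection (typically translational selection for a
set of "optimal" codons in highly expressed genes). `cubtools` implements
the standard comparative toolkit for quantifying codon usage bias (CUB) in
coding sequences and for attributing it to those forces:

1. **Ingest and QC** — CDS FASTA files are read, normalised and filtered by
   an explicit, toggleable rule set (frame, start codon, terminal stop, no
   internal stop, no ambiguous bases, minimum length).
2. **Indices** — per gene and per genome: GC1/GC2/GC3 (G+C by codon
   position), GC12, GC3s (silent-site G+C over the 59 codons of synonymous
   families), RSCU, CAI, CBI, FOP, ENC, GRAVY and aromaticity.
3. **Force diagnostics** — the neutrality regression of GC12 on GC3,
   Wright's expected ENC curve and the ENC ratio, the PR2-bias plot, and
   the full index correlation matrix.
4. **Correspondence analysis** of per-gene RSCU profiles in 59-codon space.
5. **Optimal codons** — CAI-defined expression extremes, delta-RSCU, and
   the classification rule (delta-RSCU > 0.08 and RSCU > 1).
6. **Codon context** — 64 x 64 adjacent-pair counts, contingency-table
   adjusted residuals, start/stop context reports, and context clustering.
7. **Genome clustering** on genome-level RSCU vectors.

All stages run against a built-in synthetic genome generator with recorded
truth, so every inference the package makes can be checked against known
generating parameters.

## Models and definitions

### RSCU

For codon $j$ of an amino acid with $n_i$ synonymous codons,
$\mathrm{RSCU}_j = x_j / (\frac{1}{n_i}\sum_{k} x_k)$. Uniform usage gives
RSCU 1 for every family member, and RSCU values sum to the family size.
Met and Trp have single codons and are excluded throughout, leaving 59
informative codons.

### CAI

CAI is the geometric mean of relative-adaptiveness weights
$w_j = \mathrm{RSCU}_j / \max_{\text{family}} \mathrm{RSCU}$ computed from a
reference set of highly expressed genes. Because curated reference sets are
often unavailable, three selectors are provided: a header-annotation regex
(default: ribosomal proteins), an explicit id list, and a two-pass
iterative bootstrap (provisional weights from genome-wide usage, then
weights from the provisional top 5 % of genes by CAI). Codons unused in the
reference receive a pseudo-weight of 0.01 (configurable), the convention
that keeps CAI finite.

### ENC

Wright's estimator: per family with $n \ge 2$ observations, homozygosity
$F = (n\sum p_k^2 - 1)/(n-1)$; class means $\bar F_k$ over 2-, 3-, 4- and
6-fold families; $\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 +
3/\bar F_6$. Numerical choices: if the single 3-fold family (Ile) is
uninformative, $\bar F_3$ is imputed as $(\bar F_2 + \bar F_4)/2$; any
other uninformative class is dropped and the remaining terms rescaled by
the ratio of total to represented family counts; the result is clamped to
$[20, 61]$. The clamp also delivers the theoretical value 61 exactly under
finite uniform usage, where the unbiased estimator slightly exceeds 61.

### Force diagnostics

The neutrality plot regresses GC12 on GC3 across genes: slope near 1 with a
significant correlation indicates mutational pressure acting on all codon
positions; slope near 0 indicates position-3-specific forces, i.e.
selection. The expected ENC curve
$\mathrm{ENC}_{exp} = 2 + s + 29/(s^2 + (1-s)^2)$ (with $s =$ GC3s) gives
the ENC of a gene shaped by mutational bias alone; the ENC ratio
$(\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs})/\mathrm{ENC}_{exp}$ summarises
the deviation. The PR2 plot places each gene at
$(G_3/(G_3+C_3),\ A_3/(A_3+T_3))$; both ratios are 0.5 under
strand-symmetric, selection-free evolution. Third-position base counts are
taken over all sense codons by default (a fourfold-family-only variant is a
documented alternative, since PR2 is classically defined there).

### Correspondence analysis

Classical CA of the genes x 59 RSCU matrix: proportions $P$, masses $r, c$,
standardised residuals $D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, SVD, principal
coordinates. Axis $k$ contributes $\sigma_k^2/\sum\sigma^2 \times 100$ % of
inertia. CA is run on RSCU rather than raw counts so that amino-acid
composition differences do not dominate the leading axes; a raw-count
matrix can be supplied to the same function. Because CA axes are defined
only up to sign, axis signs are oriented so that their correlation with
GC3s is non-negative, which makes outputs reproducible across SVD
implementations.

### Optimal codons

Genes are ranked by CAI; the top and bottom 5 % (configurable) form the
high- and low-expression sets, with ties broken deterministically by gene
id. Set-level RSCU is computed from aggregated codon counts — the
dataset-level reading of "mean RSCU" — with a per-gene-averaged variant
available; the aggregated convention is invariant under duplicating genes
within a set. A codon is *high-frequency* if its genome-wide RSCU exceeds
1, and *optimal* if delta-RSCU (high minus low) exceeds 0.08 **and** RSCU
exceeds 1, both strict. The RSCU > 1 clause of the optimal rule is
evaluated on the high-expression set by default (the rule's natural
reading, since optimality is a property of highly expressed genes); a
genome-wide switch is provided. The two flags are deliberately independent:
a codon can be optimal without being high-frequency. When the rule flags
more than one codon of a family, CBI and FOP — which require at most one
optimal codon per family — use the family member with the largest
delta-RSCU.

### Codon context

Adjacent codon pairs (terminal stop included, self-pairs counted) form a
64 x 64 contingency table. Adjusted residuals
$(o_{ij}-e_{ij})/\sqrt{e_{ij}(1-r_i/N)(1-c_j/N)}$ are approximately
standard normal under independence; the default call threshold of 3
corresponds to a two-sided tail probability of about 0.0027. Start/stop
context reports use counts for "most used" and the most negative residual
for "most avoided". For cross-genome clustering, residual matrices are
flattened to 4096-vectors with undefined cells as 0 (so genomes lacking a
stop codon remain comparable), distances are 1 minus Pearson correlation,
and linkage is average.

### Genome clustering on RSCU

Genome-level RSCU vectors are clustered with squared Euclidean distance
and between-groups average linkage — the conventional default pairing of
the statistical packages historically used for this analysis — with
complete and Ward linkage as options.

## The synthetic genome generator

`synthetic_spec()` / `generate_genome()` define the package's study
conditions. Each gene receives a mutational GC bias $\theta_g$ (Beta
distributed, or fixed) and an expression level $e_g$ (exponential). Codons
are sampled by mode:

* **mutation** — codon probability proportional to the product of its
  three base weights (G, C each $\theta_g/2$; A, T each $(1-\theta_g)/2$),
  restricted to sense codons. Amino-acid usage co-varies with $\theta_g$,
  so GC rises at all three positions — the generative picture behind a
  neutrality slope near 1.
* **selection** — amino acids from a fixed empirical background; within a
  family the codon probability is proportional to
  $\exp(s\, e_g\, \mathbb{1}[\text{codon} \in O])$ times the third-base
  mutational weight at a genome-constant $\theta$. Only third positions
  respond, giving a neutrality slope near 0 and a CAI gradient across
  genes.
* **mixed** — selection-mode sampling with per-gene $\theta_g$.

$O$ is a planted optimal set, one codon per synonymous family (default:
the C-ending, else G-ending, member). An optional first-order context term
multiplies the next codon's probability by $e^\gamma$ when the (previous,
next) pair belongs to a planted pair set, which creates genomes with
distinguishable codon-context regimes while leaving marginal codon usage
essentially unchanged.

Default sizes are 500 genes with lognormal lengths centred near 300
codons: large enough that sampling noise stays well below the effect sizes
being tested (for example genome GC3s tracks $\theta$ to within 0.02),
small enough that the full pipeline runs in seconds. The presets in
`preset_suite()` fix the four study conditions used by the package's tests:
`null-uniform` ($\theta = 0.5$, $s = 0$), `mutation-dominated`
($\theta_g \sim \mathrm{Beta}(2,2)$, $s = 0$), `selection-dominated`
($\theta = 0.55$, $s = 1.5$) and `mixed`.

What the generator does *not* emulate: operon structure and strand
asymmetry, length- or function-dependent amino-acid composition,
context-dependent mutational dynamics, horizontal transfer, and real
annotation headers (so the reference-set selector exercised on synthetic
data is the iterative one, not the ribosomal-protein regex). Passing tests
on synthetic data therefore demonstrate correctness of the estimators and
of the recovery logic under the stated model, not robustness to every
property of real genomes.

## A worked run

```{r pipeline, eval = FALSE}
specs <- preset_suite(seed = 1, n_genes = 300)
genomes <- lapply(specs[c("mutation-dominated", "selection-dominated",
                          "mixed")],
                  function(sp) generate_genome(sp)$cds)
names(genomes) <- c("mut", "sel", "mix")
res <- run_pipeline(list(genomes = genomes), out_dir = "cub_results",
                    seed = 1)
res$genomes$mut$neutrality     # slope near 1: mutational pressure
res$genomes$sel$neutrality     # slope near 0: selection
res$codon_sets$shared          # codons optimal in all three genomes
```

`run_pipeline()` writes, per genome, the gene index table, QC report,
delta-RSCU table, neutrality fit, ENC-GC3s and PR2 points, CA coordinates
and inertia contributions, pair-count and residual matrices (RNA codon
labels), and the context report; across genomes it writes the index-mean
summary, the optimal-codon membership matrix, the RSCU and context trees
as Newick, and a JSON manifest of parameters and failures. Internally all
fractions are kept in $[0,1]$; summary outputs scale GC quantities by 100
where the field's tables conventionally print percentages.

## Numerical and degenerate-input choices

* QC failures are reported, never raised; the report accounts for every
  input gene. Genes shorter than 100 sense codons are flagged rather than
  removed, because ENC is unstable on short genes.
* Ambiguous bases discard the gene by default; a drop-codon mode removes
  only the offending codons and preserves the frame.
* RSCU of an unused family is 0 for all members and the family is flagged
  absent; ENC returns `NA` when no family has two or more observations;
  CBI is `NA` when observed and random expectation coincide
  ($N_{tot} = N_{ran}$).
* PR2 genes with a zero denominator are flagged and excluded from quadrant
  summaries; quadrant boundaries at 0.5 are assigned to the lower side.
* CA removes zero-sum rows and columns (reported), returns a degenerate
  "no variation" result when total inertia vanishes, and errors on rank
  < 2 input.
* Expression-extreme ties are broken by gene id and recorded; identical
  CAI everywhere still yields deterministic (warned) sets.
* GRAVY uses the standard Kyte-Doolittle scale, whose range is
  $[-4.5, 4.5]$; some of the literature describes GRAVY as ranging from
  -2 to 2, which reflects typical proteome values rather than the scale's
  bounds.

## Known limitations

* CAI depends on the reference set; the iterative selector assumes the
  genome actually contains an expression-linked usage gradient and can
  lock onto compositional extremes when it does not. The provenance of the
  reference is recorded with the weights.
* The force diagnostics assume strand-symmetric composition; genomes with
  strong replication-strand asymmetry will show PR2 deviations that are
  mutational, not selective, in origin.
* ENC's missing-class rescaling is a pragmatic convention; genes missing
  whole degeneracy classes (very short or compositionally extreme genes)
  carry more estimator variance, which is why short genes are flagged.
* The RSCU and context clusterings are descriptive; no uncertainty is
  attached to the dendrograms.
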