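---
title: "Methods: pan-genome partitioning and base-composition inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome partitioning and base-composition inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pancomp` asks whether the core and accessory compartments of bacterial
genomes differ in base composition, and answers it with a fixed chain of
stages: protein clustering into gene families, core/accessory
partitioning, three per-region composition statistics, and a hierarchy of
statistical models. This vignette explains each stage's model and
assumptions, the tunable parameters, the synthetic data the package tests
itself on, and the numerical choices made where several were defensible.

## Gene families from reciprocal alignment scores

Two coding genes A and B, compared as proteins, get the dissimilarity

$$d(A,B) = 1 - \tfrac12\left(\frac{b(A;B)}{b(A;A)} +
\frac{b(B;A)}{b(B;B)}\right),$$

where $b(A;B)$ is the local-alignment score with A as query and $b(A;A)$
the self-alignment, i.e. the maximum attainable score for A. The ratio
normalizes away protein length; reciprocal averaging symmetrizes it. A
pair with no reported alignment is scored 0, hence $d = 1$: this matters
because score lists (BLAST output in particular) omit non-significant
pairs, and the formula needs a value for every pair. The result is clamped
into $[0,1]$ against floating-point drift.

Scores come from one of two sources, never mixed within an analysis:

- **imported** 12-column BLAST tabular files (bitscore in field 12;
  duplicate HSPs per ordered pair resolved by maximum bitscore, since the
  distance needs exactly one score per ordered pair);
- **internal**: Smith–Waterman local alignment via `Biostrings`, BLOSUM62,
  gap open 11 / extend 1 (the standard protein-search penalties), raw
  scores. Raw SW scores are symmetric, and the implementation asserts the
  scorer contract $b(A;A) \ge b(A;B)$ at run time.

Because the distance is a ratio, bitscores and raw scores both satisfy the
contract; they just may not be mixed.

Families are **complete-linkage** clusters: the merge height of two
clusters is the *maximum* pairwise member distance, and the dendrogram is
cut strictly below the threshold (default **0.75**). Complete linkage is
the conservative choice here — it refuses chained merges, so every member
of a family is within the threshold of every other member. Clustering is
run per pan-genome group (per species by default; `level = "genus"`
collapses congeneric species into one pan-genome, appropriate for genera
whose species boundaries are genomically thin). Gene ids are
lexicographically sorted before clustering so the output is deterministic
regardless of input order; the cut uses `threshold - 1e-10`, so a merge at
exactly the threshold is refused, consistent with "strictly below".

## Core, accessory, whole

Within one pan-genome of $n$ strains, a family present in exactly one
strain is a **singleton**; present in at least a fraction `core_frac`
(default **0.95**, compared as an exact ratio with no rounding — presence
19 of 20 is core) is **core**; otherwise **accessory** (at least two
strains, fewer than the core fraction). Singletons are excluded from the
core/accessory comparison as probable annotation artifacts, but the
**whole** region keeps them: "whole genome" means all coding genes of the
strain (`whole_includes_singletons = FALSE` switches to the clustered-only
interpretation, since published analyses are not always explicit about
this). Per strain, the core and accessory gene sets are disjoint and both
are subsets of whole — an invariant the tests enforce.

## Composition statistics

All three statistics pool a strain's genes within a region but never let a
window or k-mer span the junction between two genes — junctions are
artifacts of concatenation order, not biology.

- **GC content**: unambiguous G+C over unambiguous A+C+G+T. IUPAC
  ambiguity codes are excluded from numerator and denominator.
- **Relative entropy** (trinucleotide Kullback–Leibler divergence):
  overlapping (step 1) trinucleotide frequencies $f_{XYZ}$ against the
  product $f_X f_Y f_Z$ of pooled mononucleotide frequencies,
  $\sum f_{XYZ}\log(f_{XYZ}/f_Xf_Yf_Z)$. Zero-count trinucleotides
  contribute 0; windows containing ambiguity codes are skipped. The value
  is non-negative (Gibbs' inequality) and tends to 0 with length for an
  i.i.d. sequence; high values indicate biased oligonucleotide (codon)
  usage.
- **GCVAR**: $\log\!\big(\tfrac1N\sum_i |GC_i - GC|\big)$, where $GC_i$
  runs over sliding windows (default width **100 bp**, step **1**) within
  each gene and $GC$ is the region's pooled value. Genes shorter than the
  window contribute no windows but still count toward the pooled GC. If
  every window equals the pooled GC exactly the mean deviation is 0; the
  function returns $-\infty$ with a `zero_deviation` flag rather than
  raising, and the model layer drops such rows listwise with a count.

Logarithms are natural (nats) by default for both entropy and GCVAR,
configurable to base 2; window step is configurable and recorded with the
output, since GCVAR values are step-dependent. Statistics are computed on
the coding strand as deposited, with no reverse-complement
symmetrization. Whether the mononucleotide expectation should be pooled
per region or computed per gene is genuinely open; pooled is used, matching
the pooling of the trinucleotide counts themselves.

## The model layer

The observation unit is one row per strain × region, so each strain
contributes up to three rows. The mixed model

$$y = \beta_0 + \beta_1 x + Zu + \varepsilon$$

takes $y$ = GC, GCVAR or relative entropy, $x$ = region (factor with
reference level *accessory*, so coefficients read as accessory→whole and
accessory→core shifts) or GC content, and uncorrelated random intercepts
for taxonomy — genus and species by default, phylum optionally. Fits use
REML; coefficient tests use Satterthwaite denominator degrees of freedom
(`lmerTest`). GC is modelled in percentage points (0–100) for readable
coefficients; the scale is recorded. Singular fits (a variance component
estimated at zero) are flagged, not hidden.

Model comparisons refit by maximum likelihood and use
$2\Delta\log L \sim \chi^2_{df}$ with $df$ = parameter-count difference.
One caveat is intrinsic: testing a variance component sits on the boundary
of its parameter space, where the LRT statistic is a
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture — the statistic is exactly 0
in about half of null replicates, and the plain $\chi^2_1$ p-value is
conservative. The acceptance suite therefore checks calibration
*conditionally on a positive statistic* (where the $\chi^2_1$ p-values are
uniform) rather than pretending the unconditional p-values are.

Tukey HSD contrasts among the three regions come from `multcomp::glht`
with single-step family-wise adjustment; adjusted p-values are never below
unadjusted ones, which the tests assert.

The phylogenetic stage fits species-level GC on phylum by generalized
least squares with the Brownian covariance of a supplied tree, off-diagonal
entries scaled by Pagel's $\lambda$. $\lambda$ is profiled by maximum
likelihood over $[0,1]$ (`optimize`, tolerance $10^{-4}$, with both
boundary values checked explicitly since the optimum often sits at 1);
$\lambda = 0$ reduces exactly to ordinary least squares, which the tests
require to $10^{-8}$. The phylum effect is tested with the ANOVA F-test of
the GLS fit (sequential sums of squares; identical to the marginal test
here because phylum is the only predictor). The tree is consumed, never
built: one leaf per species, branch lengths required.

Core-genome fractions (core nucleotides over whole-gene nucleotides, per
strain) are compared between strain groups with a two-sided Wilcoxon
rank-sum test, exact when sample sizes and ties allow.

## What the synthetic generator emulates — and what it does not

`simulate_pangenome()` mirrors the structure of a multi-species strain
panel: a balanced taxonomy (phyla ⊃ genera ⊃ species ⊃ strains), a random
ultrametric coalescent species tree, core families present in every strain
of their species, accessory families on random strain subsets of at least
two (per-strain presence probability `accessory_presence_prob`), and
per-strain singletons. Sequences are codon-structured (no in-frame stops,
so translation and protein clustering are always valid) and each family
derives from an ancestor by point mutations (`mutation_rate_within_family`,
default 0.01), keeping intra-family distances near 0 and inter-family
distances near 1 — which is what makes exact family recovery a meaningful
test. Compositional contrasts are planted per gene class: core genes GC
0.55 with preferred-codon bias, accessory and singleton genes GC 0.45 with
alternating-GC mosaic blocks, plus species- and genus-level normal GC
offsets (`gc_species_sd`, `gc_genus_sd`) that create exactly the
variance-component structure the mixed models estimate.

Two generator details deserve a note. First, conditioning codons on "not a
stop" removes AT-rich codons and would drag GC above target, so the
per-base GC parameter is solved numerically (uniroot on the
stop-conditioned expectation) to hit the target exactly; a faint
structural trinucleotide signature (about $2\times10^{-3}$ nats) remains
at bias 0 — the package's own floor for "unbiased" codon-structured
sequence, distinct from a truly i.i.d. sequence. Second, mosaic blocks
start in a random phase; a fixed phase would bias the expected GC of genes
whose length is not a whole number of blocks.

For calibration studies that need hundreds of model fits,
`simulate_composition()` skips sequences entirely and draws per-region GC
as binomial base counts at the planted probabilities — distributionally
identical to measuring GC on i.i.d. sequences of the same pooled length,
at a fraction of the cost.

What the generator does **not** emulate: realistic substitution-model
evolution along the tree (sequences are exchangeable within a family),
indels, recombination breakpoints, gene-length and GC correlations,
annotation errors, or paralog inflation. Passing tests therefore
demonstrate that the pipeline recovers structure *of the planted kind*;
they cannot certify behaviour on, say, heavily rearranged or
contaminated assemblies.

## Problem sizes and numerical choices

The test and acceptance suites run at deliberately small sizes chosen so
the statistical conclusions stay unambiguous: 500 random score tables of
up to 12 genes against a brute-force clustering oracle; pipeline runs of 4
species × 5 strains with ~540 genes; mixed-model studies at 20 species ×
10 strains with pooled region lengths of $10^5$ (recovery, type-I) or
$2\times10^4$ (LRT replicates) bases; 200 replicates for calibration
checks; a 36-species tree with 50 (tests) or 20 (acceptance script)
Brownian replicates for $\lambda$ recovery. Tie-breaking, cut strictness
and ordering conventions are fixed as described above so that identical
configurations and seeds give byte-identical artifacts, which the suite
verifies literally.

Known limitations: complete linkage is quadratic in genes per pan-genome
(distance matrices are dense); the internal scorer is slower than BLAST
and intended for moderate gene counts or testing; GCVAR's absolute value
depends on the window step, so only like-for-like comparisons are
meaningful; and the $\chi^2$ reference for variance-component LRTs is
conservative, as discussed.
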