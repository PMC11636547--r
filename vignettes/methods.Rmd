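---
title: "Methods: composition stratification of differential-expression gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition stratification of differential-expression gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Most internal mRNA methylation (m6A) in plants sits inside the degenerate
consensus motif RRACH (R = A/G, H = A/C/U), and the mark is predominantly
destabilizing. When an m6A eraser such as FTO is expressed transgenically, a
transcriptome-wide reduction of the mark should preferentially stabilize
transcripts that carry many methylatable sites. The testable downstream
signature is *compositional*: genes upregulated after the perturbation should
be adenosine-rich and dense in RRACH motifs relative to downregulated genes,
with a random gene set sitting in between as a reference stratum.

`rrachstrat` implements that whole downstream chain as a reusable, testable
pipeline: differential expression (DE) per transgenic line, multi-line shared
gene lists, enrichment screens, and gated nonparametric comparison of
sequence-composition metrics across up / random / down transcript sets — plus
a synthetic-data generator that plants known structure so every stage can be
validated by parameter recovery.

## Sequence-composition metrics

For each gene the 5'UTR, CDS and 3'UTR are extracted strand-aware from a
genome FASTA and GFF3 gene models, and three metrics are computed per region:

* **Adenosine frequency** — `count(A) / count(A,C,G,T)`. Ambiguous letters
  (e.g. N) are excluded from the denominator because the quantity is a
  composition estimate.
* **Length** — physical length in bases, ambiguous letters included. Both
  `length` and `length_acgt` are reported so per-kb densities can be
  renormalized either way.
* **RRACH motifs per kb** — `1000 * matches / length`. Matching slides a
  window and counts *every* position-wise match. Overlapping matches are all
  counted; RRACH cannot self-overlap at offsets 1–3 (the A and C positions
  clash with R/H constraints), so the choice only matters at offsets ≥ 4 and
  counting all windows is the standard scanning convention. Windows touching
  a non-ACGT letter never match, but those letters still count toward the
  per-kb denominator (density is per physical kb). RNA-style `U` is mapped
  to `T` on input; all sequences are handled DNA-sense.

Under an i.i.d. base model the expected density is
`1000 * Π_positions Σ_{b in allowed} P(b)`; with equal base frequencies this
gives `1000 × (1/2)(1/2)(1/4)(1/4)(3/4) = 11.71875` RRACH per kb, i.e. about
12 per kb, which the test suite verifies against Monte-Carlo scans of random
3-kb sequences.

## The DE stage

The DE stage is an openly simplified negative-binomial test, because the
package's scientific core lies downstream of DE:

1. **Normalization** — median-of-ratios size factors (the median over genes
   of each sample's count divided by the gene's geometric mean across
   samples).
2. **Effect size** — `log2fc = log2(m1 + 0.5) − log2(m0 + 0.5)` on normalized
   group means; the 0.5 pseudo-count keeps genes expressed in only one group
   finite. Computing the difference of logarithms (not the log of the ratio)
   makes contrast swapping negate the estimate exactly in floating point.
3. **Dispersion** — one common NB dispersion per contrast, the pooled
   within-group moment estimator `Σ(s² − ȳ) / Σ(ȳ²)` over genes whose pooled
   mean lies in the central 90%. The per-gene moment estimate
   `(s² − ȳ)/ȳ²` is available as an option, but with six replicates per group
   it is so noisy that the Wald test becomes anticonservative (about 7%
   rejections at nominal 5% in our null simulations); the trimmed
   ratio-of-sums estimator is nearly unbiased for a shared dispersion and
   restores calibration. This matches the generator's model, which draws all
   genes at one dispersion, and mirrors the common-dispersion option of
   standard count-model toolkits without importing their shrinkage machinery.
4. **Test** — Wald z on `log2fc` with a delta-method standard error from the
   NB variance `μ + αμ²` propagated through the size factors; two-sided
   normal p; Benjamini–Hochberg across all testable genes of one contrast;
   classification `up` / `down` at adjusted p < .01 (the threshold the
   analysis was designed around), `na` for all-zero genes.

There is no GLM fitting, no empirical-Bayes shrinkage, no independent
filtering and no outlier replacement; the stage is validated by simulation
(type-I calibration and sign/symmetry properties), not by gene-for-gene
agreement with any specific DE package.

## Gene lists and overlap

Per line, directional lists are built either from DE status or as the top
100 by fold change (ties broken by ascending adjusted p, then gene ID). The
multi-line sharing rule "in all lines, or in the two strongest lines" is the
union of the two intersections; when the named subset is contained in the
full collection this reduces to the plain intersection of the subset — the
implementation computes the rule literally and records the reduction in the
set's provenance. Overlap between two lists is tested against a
hypergeometric null (upper tail, computed by `phyper`); the universe defaults
to the genes with a defined DE status in both lines, since the most
defensible null draws both lists from the genes that could have appeared in
either.

When only an external DE table is available, the re-analysis policy builds
numerically balanced lists: the 1,000 most-upregulated, 1,000
most-downregulated, and 1,000 genes sampled uniformly at random.

## Enrichment screens

Category enrichment reports the fold ratio `(k/n)/(K/M)` with an exact
hypergeometric upper tail. Two-sample screens (keyword matches over GO term
names, tissue-of-maximal-expression classes) build a 2×2 table and use the
two-tailed Fisher exact test with the conventional conditional rule: sum the
probabilities of all tables with fixed margins whose point probability does
not exceed the observed one (relative tolerance 1e-7). Keyword matching is
case-insensitive substring matching on term *names*; genes without
annotation count as unmatched and are logged. Tissue assignment is the
per-gene argmax over atlas columns with lexicographic tie-breaking.
Degenerate 2×2 margins (a keyword matching nothing) return p = 1 with a
warning rather than an error.

## Group comparisons

Every phenotype or composition panel uses the same recipe: a Kruskal–Wallis
omnibus test first, and pairwise two-sided Wilcoxon rank-sum tests with BH
correction only when the omnibus p passes the gate (default .05; the gate is
configurable because the conditional wording of the procedure implies but
does not fix it). Exact rank-sum p-values are used for tie-free comparisons
with combined n ≤ 25; otherwise the normal approximation with continuity and
tie correction is used, and the switch is recorded per comparison so results
are reproducible across inputs. Fully tied comparisons return p = 1. The
phenotype hook additionally applies the bolting filter (floral stem mass
> 100 mg and at least one flower) when those columns are present, and
reports each line's percent change in mean against the reference group.

## What the generator emulates — and what it does not

`synthetic_spec()` defaults describe the assumed study design: one wild-type
control plus three transgenic lines, six biological replicates each, ~2,000
genes. Per gene the generator draws log-normal region lengths (medians
roughly 150 / 1,200 / 220 bases for 5'UTR / CDS / 3'UTR, Arabidopsis-like),
a Beta(28, 72) adenosine propensity (mean 0.28, spread a few percentage
points, typical of plant CDS), a compartment (94% nuclear, 3% mitochondrial,
3% plastid), and a category: 8% defense-like (planted log2FC −1), 8%
growth-like (+1), organellar (−1.5), rest neutral. The planted fold change
adds `beta_motif` (default 1) log2 units per standard deviation of realized
CDS RRACH density, so recovery tests have a known compositional signal; the
magnitude of this coupling is a free parameter of the generator, not an
estimate from any dataset. Counts are NB with a single shared dispersion
(default α = 0.05) and log-uniform library-size factors in [0.5, 2] so the
normalization stage has real work to do.

Design choices worth knowing:

* Planted motifs overwrite sampled bases at uniformly chosen non-overlapping
  CDS positions (an exact combinatorial construction, never touching the
  start or stop codon). This decouples RRACH density from adenosine
  propensity so the two metrics are separately testable. Overwriting
  displaces a small fraction of background matches, so the realized density
  gain sits slightly under the nominal boost; the truth table therefore
  records *realized* composition, measured on the final sequence, and the
  round-trip identity (truth table = composition module's measurement of the
  emitted FASTA/GFF3) is asserted in the tests.
* Genes are tiled on one chromosome with fixed 100-base spacers and a
  fair-coin strand, exercising strand-aware extraction.
* Boosts above 200/kb are rejected: non-overlapping 5-mers cannot pack
  denser than that.

The generator does **not** emulate splicing or isoforms, intron structure,
sequencing-read noise, polyA-selection bias, codon usage, or correlated
gene-gene expression. Passing recovery tests therefore demonstrate that the
pipeline detects compositional structure *of the planted kind* at realistic
effect sizes and depths — they do not certify behavior on real libraries
with isoform mixtures or alignment artifacts.

## Numerical and policy choices

* **Coordinates** are 1-based inclusive everywhere internally, matching the
  GFF3 and GRanges conventions native to R; the reader converts nothing and
  the writer emits the same convention, avoiding off-by-one drift.
* **Isoform policy**: the first-listed mRNA per gene, logged and overridable
  to "longest CDS" — annotation sources differ in which isoform they list
  first, and the configuration records the choice used.
* **Exact vs brute force**: hypergeometric tails and Fisher two-tailed
  p-values are checked against exhaustive enumeration (all 2×2 tables with
  margins ≤ 12; all overlap configurations with universe ≤ 20) at 1e-10.
* **Randomness** flows from one integer seed; each stage derives a named
  substream by fixed offsets, and the RNG state of the calling session is
  saved and restored around every draw, so identical configurations
  reproduce byte-identical outputs.
* **Degenerate inputs**: empty sequences give missing metrics rather than
  zeros; all-zero genes get DE status `na`; all-tied group comparisons give
  p = 1 with a warning; a "down" list requested from an all-positive table
  returns the least-opposed genes with a note.

## Problem sizes used in validation

The recovery study runs 50 replicates with a planted motif effect
(`beta_motif = 1`) and 50 with no planted structure, each at 2,000 genes and
6 vs 6 samples, asking whether the pipeline's upregulated set shows higher
median CDS adenosine frequency and RRACH density than the downregulated set
at BH-adjusted Wilcoxon p < .05. In null replicates the BH-classified sets
are empty by design (the FDR threshold is doing its job), so the pipeline's
top-100 fold-change lists stand in as the directional sets — under the null
those are random with respect to composition, which is exactly what the
rejection-rate check needs. DE calibration uses a single planted-null run at
2,000 genes. These sizes keep the whole validation suite to a few minutes
while leaving Monte-Carlo error well inside the asserted bands.

## Known limitations

* The DE stage assumes a dispersion shared across genes (matching its
  simulation model); strongly gene-specific overdispersion in real data
  calls for a dedicated DE package upstream, with the results fed in as an
  external DE table.
* Fold-enrichment results depend on user-supplied annotation tables; the
  package ships no category sizes or universes of its own.
* The composition analysis treats each gene as one transcript; isoform
  choice is a recorded policy, not a modeled quantity.
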