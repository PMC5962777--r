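---
title: "Clade-specific variant discrimination for flor yeast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-specific variant discrimination for flor yeast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florvar)
```

## The scientific problem

Flor yeasts are *Saccharomyces cerevisiae* strains that form a surface
biofilm (velum) on fortified wine during biological aging. They form a tight
phylogenetic cluster adjacent to the main wine clade, and the genetic changes
that distinguish them — clade-fixed SNVs and indels, promoter mutations, gene
losses and non-reference gene content — are candidate signatures of
domestication under sherry-making conditions.

`florvar` implements the comparative stage of that analysis as a reusable,
fully tested pipeline: given multi-sample variant calls against a reference
genome, a two-clade sample grouping (in-clade "flor" vs out-clade "wine"),
gene models, per-gene coverage breadth and alignment hit tables, it discovers
clade-fixed variants, classifies their effects, stratifies genes by
polymorphism load, calls gene presence/absence and novelty, and builds a
SNP-matrix phylogeny. Because the original sequencing data live in external
archives, the package also ships a synthetic data generator that reproduces
the *statistical structure* of the problem with machine-readable truth, so
every stage is testable offline.

## The discrimination filter

The core computation is a per-site predicate over per-sample read
observations. For sample $s$ at a site, let $d_s$ be the read depth and
$f_s(a)$ the read frequency of allele $a$ (reads supporting $a$ divided by
$d_s$). A site is reported as clade-specific iff:

1. every sample in both clades has data and $d_s \ge 20$;
2. there exists one allele $a$ with $f_s(a) \ge 0.9$ in **every** in-clade
   sample;
3. every out-clade sample has **some** allele $b \ne a$ with $f_s(b) \ge
   0.9$ — out-clade samples need not agree with each other;
4. (biallelic restriction, on by default) exactly two distinct alleles reach
   the 0.9 bound across all samples.

Numerical conventions worth stating explicitly:

* both bounds are inclusive (`>=`), reading "minimum 20x" and "90% support"
  as inclusive minima;
* because the frequency bound exceeds 0.5, at most one allele can satisfy
  clause 2, so the clade allele is unique and no tie-break is needed;
* a sample with no usable genotype data at a site is treated as *no-data*
  and fails clause 1 — deliberately distinct from depth 0, so "insufficient
  evidence" can never produce a call;
* read counts come from the freebayes `RO`/`AO` FORMAT fields, with GATK-style
  `AD` as a fallback when they are absent.

The filter is monotone: raising the depth or frequency bound can only shrink
the call set (tested), and swapping the clade labels returns the same sites
with the allele roles exchanged (tested).

Calls are mapped to *loci* for the headline locus count: a call's locus is
the gene owning its primary effect, or, for intergenic calls, an identifier
of the interval between the two flanking gene starts. This definition is a
documented package choice; other partitions of intergenic space are
defensible.

## Effect classification and dN/dS

Each call is classified against gene models into exactly one of eight
categories: `frameshift`, `stop_splice` (stop gained, stop lost, or splice
region), `missense`, `synonymous`, `intron`, `upstream`, `downstream`,
`intergenic` — listed here in the severity order used to reduce multiple
overlapping records to one primary record (ties at equal severity go to the
lexicographically smallest gene id, a deterministic and documented rule).

* Coding SNVs and equal-length multi-nucleotide substitutions are translated
  codon-wise under the standard nuclear genetic code, strand-aware. The
  translation is literal: no initiator-codon special-casing, because gene
  models carry no start-codon semantics.
* CDS indels whose length change is not a multiple of 3 are `frameshift`;
  in-frame indels are reported under `missense` with detail
  `inframe_indel`, keeping the eight-way partition stable (there is no
  separate in-frame category in the reported tables).
* The first and last 2 nt of an intron are splice regions (`stop_splice`);
  interior intron positions are `intron`.
* Promoter (`upstream`) and terminator (`downstream`) windows default to
  1000 bp on the appropriate strand side. The window sizes used by the
  original annotation tooling are not recoverable, so they are explicit,
  configurable parameters here; category counts depend on them and any
  comparison should state them.
* The classified allele at a biallelic clade site is its non-reference
  allele: the clade-fixed allele when it differs from the reference,
  otherwise the out-clade alternate — either way, the site's variation
  relative to the reference genome.

The dN/dS statistic is deliberately the **raw count ratio**
missense/synonymous, not a site-normalised (Nei–Gojobori-type) estimator:
that is the quantity the workflow reports, with `Inf` flagging
missense-with-zero-synonymous and `NaN` flagging an undefined ratio. It
should be read as a coarse excess-of-nonsynonymous signal, not a formal
selection test.

## Gene stratification and enrichment

Per-gene summaries count missense, synonymous, upstream and downstream
records; the ranking total is exactly that four-term sum (deleterious and
intron records are tracked separately and do not enter the total — the tier
definition is quoted verbatim from the workflow being reproduced). Tiers:

* *highly polymorphic*: >= 2 missense variants;
* *promoter-mutated*: >= 2 (and a stricter >= 3) upstream variants;
* *extremely polymorphic*: >= 5 total sites **and** per-gene dN/dS > 1,
  where `Inf` (missense without synonymous) counts as passing — consistent
  with the count-ratio definition — and `NaN` (no coding variants) does not;
* *deleterious*: any frameshift or stop/splice record.

All selectors are monotone in their thresholds (tested as superset
relations).

Enrichment is a generic hypergeometric upper-tail test per term over a
user-supplied flat gene-to-term map, Holm–Bonferroni adjusted across terms,
with the background defaulting to all annotated genes. Hypergeometric
p-values are discrete, so their null rejection rate at 0.05 approaches 0.05
only when the overlap counts have dense support; the calibration experiment
in the test suite therefore uses 2,000 background genes, 25 terms of 300–700
genes and selections of 200 — sizes chosen so the attained significance
levels are fine-grained — and observes a rejection rate slightly *below*
0.05, as expected for a discrete, exact test.

## Gene presence/absence and novelty

"Coverage" means breadth: the fraction of a gene's bases covered by at least
one read. A gene is missing when breadth is strictly below 50% ("less
than"), novel when no alignment achieves strictly more than 70% identity
over strictly more than 80% of the gene length ("more than", both clauses).
The boundary cases 69%/95%, 95%/79% and 71%/81% pin these inequalities down
in the tests. An optional second coverage track (breadth by de novo assembly
contigs) can be supplied; a missing call then requires both tracks to concur
(logical AND). Non-reference region status is three-valued: present at
breadth >= 0.95, absent below 0.5, truncated between.

## SNP-matrix phylogeny

Tree sites are selected by a different rule than the discrimination filter:
every sample's *major allele* (highest read frequency, ties resolved to the
lexicographically smallest allele — though ties cannot actually reach the
0.9 bound) must have frequency >= 0.9 at depth >= 20, and sites where all
samples share the major allele are excluded as uninformative. Retained
majors are concatenated into per-sample pseudo-sequences; by default indel
sites are dropped entirely (`snps_only = TRUE`, reflecting a SNP alignment),
otherwise indel alleles are written as `-` and count as mismatches.

Distances are p-distances (proportion of mismatching columns). The tree is
built by the classic Saitou–Nei neighbor-joining agglomeration, implemented
in-package with a fully deterministic tie rule (smallest Q criterion, ties
by lexicographic taxon-pair labels) and negative branch lengths clamped to
zero. The original workflow fit its genome-wide SNP tree by maximum
likelihood; ML inference is out of scope here, so the package substitutes NJ
— the same method the source workflow used for its conserved-region tree —
and exports the concatenated FASTA alignment so any external ML program can
be run on it. On exactly additive distances NJ provably recovers the
generating topology, which the suite verifies on 100 random 6–10-taxon
cases and cross-checks against an independent NJ implementation
(`ape::nj`).

## The synthetic data generator

`generate_dataset()` emulates the study conditions at desk scale:

* a 200 kb single-chromosome genome with 30 non-overlapping genes on both
  strands (15% of genes carry one intron) — nothing downstream depends on
  chromosome count, so one chromosome keeps files readable;
* an in-clade of 3 deeply sequenced flor-analog samples (mirroring the three
  newly sequenced sherry strains) against 5 wine-analog samples;
* per-sample, per-site depths drawn as 20 + NB(mu = mean_depth − 20,
  size = dispersion) with `mean_depth = 60`: overdispersed like short-read
  coverage, but floored at the filter's 20x bound because the emulated
  study sequenced at ~200x, where depth failures at a typical site are
  negligible; sites *below* the bound are a planted decoy class, not a
  random event;
* 50 planted clade-fixed biallelic variants whose positions are chosen to
  cover all eight effect categories, in proportions loosely following the
  reported category spectrum (missense-heavy, then upstream and synonymous,
  few deleterious). Placement uses local geometry and codon arithmetic only
  — the downstream classifier is never consulted, so truth labels stay
  independent of the code they test;
* three decoy classes: 200 shared polymorphisms (fixed in a sample subset
  that never coincides with either clade), 50 heterozygous-like sites
  (major-allele frequency drawn in [0.4, 0.6] for a subset), and 30
  low-depth sites (perfect clade pattern, >= 1 sample forced to 5–19x);
* allele read counts are `AO = round(f × DP)`, `RO = DP − AO`, so
  `RO + AO = DP` holds exactly (a tested invariant);
* clade-fixed allele frequencies are jittered within
  `[1 − support_noise, 1]` with `support_noise = 0.02` by default. The
  within-clade frequency noise of the real strains is unknown; this jitter
  is a stand-in, not an estimate, and the noise-free setting
  (`support_noise = 0`) is the regime in which exact truth recovery is
  asserted;
* planted gene deletions (breadth drawn in [0.05, 0.45] in every in-clade
  sample, [0.90, 1.00] elsewhere) and novel-gene candidates whose hit-table
  rows fall below the 70%/80% rule.

All randomness flows from one integer seed; identical configurations yield
byte-identical files (tested via checksums).

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: read-level error and mapping artifacts,
alignment bias near indels, linkage between sites, non-uniform base
composition, ploidy mixtures, structural variation beyond whole-gene loss,
and multi-allelic segregation within a clade. Results on real callsets
depend on the upstream mapper and caller in ways the synthetic path cannot
probe.

## Problem sizes in the test and acceptance runs

The suite exercises: noise-free recovery on ten replicate simulations (50
planted sites against 200 decoys each); filter-vs-brute-force equivalence on
10,000 random sites; classifier-vs-retranslation equivalence on 1,000 random
coding edits across strands; NJ topology recovery on 100 random additive
matrices plus clade bipartition on ten simulated replicates; and a
1,000-replicate enrichment null calibration. These sizes are the package's
own choice of a thorough-but-quick regression envelope; all scale linearly
if larger sweeps are wanted.

## Known limitations

* The dN/dS ratio is a raw count ratio; it ignores codon composition and
  the number of synonymous/nonsynonymous sites per gene.
* Effect classification assumes gene models with well-formed CDS intervals
  (total length a multiple of 3; trailing partial codons are ignored) and
  does not model UTR structure beyond fixed windows.
* The locus partition for intergenic calls is a package convention.
* Complex freebayes alleles are handled as literal allele strings; no
  variant normalisation (left-alignment, decomposition) is performed.
* NJ substitutes for ML tree inference; use the exported alignment for ML.
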