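---
title: "Methods: gene ages, chromatin classes and NMD features in genage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene ages, chromatin classes and NMD features in genage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genage)
library(dplyr)
```

`genage` chains five analyses that together characterise how evolutionarily
young genes are regulated: phylostratigraphic age assignment, NMD-feature
annotation from gene models, open-chromatin peak classification and
enrichment, metagene accessibility profiling, and age-stratified
nonparametric group comparisons. This vignette explains the models and the
choices behind them; the README shows the end-to-end usage.

## Phylostratigraphy: the deepest-clade rule

A rooted species tree with a focal leaf defines a *lineage*: the nested
clades $C_1 \supset C_2 \supset \dots \supset C_S$ on the root-to-focal
path. A best hit in species $s$ is evidence that the gene predates the
divergence at stratum $\mathrm{stratum}(s) = \max\{i : s \in C_i\}$, so a
protein's phylostratum is the minimum of $\mathrm{stratum}(s)$ over its hit
species — the deepest clade still containing a homolog. Assumptions and
edge rules:

* **Hitless proteins are youngest** (stratum $S$), not "unassigned": absence
  of any homolog outside the focal species is exactly what defines the
  youngest class.
* **Self-hits** (hit species = focal) map to stratum $S$ and are therefore
  neutral under the min rule.
* **Gene age = min over isoform proteins.** How isoform-level ages combine
  into a gene age is genuinely open; we take the oldest isoform, because a
  single ancient homolog of any isoform establishes the gene's ancestry.
  The aggregation is a one-line change if a different convention is needed.
* **Topology only.** Strata count nodes on the root-to-focal path;
  branch lengths and polytomies are respected but not interpreted.

`assign_phylostratum()` is checked against an independent exhaustive
clade-scan oracle on random trees, and against the generator's planted ages.

## Transcript models and NMD rules

Internally all intervals are 0-based half-open; GFF3 (1-based closed)
converts at the I/O boundary, so exon arithmetic lines up with BED peaks
without off-by-one cases. In mature-mRNA coordinates (exons concatenated
5′→3′), with stop position $t$, transcript length $L$ and last exon-exon
junction $j$:

* `utr3_len` $= L - t$, and a transcript is flagged for a long 3′UTR when
  `utr3_len` $> 350$ nt;
* `stop_to_last_ejc` $= j - t$, and flagged as PTC-like when $> 50$ nt;
  single-exon transcripts have no junction and can never satisfy this rule;
* `nmd_feature` is the OR of the two flags, and a gene is NMD-flagged if any
  isoform is.

Both thresholds are strict inequalities — values exactly at 350/50 are never
flagged — and both are exposed as parameters. The stop position is taken at
the 3′ end of the CDS feature as annotated (the common plant-annotation
convention that includes the stop codon). We deliberately do **not**
subtract an EJC deposition offset (~20–24 nt upstream of the junction): the
rule is stated on the junction distance itself, and the threshold parameter
absorbs the difference if a user prefers the offset convention.

## Chromatin classes, enrichment and metagenes

**RPM filter.** A peak is kept only if count/library-size × 10⁶ ≥ 1 in
*every* replicate; the filter is idempotent and order-preserving.
Replicate concordance is Pearson correlation of log10(RPM + 0.01); the
0.01-RPM pseudocount keeps zero-count peaks on the plot without dominating
the correlation.

**Region classes.** Each interval is assigned to its nearest gene by
distance to the TSS (0 if the TSS lies inside the interval, else the gap to
the nearer edge; exact ties break to the lexicographically smaller gene id
for determinism). Overlap with a gene body wins over everything; otherwise
the interval is TSS-proximal when it lies within 1.5 kb upstream (boundary
*inclusive*, "up to 1.5 kb"), TSS-distal when upstream-intergenic strictly
beyond, and "other" when downstream of the gene — a downstream peak past the
3′ end is not an upstream enhancer candidate and must not inflate the distal
class. Upstream is strand-aware: upstream of a minus-strand gene lies at
larger coordinates.

**Enrichment.** For age group $g$ and region class $c$, enrichment is
$\mathrm{obs}(g,c)/\mathrm{exp}(c)$, where the expected value is the
percentage of *all* aged genes carrying the class. The background definition
is genuinely ambiguous in this kind of analysis, so both components are
reported alongside the ratio; any alternative background can be recomputed
from the table. With this definition, group ratios weighted by group size
average to exactly 1 when the groups partition the universe — a property the
tests assert.

**Metagene profiles.** The coverage track is scaled to genome-wide mean 1
(per-base mean over the track's span) — coverage normalization is
underdetermined in general, and a whole-track scaling keeps conditions
comparable without per-gene renormalization hiding height differences.
Signal over TSS ± 2000 bp is extracted per gene, reversed for minus-strand
genes so the axis runs 5′→3′, averaged in 50-bp bins, then averaged over the
genes of each group. Genes whose window would cross a chromosome edge are
skipped and counted. Mirroring the entire genome (coordinates and strands)
reproduces the profile bin-for-bin, which is the property test for the
strand logic. When a quantity in *track units* is needed (e.g. a stress
re-opening factor), the profile is multiplied back by the stored normalizer
and the track floor — estimated from the outermost bins, which lie > 6
bump-SDs from the TSS — is subtracted; ratios of bump heights are then
comparable across conditions even though each condition is normalized by its
own mean.

## Group comparisons

All old-vs-young comparisons use the two-sided Mann–Whitney test: exact
p-values when the smaller group has ≤ 8 observations and there are no ties,
otherwise the normal approximation with continuity and tie corrections.
Degenerate inputs (every value identical, or all paired differences zero)
carry no evidence and report p = 1 rather than NaN. TPM values get a
0.01-TPM pseudocount before log10 — zeros occur in any real TPM table — and
because the test is rank-based, monotone transforms change only the reported
medians, never the p-value (asserted as a property test). The NMD-null
response is per-gene $\log_2((\mathrm{mut}+pc)/(\mathrm{wt}+pc))$; the
monosome score is treated as given per genotype, compared with a paired
Wilcoxon signed-rank test within each age group, and its definition
($\log_2$ monosome/polysome abundance) is a configurable contract rather
than a fixed formula. The handful of headline comparisons is reported with
raw p-values; no multiple-testing correction is applied across them.

## The synthetic-data generator

The generator emits a complete dataset — species tree, hit tables, GFF3,
peaks with replicate counts, enhancers, per-condition coverage, expression
and metric tables — whose every age-dependent signal is planted and
recorded in a ground-truth table:

* **Ages**: 1250 genes by default — 500 old (PS1), 500 young (PS19), 250
  uniform over PS2–PS18 so age gradients (e.g. nearest-gene age by enhancer
  class) are testable. Hit tables are constructed so the deepest-clade rule
  returns the planted ages exactly.
* **Genome layout**: one 12-kb slot per gene on 2 chromosomes, bodies of
  roughly 0.9–4.6 kb (set by realistic UTR/CDS/intron draws), TSSs ≥ 7 kb
  apart. The spacing, not the body length, is what makes the
  proximal/distal ground truth unambiguous, so the slot layout is the
  invariant we guarantee.
* **Expression**: between-gene log10 TPM $\sim N(1.5 - 0.5w, 0.4)$ where
  $w$ interpolates 0 (old) to 1 (young) — a planted 0.5 log10 deficit for
  young genes — with 0.1 log10 per-sample noise, 2 replicates per genotype;
  the NMD-null genotype multiplies young-gene means by 1.5.
* **Chromatin**: Gaussian TSS-openness bumps (SD 300 bp) of height 3 (old)
  to 1 (young) over a 0.5 floor, 5% log-normal bin noise; stress conditions
  multiply young-gene bump heights by a re-opening factor (2.0 for the
  default stress, and deliberately 1.0 for the 12-h-cold-like condition, the
  one stress that does not re-open chromatin). Proximal peaks are planted at
  0.8 (old) → 0.3 (young), distal enhancers at 0.2 (old) → 0.6 (young);
  every enhancer co-locates with an open-chromatin peak with probability
  0.65, which is what the Venn-style overlap fraction recovers.
* **Peak counts**: per-peak log10 RPM is drawn bivariate-normal across the
  two replicates with correlation 0.9 and SD 0.5 around mean 1.5, and
  counts are Poisson-sampled at 2×10⁷ reads per library — a
  Poisson-lognormal, i.e. overdispersed counts correlated on the log scale.
  The large library size keeps Poisson noise from attenuating the planted
  correlation.
* **NMD geometry**: a planted feature is realized through actual exon/CDS
  geometry — a 3′UTR drawn from 400–900 nt, or a stop placed 51–250 nt
  before the last junction — and a planted non-feature stays strictly below
  both thresholds, so `classify_nmd()` recovers the plant for 100% of
  genes by construction.
* **Metrics**: half-lives log-normal around 4 h with a 0.7× young scale;
  TRAP association 1.0 with a −0.5 young shift (log2); monosome scores
  paired across genotypes with a −0.3 shift for young genes in the NMD-null
  only.

Everything is drawn from a single seed and reproduces bit-for-bit.

**What the generator does not emulate:** sequence content, read-level noise,
peak-calling artifacts, overlapping or nested genes, irregular gene spacing,
chromatin domains, correlated gene neighborhoods, or isoform-level
expression variation. Passing tests therefore demonstrate that the
*implementation* is correct under the planted statistical structure, not
that real data will show these effects at these magnitudes.

## Numerical choices and problem sizes

Interval arithmetic is integer throughout; coverage extraction uses
run-length encodings, so track resolution (25 bp in the generator) is a
storage choice, not an analysis parameter. The test suite runs the
generator at 60–1250 genes depending on what the test measures: exact
recovery checks need no replication, effect-detection checks use the default
500 genes per age group, the replicate-correlation check uses the full
default peak set (~2000 peaks), and the type-I-error calibration uses 1000
simulated null datasets of 50 genes per group. The pipeline is a pure
function of its inputs and configuration: reruns produce byte-identical
tables, which the tests assert file-by-file.

## Known limitations

* The nearest-gene assignment considers TSS distance (with a gene-body
  override) only; it does not model 3D contacts or skip-over-gene enhancer
  targeting.
* The expected-background definition for enrichment is one of several
  defensible choices; the components are reported so others can be derived.
* Gene-level TSS and UTR metrics come from the longest coding isoform;
  alternative representative-transcript rules would shift metagene anchors
  by at most the isoform TSS spread.
* The Mann–Whitney exactness switch (n ≤ 8, tie-free) matches common
  practice but is a policy, not a theorem; near the switch the p-values
  differ slightly between regimes.
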