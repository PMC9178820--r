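# genage

Phylostratigraphic gene ages and age-stratified regulatory genomics in R.

## The problem

Evolutionarily young ("orphan") genes — genes with no detectable homolog
outside a recent lineage — tend to be weakly expressed, and several layers of
regulation have been proposed to keep them that way: closed chromatin at
their transcription start sites (TSS), reliance on distal rather than
promoter-proximal enhancers, and post-transcriptional degradation of their
mRNAs by nonsense-mediated decay (NMD). Testing these ideas requires wiring
together several otherwise separate analyses: assigning every gene an
evolutionary age, classifying open-chromatin peaks and enhancers relative to
gene TSSs, profiling accessibility around TSSs per age class, annotating NMD
features from gene models, and comparing expression and translation metrics
between age classes.

`genage` implements that whole chain as a tested, composable pipeline, plus a
synthetic-data generator that plants all of the age-dependent structure with
known ground truth so every stage can be validated end to end.

## What it computes

**Gene age (phylostratum).** Given a rooted species tree with a focal leaf,
the root-to-focal path defines nested clades `C_1 ⊃ C_2 ⊃ … ⊃ C_S` (`C_1` =
all species, `C_S` = the focal species alone). A protein with best hits in a
set of species `H` is assigned the stratum

```
PS(p) = min { stratum(s) : s ∈ H },    stratum(s) = max { i : s ∈ C_i }
```

i.e. the deepest clade that still contains a homolog; proteins with no hits
get `S` (youngest). A gene's age is the minimum over its isoforms.

**NMD features.** In mature-mRNA coordinates, a transcript carries an NMD
feature if its termination codon lies more than 50 nt upstream of the last
exon–exon junction (a premature termination codon under the exon-junction
complex model), or its 3′UTR exceeds 350 nt. Both inequalities are strict.

**Chromatin.** Peaks are filtered at ≥ 1 RPM in *every* replicate
(RPM = count / library size × 10⁶), classified as TSS-proximal (within
1.5 kb upstream of the nearest TSS, boundary inclusive), TSS-distal
(upstream beyond 1.5 kb), gene-body, or other, with strand-aware upstream
logic; enrichment of each class in an age group is observed % / expected %
against the all-gene background. Metagene profiles average
mean-1-normalized coverage in 50-bp bins over ±2 kb around TSSs, oriented
5′→3′.

**Group statistics.** Old-vs-young comparisons of log10 TPM, log2
mutant/wild-type response, mRNA half-life and ribosome association use the
two-sided Mann–Whitney test (exact for small tie-free samples, normal
approximation with continuity and tie correction otherwise); monosome-score
shifts between genotypes use the paired Wilcoxon signed-rank test within
each age group.

## Worked example

```r
library(genage)
library(dplyr)

ds <- generate_dataset(generator_config(seed = 42, n_genes = 400))

# 1. gene ages from the species tree + best-hit tables
lin <- phylo_lineage(ds$tree_newick, ds$focal_species)
lin
#> <phylo_lineage> focal species: focal_sp | strata: 19
ages <- assign_phylostratum(ds$hits, lin, proteins = ds$protein_map$protein_id) |>
  gene_ages(ds$protein_map) |>
  age_groups(old_strata = 1, young_strata = lin$n_strata)
count(ages, age_group)
#>   age_group     n
#> 1 old         160
#> 2 young       160
#> 3 other        80

# 2. expression by age: young genes are lower
cmp <- compare_expression(ds$expression$wild_type, ages)
glance(cmp)
#>   comparison                  statistic  p_value  direction   median_diff
#> 1 expression (log10 mean TPM)      3754 8.21e-28 young_lower      -0.621
```

The young-gene median is 0.62 log10 units (≈ 4-fold) below the old-gene
median, Mann–Whitney p ≈ 8×10⁻²⁸ — the generator's planted 0.5 log10 shift,
recovered. Continuing:

```r
# 3. NMD features accumulate in young genes
nmd_frequency_by_age(classify_nmd(ds$transcripts), ages)
#>   age_group n_genes n_flagged fraction
#> 1 old           160        11   0.0688
#> 2 young         160        68   0.425

# 4. open chromatin at TSSs, by age and condition
anchors <- ds$ground_truth[, c("gene_id", "chrom", "strand", "tss", "age_group")]
prof <- metagene(ds$tracks$control, anchors)
autoplot(prof)   # old genes open, young genes closed at the TSS

# 5. peak filtering and enhancer overlap
filtered <- filter_peaks_rpm(ds$peaks, ds$library_sizes)
overlap_sets(filtered, ds$enhancers)$frac_b_overlapping
#> [1] 0.679     # fraction of enhancers covered by open chromatin
```

`run_pipeline(pipeline_config(dir), outdir)` chains all of the above over a
dataset directory (the layout written by `write_dataset()`) and writes every
figure-level table as TSV plus a run log; `inst/cli/genage` wraps it for the
shell (`genage generate`, `genage run-all`, per-stage subcommands).

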