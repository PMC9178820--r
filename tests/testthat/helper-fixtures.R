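# Shared fixture builders: everything is generated in code at test time.

# one-row transcript tibble from raw geometry
make_tx <- function(exon_starts, exon_ends, cds_start = NA, cds_end = NA,
                    strand = "+", id = "t1", gene = "g1", chrom = "chr1") {
  tibble::tibble(
    transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
    exon_starts = list(exon_starts), exon_ends = list(exon_ends),
    cds_start = cds_start, cds_end = cds_end, coding = !is.na(cds_start)
  )
}

# mirror a transcript table through genome length L: x -> L - x, strand flip
mirror_tx <- function(tx, L) {
  out <- tx
  for (i in seq_len(nrow(tx))) {
    s <- tx$exon_starts[[i]]; e <- tx$exon_ends[[i]]
    out$exon_starts[[i]] <- sort(L - e)
    out$exon_ends[[i]] <- sort(L - s)
  }
  out$cds_start <- L - tx$cds_end
  out$cds_end <- L - tx$cds_start
  out$strand <- ifelse(tx$strand == "+", "-", "+")
  out
}

# exhaustive clade-scan oracle for the deepest-clade rule: the smallest
# lineage index whose clade holds a hit species absent from the next clade
oracle_stratum <- function(hit_species, clades) {
  S <- length(clades)
  if (!length(hit_species)) return(S)
  for (i in seq_len(S)) {
    nxt <- if (i < S) clades[[i + 1]] else character(0)
    divergent <- setdiff(intersect(hit_species, clades[[i]]), nxt)
    if (length(divergent)) return(i)
  }
  S
}

# random rooted species tree with a designated focal tip
random_species_tree <- function(n_leaves) {
  phy <- ape::rtree(n_leaves, rooted = TRUE)
  phy$tip.label <- sprintf("sp%02d", seq_len(n_leaves))
  list(tree = phy, focal = sample(phy$tip.label, 1))
}

# gene table for a toy chromosome: one plus- and one minus-strand gene
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(10000, 30000),
    end = c(13000, 33000),
    tss = c(10000, 33000)
  )
}
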