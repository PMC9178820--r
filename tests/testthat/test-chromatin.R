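make_peaks <- function(counts1, counts2, chrom = "c1") {
  n <- length(counts1)
  tibble::tibble(
    chrom = chrom, start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 200L,
    name = sprintf("p%03d", seq_len(n)), rep1 = counts1, rep2 = counts2)
}
libs2 <- c(rep1 = 1e6, rep2 = 1e6)  # with 1e6 reads, count == RPM

test_that("RPM filter removes peaks below threshold in any replicate", {
  # a peak at 1.2 RPM in one replicate but 0.9 in the other is removed
  p <- make_peaks(c(1.2, 5, 3), c(0.9, 5, 3))
  kept <- filter_peaks_rpm(p, libs2, threshold = 1)
  expect_equal(kept$name, c("p002", "p003"))

  # threshold 0 is the identity
  expect_equal(filter_peaks_rpm(p, libs2, threshold = 0), p)

  # planted fixture: 30 of 100 peaks dip below 1 RPM in replicate 2 only
  set.seed(3)
  low <- sample(100, 30)
  c2 <- rep(50, 100); c2[low] <- 0.5
  p100 <- make_peaks(rep(50, 100), c2)
  kept100 <- filter_peaks_rpm(p100, libs2, threshold = 1)
  expect_equal(nrow(kept100), 70L)
  # idempotence and order preservation
  expect_equal(filter_peaks_rpm(kept100, libs2, threshold = 1), kept100)
  expect_equal(kept100$name, p100$name[-sort(low)])

  expect_error(filter_peaks_rpm(p, c(rep1 = 0, rep2 = 1e6)), "positive")
})

test_that("replicate concordance recovers planted log-scale correlation", {
  p <- make_peaks(c(10, 20, 30, 5), c(10, 20, 30, 5))
  expect_equal(replicate_concordance(p, libs2)$r, 1.0)
  expect_error(replicate_concordance(p, libs2[1]), "two replicates")

  # independent counts: near-zero correlation
  set.seed(21)
  ind <- make_peaks(runif(1000, 1, 100), runif(1000, 1, 100))
  expect_lt(abs(replicate_concordance(ind, libs2)$r), 0.1)

  # generator's planted rho = 0.9 recovered within 0.05 at n ~ 2000
  ds <- generate_dataset(generator_config(seed = 4, n_genes = 1250))
  r <- replicate_concordance(ds$peaks, ds$library_sizes)$r
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("intervals classify by gene-body overlap and strand-aware upstream distance", {
  genes <- toy_genes()  # gA: + strand TSS 10000; gB: - strand TSS 33000
  iv <- tibble::tibble(
    chrom = "chr1",
    start = c(9000, 7000, 10500, 13500, 33000, 36000, 8500, 6999),
    end   = c(9500, 7400, 10600, 13900, 34500, 36400, 8501, 7000),
    name  = paste0("p", 1:8))
  got <- classify_intervals(iv, genes, proximal_bp = 1500)
  want <- c("tss_proximal",  # 500 bp upstream of + TSS
            "tss_distal",    # 2.6 kb upstream, intergenic
            "gene_body",     # inside gA
            "other",         # downstream of gA, not upstream of anything
            "tss_proximal",  # abutting - strand TSS (upstream at larger coords)
            "tss_distal",    # 3 kb upstream of - strand gene
            "tss_proximal",  # edge at 1499 bp
            "tss_distal")    # edge at 3000 bp
  expect_equal(as.character(got$region_class), want)
  expect_equal(got$nearest_gene, c("gA", "gA", "gA", "gA", "gB", "gB", "gA", "gA"))

  # boundary: gap of exactly proximal_bp is proximal (inclusive), 1 bp more is distal
  edge <- tibble::tibble(chrom = "chr1",
                         start = c(8400, 8399), end = c(8500, 8499),
                         name = c("at", "past"))
  got_edge <- classify_intervals(edge, genes, proximal_bp = 1500)
  expect_equal(as.character(got_edge$region_class),
               c("tss_proximal", "tss_distal"))

  # order invariance
  perm <- sample(nrow(iv))
  got_perm <- classify_intervals(iv[perm, ], genes)
  expect_equal(got_perm$region_class,
               got$region_class[perm])
  # every interval gets exactly one class
  expect_false(anyNA(got$region_class))

  # unknown chromosome -> other, with a warning
  expect_warning(
    other <- classify_intervals(
      tibble::tibble(chrom = "chrX", start = 1, end = 100, name = "x"), genes),
    "absent")
  expect_equal(as.character(other$region_class), "other")
})

test_that("per-gene presence flags and both-class combine correctly", {
  genes <- toy_genes()
  iv <- tibble::tibble(chrom = "chr1",
                       start = c(9000, 7000), end = c(9500, 7400),
                       name = c("prox", "dist"))
  pres <- gene_region_presence(classify_intervals(iv, genes), genes)
  expect_true(pres$both[pres$gene_id == "gA"])
  expect_false(pres$has_proximal[pres$gene_id == "gB"])
  expect_false(pres$both[pres$gene_id == "gB"])
})

test_that("enrichment ratios follow the observed/expected definition", {
  # analytic toy: young 60% distal, background 30% -> ratio exactly 2
  n <- 100
  pres <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    has_proximal = rep(FALSE, n),
    has_distal = c(rep(TRUE, 30), rep(FALSE, 20),  # young: 30/50
                   rep(FALSE, 50)),
    both = rep(FALSE, n))
  ages <- age_groups(tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    phylostratum = c(rep(19L, 50), rep(1L, 50))), 1, 19)
  enr <- enrichment_by_age(pres, ages)
  young_distal <- enr$ratio[enr$age_group == "young" & enr$region == "distal"]
  expect_equal(young_distal, 2.0)
  expect_equal(enr$expected_pct[enr$region == "distal"][1], 30)

  # a group identical to the background has ratio 1 everywhere it is defined
  pres_u <- pres
  pres_u$has_distal <- rep(c(TRUE, FALSE), 50)
  enr_u <- enrichment_by_age(pres_u, ages)
  expect_equal(enr_u$ratio[enr_u$region == "distal"], c(1, 1))

  # size-weighted group ratios average to 1 when groups partition the universe
  w <- enr$n_genes[enr$region == "distal"]
  r <- enr$ratio[enr$region == "distal"]
  expect_equal(sum(w * r) / sum(w), 1.0)
})

test_that("overlap fractions are exact on constructed sets", {
  a <- tibble::tibble(chrom = "c1", start = (1:10) * 1000,
                      end = (1:10) * 1000 + 100)
  expect_equal(overlap_sets(a, a)$frac_b_overlapping, 1.0)
  b_disjoint <- dplyr::mutate(a, start = start + 500, end = end + 500)
  expect_equal(overlap_sets(a, b_disjoint)$frac_a_overlapping, 0)

  # planted: 60 of 100 enhancers inside peaks
  peaks <- tibble::tibble(chrom = "c1", start = (1:100) * 10000,
                          end = (1:100) * 10000 + 500)
  enh <- peaks
  enh$start[61:100] <- enh$start[61:100] + 5000  # move 40 away
  enh$end[61:100] <- enh$end[61:100] + 5000
  ov <- overlap_sets(peaks, enh)
  expect_equal(ov$frac_b_overlapping, 0.60)
  # symmetric overlap counts at min_overlap = 1
  expect_equal(ov$a_overlapping, ov$b_overlapping)
})

test_that("nearest-gene ages by class summarise with deterministic ties", {
  genes <- toy_genes()
  ages <- tibble::tibble(gene_id = c("gA", "gB"), phylostratum = c(1L, 19L))
  iv <- tibble::tibble(chrom = "chr1", start = c(9000, 6000, 35000),
                       end = c(9500, 6500, 35400), name = paste0("e", 1:3))
  cls <- classify_intervals(iv, genes)
  out <- nearest_gene_age_by_class(cls, ages)
  expect_equal(out$median_age[out$region_class == "tss_proximal"], 1)
  expect_equal(out$median_age[out$region_class == "tss_distal"],
               stats::median(c(1, 19)))

  # tie at exactly equal TSS distance resolves to the smaller gene_id
  mid <- tibble::tibble(chrom = "chr1", start = 21400, end = 21600,
                        name = "tie")
  # distances: gA TSS 10000 -> 11400; gB TSS 33000 -> 11400
  tie <- classify_intervals(mid, genes)
  expect_equal(tie$nearest_gene, "gA")
})

test_that("metagene profiles are flat on constant tracks and strand-symmetric", {
  flat <- tibble::tibble(chrom = "chr1", start = seq(0, 39950, 50),
                         end = seq(50, 40000, 50), value = 3)
  anchors <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                            strand = c("+", "-"), tss = c(10000, 30000),
                            age_group = c("old", "young"))
  prof <- metagene(flat, anchors, window = 2000, binsize = 50)
  # normalization scales a constant track to exactly 1 everywhere
  expect_equal(unique(prof$mean_coverage), 1)
  expect_equal(nrow(prof), 2 * 80)
  expect_equal(range(prof$bin_center), c(-1975, 1975))

  # a linear ramp seen from a minus-strand gene mirrors the plus-strand view
  ramp <- tibble::tibble(chrom = "chr1", start = 0:39999,
                         end = 1:40000, value = (0:39999) / 1000)
  plus_view <- metagene(ramp, anchors[1, ], normalize = FALSE)
  minus_anchor <- tibble::tibble(gene_id = "gB", chrom = "chr1", strand = "-",
                                 tss = 10000, age_group = "old")
  minus_view <- metagene(ramp, minus_anchor, normalize = FALSE)
  expect_equal(minus_view$mean_coverage, rev(plus_view$mean_coverage))

  # genes too close to a chromosome edge are skipped and counted
  edge <- dplyr::mutate(anchors[1, ], tss = 1000)
  expect_error(metagene(flat, edge), "no usable")
  both <- dplyr::bind_rows(anchors[1, ], edge)
  prof2 <- metagene(flat, both)
  expect_equal(attr(prof2, "n_skipped"), 1L)
})

test_that("metagene is invariant under mirroring the whole genome", {
  ds <- generate_dataset(generator_config(seed = 6, n_genes = 60,
                                          n_chroms = 1))
  track <- ds$tracks$control
  anchors <- ds$ground_truth[, c("gene_id", "chrom", "strand", "tss",
                                 "age_group")]
  L <- ds$chrom_len[[1]]
  prof <- metagene(track, anchors)
  m_track <- tibble::tibble(chrom = track$chrom, start = L - track$end,
                            end = L - track$start, value = track$value)
  m_anchors <- dplyr::mutate(anchors,
                             tss = L - tss,
                             strand = ifelse(strand == "+", "-", "+"))
  m_prof <- metagene(m_track, m_anchors)
  expect_equal(m_prof$mean_coverage, prof$mean_coverage, tolerance = 1e-12)
})
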