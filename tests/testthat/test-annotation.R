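test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
           "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
           "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=t1.e1;Parent=t1",
           "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=t1.e2;Parent=t1",
           "chr1\tsrc\tCDS\t101\t200\t.\t+\t.\tID=t1.c1;Parent=t1",
           "chr1\tsrc\tCDS\t301\t350\t.\t+\t.\tID=t1.c2;Parent=t1")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  tx <- read_gff3(path)
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$exon_starts[[1]], c(100L, 300L))
  expect_equal(tx$exon_ends[[1]], c(200L, 400L))
  expect_equal(tx$cds_start, 100L)
  expect_equal(tx$cds_end, 350L)

  # write -> read preserves every TranscriptModel field
  out <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(tx, out)
  back <- read_gff3(out)
  expect_equal(back$exon_starts, tx$exon_starts)
  expect_equal(back$exon_ends, tx$exon_ends)
  expect_equal(back[, c("transcript_id", "gene_id", "chrom", "strand",
                        "cds_start", "cds_end", "coding")],
               tx[, c("transcript_id", "gene_id", "chrom", "strand",
                      "cds_start", "cds_end", "coding")])
})

test_that("generator GFF3 parses back to the planted gene set", {
  ds <- generate_dataset(generator_config(seed = 5, n_genes = 50))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ds$transcripts, path)
  tx <- read_gff3(path)
  expect_equal(sort(unique(tx$gene_id)), sort(unique(ds$transcripts$gene_id)))
  expect_equal(length(unique(tx$gene_id)), 50L)
})

test_that("inconsistent exon/CDS structure is excluded with a warning", {
  tx_bad <- make_tx(c(0, 200), c(100, 300), cds_start = 0, cds_end = 250)
  tx_bad$cds_end <- 251  # CDS length 151, not divisible by 3
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(tx_bad, path)
  expect_warning(tx <- read_gff3(path), "inconsistent")
  expect_equal(nrow(tx), 0L)
  expect_equal(attr(tx, "excluded"), "t1")
})

test_that("TSS is the 5'-most transcribed position, strand-aware", {
  plus <- make_tx(c(100, 300), c(200, 400), strand = "+")
  minus <- make_tx(c(100, 300), c(200, 400), strand = "-")
  expect_equal(transcript_tss(plus)$tss, 100)
  expect_equal(transcript_tss(minus)$tss, 400)
  # generator ground truth: TSS of representatives matches the plant
  ds <- generate_dataset(generator_config(seed = 2, n_genes = 80))
  gt <- gene_table(ds$transcripts)
  expect_equal(gt$tss[match(ds$ground_truth$gene_id, gt$gene_id)],
               ds$ground_truth$tss)
})

test_that("mRNA-space mapping places junctions and stop correctly", {
  single <- make_tx(0, 300, cds_start = 0, cds_end = 150)
  mc1 <- mrna_coords(single)
  expect_equal(mc1$stop_pos, 150)
  expect_equal(mc1$junctions[[1]], numeric(0))

  spliced <- make_tx(c(0, 200), c(100, 300), cds_start = 0, cds_end = 250)
  mc2 <- mrna_coords(spliced)
  expect_equal(mc2$tx_length, 200)
  expect_equal(mc2$junctions[[1]], 100)
  expect_equal(mc2$stop_pos, 150)

  # mirrored minus-strand version gives identical mRNA-space answers
  mirrored <- mirror_tx(spliced, 300)
  mc3 <- mrna_coords(mirrored)
  expect_equal(mc3$tx_length, mc2$tx_length)
  expect_equal(mc3$junctions, mc2$junctions)
  expect_equal(mc3$stop_pos, mc2$stop_pos)

  expect_error(mrna_coords(make_tx(0, 300, strand = "+")), "coding")
  bad <- make_tx(c(0, 200), c(100, 300), cds_start = 0, cds_end = 250)
  bad$cds_end <- 400
  expect_error(mrna_coords(bad), "outside exons")
})

test_that("NMD thresholds are strict and single-exon transcripts never PTC", {
  # 3'UTR exactly at the threshold is never flagged, one past always is
  utr_at <- make_tx(0, 500, cds_start = 0, cds_end = 150)   # utr3 = 350
  utr_over <- make_tx(0, 501, cds_start = 0, cds_end = 150) # utr3 = 351
  ann <- classify_nmd(dplyr::bind_rows(utr_at, utr_over))
  expect_equal(ann$utr3_len, c(350, 351))
  expect_equal(ann$long_utr_flag, c(FALSE, TRUE))
  expect_equal(ann$nmd_feature, c(FALSE, TRUE))

  # stop-to-junction exactly 50 not flagged, 51 flagged
  # exons [0,150+d) and [500,600): junction at 150+d, stop at 150
  d50 <- make_tx(c(0, 500), c(200, 600), cds_start = 0, cds_end = 150)
  d51 <- make_tx(c(0, 500), c(201, 600), cds_start = 0, cds_end = 150)
  ann2 <- classify_nmd(dplyr::bind_rows(d50, d51))
  expect_equal(ann2$stop_to_last_ejc, c(50, 51))
  expect_equal(ann2$ptc_flag, c(FALSE, TRUE))

  # single exon: no junction, below UTR threshold -> nothing flagged
  se <- classify_nmd(make_tx(0, 250, cds_start = 0, cds_end = 150))
  expect_true(is.na(se$stop_to_last_ejc))
  expect_false(se$ptc_flag)
  expect_false(se$nmd_feature)
})

test_that("NMD annotation is invariant under strand mirroring", {
  ds <- generate_dataset(generator_config(seed = 9, n_genes = 250))
  tx <- ds$transcripts
  L <- max(unlist(tx$exon_ends)) + 1000
  ann <- classify_nmd(tx)
  ann_m <- classify_nmd(mirror_tx(tx, L))
  expect_equal(ann_m$utr3_len, ann$utr3_len)
  expect_equal(ann_m$stop_to_last_ejc, ann$stop_to_last_ejc)
  expect_equal(ann_m$nmd_feature, ann$nmd_feature)
  # utr3_len + stop position always equals the mature transcript length
  mc <- mrna_coords(tx)
  expect_equal(ann$utr3_len + mc$stop_pos, mc$tx_length)
})

test_that("NMD frequencies count flagged genes per group", {
  nmd <- tibble::tibble(
    transcript_id = sprintf("t%02d", 1:20),
    gene_id = sprintf("g%02d", 1:20),
    nmd_feature = c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 2), rep(FALSE, 8)))
  ages <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    phylostratum = c(rep(1L, 10), rep(19L, 10)))
  ages <- age_groups(ages, 1, 19)
  freq <- nmd_frequency_by_age(nmd, ages)
  expect_equal(freq$fraction[freq$age_group == "old"], 0.4)
  expect_equal(freq$fraction[freq$age_group == "young"], 0.2)
  expect_equal(freq$n_genes, c(10L, 10L))
  expect_error(nmd_frequency_by_age(nmd[1:10, ], ages), "empty")
})
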