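#' Read transcript models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (linked by `Parent` attributes) into a
#' transcript table.  GFF3 coordinates (1-based, closed) are converted to the
#' package-internal convention, 0-based half-open, at this boundary so that
#' all interval arithmetic matches BED inputs.
#'
#' @param path Path to a GFF3 file.
#' @param validate_cds If `TRUE` (default), transcripts whose exonic CDS
#'   length is not divisible by 3, or whose CDS span is not contained in the
#'   exon union, are excluded with a warning; excluded ids are attached as
#'   attribute `excluded`.
#'
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `exon_starts`, `exon_ends` (list columns, 0-based
#'   half-open, sorted by coordinate), `cds_start`, `cds_end` (genomic CDS
#'   span; `NA` for non-coding transcripts) and `coding`.
#' @export
read_gff3 <- function(path, validate_cds = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = vapply(gr$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  )
  mrna <- df[df$type %in% c("mRNA", "transcript"), ]
  parts <- df[df$type %in% c("exon", "CDS"), ]
  tx <- mrna |>
    dplyr::rename(transcript_id = "id", gene_id = "parent") |>
    dplyr::select("transcript_id", "gene_id", "chrom", "strand")
  exn <- parts |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::arrange(.data$parent, .data$start) |>
    dplyr::summarise(exon_starts = list(.data$start),
                     exon_ends = list(.data$end), .by = "parent")
  cds <- parts |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::summarise(cds_start = min(.data$start),
                     cds_end = max(.data$end),
                     cds_len = sum(.data$end - .data$start),
                     .by = "parent")
  out <- tx |>
    dplyr::left_join(exn, by = c(transcript_id = "parent")) |>
    dplyr::left_join(cds, by = c(transcript_id = "parent")) |>
    dplyr::mutate(coding = !is.na(.data$cds_start)) |>
    tibble::as_tibble()
  if (any(lengths(out$exon_starts) == 0L)) {
    rlang::abort("transcripts without exon features present")
  }
  excluded <- character(0)
  if (validate_cds && any(out$coding)) {
    bad <- vapply(seq_len(nrow(out)), function(i) {
      if (!out$coding[i]) return(FALSE)
      s <- out$exon_starts[[i]]; e <- out$exon_ends[[i]]
      # exonic nt within the CDS span must equal the summed CDS part lengths
      inside <- sum(pmax(0, pmin(e, out$cds_end[i]) - pmax(s, out$cds_start[i])))
      inside != out$cds_len[i] || (out$cds_len[i] %% 3L != 0L)
    }, logical(1))
    if (any(bad)) {
      excluded <- out$transcript_id[bad]
      rlang::warn(paste0("excluding ", length(excluded),
                         " transcript(s) with inconsistent exon/CDS structure: ",
                         paste(utils::head(excluded, 5), collapse = ", ")))
      out <- out[!bad, ]
    }
  }
  out <- dplyr::select(out, -dplyr::any_of("cds_len"))
  attr(out, "excluded") <- excluded
  out
}

#' Write transcript models to GFF3
#'
#' Emits gene, mRNA, exon and CDS lines with `Parent` attributes, converting
#' back from the internal 0-based half-open convention to GFF3 1-based
#' closed coordinates.  Reading the file back with [read_gff3()] reproduces
#' the input table.
#'
#' @param tx Transcript table in the format returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(tx, path) {
  tx <- tibble::as_tibble(tx)
  lines <- c("##gff-version 3")
  genes <- tx |>
    dplyr::mutate(tx_start = vapply(.data$exon_starts, min, numeric(1)),
                  tx_end = vapply(.data$exon_ends, max, numeric(1))) |>
    dplyr::summarise(start = min(.data$tx_start), end = max(.data$tx_end),
                     chrom = .data$chrom[1], strand = .data$strand[1],
                     .by = "gene_id")
  fmt <- function(chrom, type, start0, end0, strand, attrs) {
    sprintf("%s\tgenage\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, as.integer(start0) + 1L, as.integer(end0),
            strand, attrs)
  }
  for (g in seq_len(nrow(genes))) {
    lines <- c(lines, fmt(genes$chrom[g], "gene", genes$start[g], genes$end[g],
                          genes$strand[g], paste0("ID=", genes$gene_id[g])))
    sub <- tx[tx$gene_id == genes$gene_id[g], ]
    for (i in seq_len(nrow(sub))) {
      s <- sub$exon_starts[[i]]; e <- sub$exon_ends[[i]]
      lines <- c(lines,
        fmt(sub$chrom[i], "mRNA", min(s), max(e), sub$strand[i],
            paste0("ID=", sub$transcript_id[i], ";Parent=", sub$gene_id[i])),
        fmt(sub$chrom[i], "exon", s, e, sub$strand[i],
            paste0("ID=", sub$transcript_id[i], ".exon", seq_along(s),
                   ";Parent=", sub$transcript_id[i])))
      if (isTRUE(sub$coding[i])) {
        cs <- pmax(s, sub$cds_start[i]); ce <- pmin(e, sub$cds_end[i])
        keep <- cs < ce
        lines <- c(lines,
          fmt(sub$chrom[i], "CDS", cs[keep], ce[keep], sub$strand[i],
              paste0("ID=", sub$transcript_id[i], ".cds", seq_len(sum(keep)),
                     ";Parent=", sub$transcript_id[i])))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Transcription start sites of transcripts
#'
#' The TSS is the 5'-most transcribed position: the start of the first exon on
#' the plus strand, and the (half-open) end of the last exon on the minus
#' strand — the coordinate immediately 5' of the transcript body.
#'
#' @param tx Transcript table ([read_gff3()] format).
#' @return A tibble `transcript_id`, `gene_id`, `chrom`, `strand`, `tss`.
#' @export
transcript_tss <- function(tx) {
  tx <- tibble::as_tibble(tx)
  tibble::tibble(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    chrom = tx$chrom,
    strand = tx$strand,
    tss = ifelse(tx$strand == "+",
                 vapply(tx$exon_starts, min, numeric(1)),
                 vapply(tx$exon_ends, max, numeric(1)))
  )
}

#' Gene-level table with TSS and body span
#'
#' The representative transcript of a gene is its longest coding isoform
#' (longest non-coding isoform if the gene has no coding transcript); the
#' gene TSS is the representative's TSS and the body spans the union of the
#' representative's exons.
#'
#' @param tx Transcript table.
#' @return Tibble `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`,
#'   `transcript_id` (the representative).
#' @export
gene_table <- function(tx) {
  tx <- tibble::as_tibble(tx)
  tx |>
    dplyr::mutate(
      .len = vapply(seq_len(dplyr::n()),
                    function(i) sum(.data$exon_ends[[i]] - .data$exon_starts[[i]]),
                    numeric(1))
    ) |>
    dplyr::arrange(dplyr::desc(.data$coding), dplyr::desc(.data$.len),
                   .data$transcript_id) |>
    dplyr::slice_head(n = 1, by = "gene_id") |>
    dplyr::mutate(
      start = vapply(.data$exon_starts, min, numeric(1)),
      end = vapply(.data$exon_ends, max, numeric(1)),
      tss = ifelse(.data$strand == "+", .data$start, .data$end)
    ) |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end", "tss",
                  "transcript_id") |>
    dplyr::arrange(.data$gene_id)
}

#' Map transcripts into mature-mRNA coordinates
#'
#' Concatenates exons 5' to 3' in transcript orientation and reports, per
#' coding transcript, the mature transcript length, the mRNA-space position of
#' the 3' end of the CDS (the stop; by default the GFF3 CDS span includes the
#' stop codon) and the mRNA-space positions of the exon-exon junctions.
#'
#' @param tx Transcript table; non-coding transcripts are an error.
#' @return Tibble `transcript_id`, `gene_id`, `tx_length`, `stop_pos`,
#'   `junctions` (list column of numeric vectors; empty for single-exon
#'   transcripts).
#' @export
mrna_coords <- function(tx) {
  tx <- tibble::as_tibble(tx)
  if (!all(tx$coding)) {
    rlang::abort("mrna_coords requires coding transcripts; filter first")
  }
  res <- lapply(seq_len(nrow(tx)), function(i) {
    s <- tx$exon_starts[[i]]; e <- tx$exon_ends[[i]]
    minus <- tx$strand[i] == "-"
    ord <- order(s)
    s <- s[ord]; e <- e[ord]
    if (minus) { s <- rev(s); e <- rev(e) }     # 5' -> 3' order
    len <- e - s
    tx_len <- sum(len)
    junctions <- if (length(len) > 1L) cumsum(len)[-length(len)] else numeric(0)
    # genomic 3' end of CDS -> mRNA offset
    g <- if (minus) tx$cds_start[i] else tx$cds_end[i]
    offs <- cumsum(c(0, len))[seq_along(len)]
    stop_pos <- NA_real_
    for (k in seq_along(len)) {
      within <- if (minus) (g >= s[k] && g <= e[k]) else (g >= s[k] && g <= e[k])
      if (within) {
        stop_pos <- offs[k] + if (minus) (e[k] - g) else (g - s[k])
        break
      }
    }
    if (is.na(stop_pos)) {
      rlang::abort(paste0("CDS outside exons for transcript ",
                          tx$transcript_id[i]))
    }
    list(tx_length = tx_len, stop_pos = stop_pos, junctions = junctions)
  })
  tibble::tibble(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    tx_length = vapply(res, `[[`, numeric(1), "tx_length"),
    stop_pos = vapply(res, `[[`, numeric(1), "stop_pos"),
    junctions = lapply(res, `[[`, "junctions")
  )
}

#' Annotate NMD features from transcript geometry
#'
#' A transcript carries an NMD feature if its termination codon lies more than
#' `ejc_thresh` nt upstream of the last exon-exon junction in mature-mRNA
#' coordinates (a premature termination codon under the EJC model), or if its
#' 3'UTR is longer than `utr_thresh` nt.  Both inequalities are strict:
#' values exactly at the threshold are not flagged.  Single-exon transcripts
#' cannot satisfy the junction rule.
#'
#' @param tx Coding transcript table.
#' @param utr_thresh 3'UTR length threshold in nt (default 350).
#' @param ejc_thresh Stop-to-last-junction threshold in nt (default 50).
#' @return Tibble `transcript_id`, `gene_id`, `utr3_len`, `stop_to_last_ejc`
#'   (`NA` for single-exon transcripts), `ptc_flag`, `long_utr_flag`,
#'   `nmd_feature`.
#' @export
classify_nmd <- function(tx, utr_thresh = 350, ejc_thresh = 50) {
  mc <- mrna_coords(tx)
  last_junc <- vapply(mc$junctions, function(j)
    if (length(j)) max(j) else NA_real_, numeric(1))
  tibble::tibble(
    transcript_id = mc$transcript_id,
    gene_id = mc$gene_id,
    utr3_len = mc$tx_length - mc$stop_pos,
    stop_to_last_ejc = last_junc - mc$stop_pos
  ) |>
    dplyr::mutate(
      ptc_flag = !is.na(.data$stop_to_last_ejc) &
        .data$stop_to_last_ejc > ejc_thresh,
      long_utr_flag = .data$utr3_len > utr_thresh,
      nmd_feature = .data$ptc_flag | .data$long_utr_flag
    )
}

#' Fraction of genes with an NMD feature, by age group
#'
#' A gene is NMD-flagged if any of its isoforms carries a feature.  Fractions
#' are reported per age group with their numerators and denominators.
#'
#' @param nmd Transcript-level annotation from [classify_nmd()].
#' @param ages Gene age table with an `age_group` column ([age_groups()]).
#' @param groups Which groups to report (default old and young).
#' @return Tibble `age_group`, `n_genes`, `n_flagged`, `fraction`.
#' @export
nmd_frequency_by_age <- function(nmd, ages, groups = c("old", "young")) {
  gene_flag <- nmd |>
    dplyr::summarise(nmd_feature = any(.data$nmd_feature), .by = "gene_id")
  joined <- tibble::as_tibble(ages) |>
    dplyr::filter(.data$age_group %in% groups) |>
    dplyr::inner_join(gene_flag, by = "gene_id")
  out <- joined |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_flagged = sum(.data$nmd_feature),
      .by = "age_group"
    ) |>
    dplyr::mutate(fraction = .data$n_flagged / .data$n_genes) |>
    dplyr::arrange(.data$age_group)
  missing <- setdiff(groups, as.character(out$age_group))
  if (length(missing)) {
    rlang::abort(paste0("empty age group(s): ", paste(missing, collapse = ", ")))
  }
  out
}
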