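#' Read genomic intervals from BED
#'
#' @param path BED file (0-based, half-open).
#' @return Tibble `chrom`, `start`, `end` and, when present, `name`/`score`.
#'   Coordinates keep the BED 0-based half-open convention, which is also the
#'   package-internal one.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' Write genomic intervals to BED
#'
#' @param x Data frame with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(x)))
  df <- as.data.frame(x)[, cols]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a coverage track from bedGraph
#'
#' @param path bedGraph file.
#' @return Tibble `chrom`, `start`, `end`, `value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score
  )
}

#' Write a coverage track to bedGraph
#'
#' @param track Data frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as.data.frame(track)[, c("chrom", "start", "end", "value")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  df$value <- formatC(df$value, format = "g", digits = 8)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: tibble of intervals -> GRanges (internal 0-based half-open -> 1-based)
as_granges <- function(x, keep = character(0)) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  for (col in keep) S4Vectors::mcols(gr)[[col]] <- x[[col]]
  gr
}
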