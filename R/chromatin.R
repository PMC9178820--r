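#' Filter peaks by reads-per-million across replicates
#'
#' A peak is retained only if its normalized read count is at least
#' `threshold` RPM in every biological replicate; a peak below the threshold
#' in any single replicate is removed.  RPM(i, r) = count(i, r) /
#' library_size(r) * 1e6.
#'
#' @param peaks Data frame with one row per peak; replicate raw counts are in
#'   the columns named by `names(library_sizes)`.
#' @param library_sizes Named numeric vector of total mapped reads per
#'   replicate; names select the count columns.
#' @param threshold Minimum RPM (default 1).
#' @return The filtered tibble, original row order preserved.
#' @export
filter_peaks_rpm <- function(peaks, library_sizes, threshold = 1) {
  peaks <- tibble::as_tibble(peaks)
  check_library_sizes(peaks, library_sizes)
  if (threshold <= 0) return(peaks)
  rpm <- rpm_matrix(peaks, library_sizes)
  keep <- rowSums(rpm < threshold) == 0L
  peaks[keep, ]
}

check_library_sizes <- function(peaks, library_sizes) {
  if (is.null(names(library_sizes)) || any(!nzchar(names(library_sizes)))) {
    rlang::abort("`library_sizes` must be named after the replicate count columns")
  }
  missing <- setdiff(names(library_sizes), names(peaks))
  if (length(missing)) {
    rlang::abort(paste0("count column(s) missing from peaks: ",
                        paste(missing, collapse = ", ")))
  }
  if (any(library_sizes <= 0)) rlang::abort("library sizes must be positive")
  invisible(TRUE)
}

rpm_matrix <- function(peaks, library_sizes) {
  counts <- as.matrix(as.data.frame(peaks)[, names(library_sizes), drop = FALSE])
  sweep(counts, 2, library_sizes, "/") * 1e6
}

#' Replicate reproducibility of peak signal
#'
#' Pearson correlation of log10(RPM + pseudocount) for every pair of
#' replicates, the statistic behind a replicate-concordance scatter plot.
#'
#' @inheritParams filter_peaks_rpm
#' @param pseudocount Added to RPM before log10 (default 0.01 RPM), so that
#'   zero-count peaks remain usable.
#' @return Tibble `rep_a`, `rep_b`, `r`, `n_peaks`.
#' @export
replicate_concordance <- function(peaks, library_sizes, pseudocount = 0.01) {
  peaks <- tibble::as_tibble(peaks)
  check_library_sizes(peaks, library_sizes)
  if (length(library_sizes) < 2L) {
    rlang::abort("need at least two replicates for concordance")
  }
  lg <- log10(rpm_matrix(peaks, library_sizes) + pseudocount)
  pairs <- utils::combn(names(library_sizes), 2)
  tibble::tibble(
    rep_a = pairs[1, ],
    rep_b = pairs[2, ],
    r = apply(pairs, 2, function(p) stats::cor(lg[, p[1]], lg[, p[2]])),
    n_peaks = nrow(peaks)
  )
}

#' Classify intervals relative to the nearest gene TSS
#'
#' Each interval is assigned a nearest gene and a region class.  An interval
#' overlapping a gene body is `gene_body` for that gene.  Otherwise the
#' nearest gene is chosen by distance between the interval and the TSS (0 if
#' the TSS lies in the interval, else the gap to the nearer edge; ties broken
#' by the lexicographically smaller `gene_id`), and the interval is
#' `tss_proximal` if it lies within `proximal_bp` upstream of that TSS
#' (boundary inclusive), `tss_distal` if upstream-intergenic beyond
#' `proximal_bp`, and `other` if downstream of the gene (or on a chromosome
#' absent from the annotation, with a warning).  Upstream is strand-aware:
#' upstream of a minus-strand gene lies at larger coordinates.
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param genes Gene table from [gene_table()] (columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`).
#' @param proximal_bp Width of the proximal upstream window (default 1500).
#' @return The input tibble with added columns `nearest_gene`,
#'   `tss_distance` and `region_class`
#'   (factor: tss_proximal/tss_distal/gene_body/other).
#' @export
classify_intervals <- function(intervals, genes, proximal_bp = 1500) {
  intervals <- tibble::as_tibble(intervals)
  genes <- tibble::as_tibble(genes)
  n <- nrow(intervals)
  nearest_gene <- rep(NA_character_, n)
  tss_distance <- rep(NA_real_, n)
  region_class <- rep("other", n)

  known <- intervals$chrom %in% genes$chrom
  if (any(!known)) {
    rlang::warn(paste0(sum(!known), " interval(s) on chromosomes absent from",
                       " the annotation classified as 'other'"))
  }
  for (cm in unique(intervals$chrom[known])) {
    ii <- which(intervals$chrom == cm)
    gg <- genes[genes$chrom == cm, ]
    s <- intervals$start[ii]; e <- intervals$end[ii]
    # distance of every interval (rows) to every TSS (columns) on this chromosome
    dmat <- outer(-e, gg$tss, "+")               # tss - end
    dmat[] <- pmax(dmat, outer(s, -gg$tss, "+"), 0)
    # gene-body overlap
    omat <- outer(e, gg$start, ">") & outer(s, gg$end, "<")
    for (k in seq_along(ii)) {
      if (any(omat[k, ])) {
        cand <- which(omat[k, ])
        cls <- "gene_body"
      } else {
        cand <- which(dmat[k, ] == min(dmat[k, ]))
        cls <- NA_character_
      }
      # deterministic tie-break: nearest TSS, then smaller gene_id
      cand <- cand[order(dmat[k, cand], gg$gene_id[cand])][1]
      g <- gg[cand, ]
      if (is.na(cls)) {
        upstream <- if (g$strand == "+") e[k] <= g$tss else s[k] >= g$tss
        d_up <- if (g$strand == "+") g$tss - e[k] else s[k] - g$tss
        cls <- if (!upstream) "other"
        else if (d_up <= proximal_bp) "tss_proximal"
        else "tss_distal"
      }
      nearest_gene[ii[k]] <- g$gene_id
      tss_distance[ii[k]] <- dmat[k, cand]
      region_class[ii[k]] <- cls
    }
  }
  intervals$nearest_gene <- nearest_gene
  intervals$tss_distance <- tss_distance
  intervals$region_class <- factor(
    region_class, levels = c("tss_proximal", "tss_distal", "gene_body", "other"))
  intervals
}

#' Per-gene presence of proximal and distal peaks
#'
#' Summarises classified intervals gene-wise: whether the gene has at least
#' one TSS-proximal peak, at least one TSS-distal peak, and both.
#'
#' @param classified Output of [classify_intervals()].
#' @param genes Gene table; every gene gets a row even without peaks.
#' @return Tibble `gene_id`, `has_proximal`, `has_distal`, `both`.
#' @export
gene_region_presence <- function(classified, genes) {
  flags <- classified |>
    dplyr::filter(!is.na(.data$nearest_gene)) |>
    dplyr::summarise(
      has_proximal = any(.data$region_class == "tss_proximal"),
      has_distal = any(.data$region_class == "tss_distal"),
      .by = "nearest_gene"
    )
  tibble::tibble(gene_id = genes$gene_id) |>
    dplyr::left_join(flags, by = c(gene_id = "nearest_gene")) |>
    dplyr::mutate(
      has_proximal = dplyr::coalesce(.data$has_proximal, FALSE),
      has_distal = dplyr::coalesce(.data$has_distal, FALSE),
      both = .data$has_proximal & .data$has_distal
    ) |>
    dplyr::arrange(.data$gene_id)
}

#' Enrichment of region classes in age groups over the background
#'
#' For each age group and region flag, the observed percentage of group genes
#' carrying the flag is compared with the expected percentage — the
#' percentage among all aged genes — and reported as a ratio.  Both
#' components are returned so alternative backgrounds can be recomputed.
#'
#' @param presence Per-gene flags from [gene_region_presence()].
#' @param ages Gene ages with `age_group` (from [age_groups()]).
#' @param groups Age groups to report (default old and young).
#' @return Tibble `age_group`, `region`, `n_genes`, `n_with`, `observed_pct`,
#'   `expected_pct`, `ratio` (`NA` where the background percentage is 0).
#' @export
enrichment_by_age <- function(presence, ages, groups = c("old", "young")) {
  joined <- tibble::as_tibble(ages) |>
    dplyr::inner_join(presence, by = "gene_id")
  if (!nrow(joined)) rlang::abort("no aged genes with presence flags")
  long <- joined |>
    tidyr::pivot_longer(c("has_proximal", "has_distal", "both"),
                        names_to = "region", values_to = "flag") |>
    dplyr::mutate(region = factor(
      sub("^has_", "", .data$region),
      levels = c("proximal", "distal", "both")))
  background <- long |>
    dplyr::summarise(expected_pct = 100 * mean(.data$flag), .by = "region")
  out <- long |>
    dplyr::filter(.data$age_group %in% groups) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_with = sum(.data$flag),
      observed_pct = 100 * mean(.data$flag),
      .by = c("age_group", "region")
    ) |>
    dplyr::left_join(background, by = "region") |>
    dplyr::mutate(ratio = ifelse(.data$expected_pct > 0,
                                 .data$observed_pct / .data$expected_pct,
                                 NA_real_)) |>
    dplyr::arrange(.data$age_group, .data$region)
  if (!all(groups %in% as.character(out$age_group))) {
    rlang::abort("empty age group in enrichment_by_age")
  }
  out
}

#' Overlap between two interval sets
#'
#' An element overlaps when it intersects at least `min_overlap` bp with any
#' element of the other set.  Reports the counts and fractions needed for a
#' Venn-style summary (e.g. the fraction of enhancers covered by open
#' chromatin).
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based half-open).
#' @param min_overlap Minimum intersection in bp (default 1).
#' @return Tibble with one row: `n_a`, `n_b`, `a_overlapping`,
#'   `b_overlapping`, `a_only`, `b_only`, `frac_a_overlapping`,
#'   `frac_b_overlapping`.
#' @export
overlap_sets <- function(a, b, min_overlap = 1) {
  gra <- as_granges(tibble::as_tibble(a))
  grb <- as_granges(tibble::as_tibble(b))
  a_hit <- GenomicRanges::countOverlaps(gra, grb, minoverlap = min_overlap) > 0
  b_hit <- GenomicRanges::countOverlaps(grb, gra, minoverlap = min_overlap) > 0
  tibble::tibble(
    n_a = length(gra), n_b = length(grb),
    a_overlapping = sum(a_hit), b_overlapping = sum(b_hit),
    a_only = sum(!a_hit), b_only = sum(!b_hit),
    frac_a_overlapping = mean(a_hit),
    frac_b_overlapping = mean(b_hit)
  )
}

#' Age of the nearest gene by enhancer region class
#'
#' For intervals classified with [classify_intervals()], joins the nearest
#' gene's phylostratum and summarises the age distribution per region class.
#'
#' @param classified Output of [classify_intervals()].
#' @param ages Gene age table (`gene_id`, `phylostratum`).
#' @return Tibble `region_class`, `n`, `median_age`, `mean_age`, `ages`
#'   (list column with the individual nearest-gene strata).
#' @export
nearest_gene_age_by_class <- function(classified, ages) {
  classified |>
    dplyr::filter(!is.na(.data$nearest_gene)) |>
    dplyr::inner_join(tibble::as_tibble(ages)[, c("gene_id", "phylostratum")],
                      by = c(nearest_gene = "gene_id")) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_age = stats::median(.data$phylostratum),
      mean_age = mean(.data$phylostratum),
      ages = list(.data$phylostratum),
      .by = "region_class"
    ) |>
    dplyr::arrange(.data$region_class)
}

#' Metagene coverage profile around TSSs
#'
#' Extracts the coverage signal over a window of `± window` bp around every
#' TSS, oriented 5' to 3' (minus-strand windows are reversed), averages it in
#' bins of `binsize` bp, and returns group-mean profiles.  The track is first
#' normalized so that its genome-wide mean signal is 1 (per-base mean over
#' the track's span); genes whose window extends past a chromosome edge are
#' skipped and counted.
#'
#' @param track Coverage tibble `chrom`, `start`, `end`, `value` (run-length
#'   intervals, 0-based half-open), e.g. from [read_bedgraph()].
#' @param anchors Tibble with `gene_id`, `chrom`, `strand`, `tss` and
#'   optionally a grouping column named by `group`; without one, a single
#'   group `all` is profiled.
#' @param window Half-window in bp (default 2000).
#' @param binsize Bin width in bp (default 50); must divide `window`.
#' @param group Name of the grouping column in `anchors` (default
#'   `"age_group"` when present).
#' @param normalize Scale the track to genome-wide mean 1 (default `TRUE`).
#' @return A `metagene_profile` tibble: `group`, `bin_center` (nt relative to
#'   the TSS), `mean_coverage`, `n_genes`; attributes `window`, `binsize`,
#'   `n_skipped`, `normalizer`.
#' @export
metagene <- function(track, anchors, window = 2000, binsize = 50,
                     group = NULL, normalize = TRUE) {
  if (window %% binsize != 0) rlang::abort("`window` must be a multiple of `binsize`")
  anchors <- tibble::as_tibble(anchors)
  if (is.null(group)) group <- if ("age_group" %in% names(anchors)) "age_group" else NULL
  grp <- if (is.null(group)) rep("all", nrow(anchors)) else as.character(anchors[[group]])

  cov <- track_coverage(track)
  normalizer <- if (normalize) {
    sum(vapply(cov, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                      S4Vectors::runLength(r)), numeric(1))) /
      sum(vapply(cov, length, numeric(1)))
  } else 1
  if (normalizer <= 0) rlang::abort("track has zero mean signal; cannot normalize")

  n_bins <- 2L * window %/% binsize
  centers <- seq(-window + binsize / 2, window - binsize / 2, by = binsize)
  ok <- anchors$chrom %in% names(cov) &
    anchors$tss - window >= 0 &
    anchors$tss + window <= vapply(anchors$chrom, function(cm)
      if (cm %in% names(cov)) length(cov[[cm]]) else 0L, numeric(1))
  n_skipped <- sum(!ok)
  if (!any(ok)) rlang::abort("no usable TSS windows within the track span")

  profiles <- matrix(NA_real_, nrow = sum(ok), ncol = n_bins)
  used <- which(ok)
  row <- 1L
  for (cm in unique(anchors$chrom[used])) {
    idx <- used[anchors$chrom[used] == cm]
    v <- IRanges::Views(cov[[cm]],
                        start = anchors$tss[idx] - window + 1L,
                        width = 2L * window)
    m <- as.matrix(v)                      # genes x positions
    minus <- anchors$strand[idx] == "-"
    if (any(minus)) m[minus, ] <- m[minus, ncol(m):1, drop = FALSE]
    # bin-average: reshape positions into binsize x n_bins
    binned <- t(apply(m, 1, function(x) colMeans(matrix(x, nrow = binsize))))
    profiles[row:(row + length(idx) - 1L), ] <- binned
    grp_rows <- grp[idx]
    if (row == 1L) grp_used <- grp_rows else grp_used <- c(grp_used, grp_rows)
    row <- row + length(idx)
  }
  profiles <- profiles / normalizer

  out <- tibble::tibble(
    group = rep(grp_used, times = n_bins),
    bin_center = rep(centers, each = nrow(profiles)),
    value = as.vector(profiles)
  ) |>
    dplyr::summarise(mean_coverage = mean(.data$value),
                     n_genes = dplyr::n(),
                     .by = c("group", "bin_center")) |>
    dplyr::arrange(.data$group, .data$bin_center)
  structure(out, class = c("metagene_profile", class(out)),
            window = window, binsize = binsize,
            n_skipped = n_skipped, normalizer = normalizer)
}

# coverage tibble -> RleList keyed by chromosome
track_coverage <- function(track) {
  track <- tibble::as_tibble(track)
  if (any(track$value < 0)) rlang::abort("coverage values must be non-negative")
  gr <- as_granges(track)
  GenomicRanges::coverage(gr, weight = track$value)
}
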