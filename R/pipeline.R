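#' Pipeline configuration
#'
#' Collects the input file paths and every analysis parameter for
#' [run_pipeline()].  File names default to the layout written by
#' [write_dataset()]; any path can be overridden.  Coverage conditions and
#' expression genotypes are discovered from `coverage_<condition>.bedGraph`
#' and `expression_<genotype>.tsv` files in `data_dir` (sorted, control
#' first).
#'
#' @param data_dir Directory holding the input files.
#' @param focal_species Focal leaf name in the species tree.
#' @param proximal_bp TSS-proximal window in bp (default 1500).
#' @param window,binsize Metagene half-window and bin size in bp (2000, 50).
#' @param rpm_threshold Peak RPM filter threshold (default 1).
#' @param utr_thresh,ejc_thresh NMD rule thresholds in nt (350, 50).
#' @param old_strata,young_strata Strata defining the old and young groups;
#'   `young_strata = NULL` means the deepest stratum found in the lineage.
#' @param pseudocount TPM/RPM pseudocount (default 0.01).
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @param paths Optional named list overriding individual input paths
#'   (`tree`, `hits`, `protein_map`, `gff3`, `peaks_bed`, `peak_counts`,
#'   `library_sizes`, `enhancers_bed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir,
                            focal_species = "focal_sp",
                            proximal_bp = 1500,
                            window = 2000,
                            binsize = 50,
                            rpm_threshold = 1,
                            utr_thresh = 350,
                            ejc_thresh = 50,
                            old_strata = 1L,
                            young_strata = NULL,
                            pseudocount = 0.01,
                            seed = 1L,
                            paths = list()) {
  stopifnot(proximal_bp > 0, window > 0, binsize > 0,
            rpm_threshold >= 0, utr_thresh > 0, ejc_thresh > 0,
            pseudocount > 0)
  defaults <- list(
    tree = "species_tree.nwk", hits = "hits.tsv",
    protein_map = "protein_map.tsv", gff3 = "annotation.gff3",
    peaks_bed = "peaks.bed", peak_counts = "peak_counts.tsv",
    library_sizes = "library_sizes.tsv", enhancers_bed = "enhancers.bed"
  )
  defaults[names(paths)] <- paths
  files <- lapply(defaults, function(f)
    if (grepl("^/", f)) f else file.path(data_dir, f))
  missing <- names(files)[!vapply(files, file.exists, logical(1))]
  if (length(missing)) {
    rlang::abort(paste0("missing input file(s): ",
                        paste(unlist(files[missing]), collapse = ", ")))
  }
  covs <- sort(list.files(data_dir, "^coverage_.*\\.bedGraph$"))
  conds <- sub("^coverage_(.*)\\.bedGraph$", "\\1", covs)
  ord <- order(conds != "control", conds)
  files$coverage <- stats::setNames(file.path(data_dir, covs[ord]), conds[ord])
  exprs <- sort(list.files(data_dir, "^expression_.*\\.tsv$"))
  files$expression <- stats::setNames(
    file.path(data_dir, exprs),
    sub("^expression_(.*)\\.tsv$", "\\1", exprs))
  mets <- sort(list.files(data_dir, "^metric_.*\\.tsv$"))
  files$metrics <- stats::setNames(
    file.path(data_dir, mets), sub("^metric_(.*)\\.tsv$", "\\1", mets))
  structure(list(
    data_dir = data_dir, files = files, focal_species = focal_species,
    proximal_bp = proximal_bp, window = window, binsize = binsize,
    rpm_threshold = rpm_threshold, utr_thresh = utr_thresh,
    ejc_thresh = ejc_thresh, old_strata = old_strata,
    young_strata = young_strata, pseudocount = pseudocount, seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may set any argument of [pipeline_config()]; `data_dir` is
#' required (relative to the YAML file's directory unless absolute).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$data_dir)) rlang::abort("config must set data_dir")
  if (!grepl("^/", y$data_dir)) {
    y$data_dir <- file.path(dirname(path), y$data_dir)
  }
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                        conditionMessage(e)))
  })
}

#' Run the full age-stratified analysis pipeline
#'
#' Chains every module over the input files named in the configuration:
#' phylostratum assignment, NMD annotation and age-stratified feature
#' frequencies, peak RPM filtering and replicate concordance, TSS
#' proximal/distal classification and enrichment of peaks and enhancers,
#' peak-enhancer overlap, nearest-gene age by enhancer class, per-condition
#' metagene profiles, and the expression / half-life / NMD-response /
#' ribosome-association / monosome-shift group comparisons.  Each result is
#' written as a TSV into `outdir` together with a run log; reruns on the
#' same inputs produce byte-identical TSVs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list with every intermediate result.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(outdir, ...)
  res <- list(config = config)
  f <- config$files

  ## gene ages ---------------------------------------------------------------
  lineage <- stage("lineage", phylo_lineage(f$tree, config$focal_species))
  young_strata <- config$young_strata %||% lineage$n_strata
  hits <- stage("hits", read_hit_table(f$hits))
  protein_map <- stage("protein_map", readr::read_tsv(
    f$protein_map, col_types = readr::cols(.default = readr::col_character())))
  protein_ages <- stage("assign_phylostratum",
                        assign_phylostratum(hits, lineage,
                                            proteins = protein_map$protein_id))
  ages <- stage("gene_ages", gene_ages(protein_ages, protein_map))
  ages <- stage("age_groups",
                age_groups(ages, old_strata = config$old_strata,
                           young_strata = young_strata))
  readr::write_tsv(ages[, c("gene_id", "phylostratum", "age_group")],
                   out("gene_ages.tsv"))
  res$lineage <- lineage; res$ages <- ages

  ## annotation and NMD ------------------------------------------------------
  tx <- stage("read_gff3", read_gff3(f$gff3))
  genes <- stage("gene_table", gene_table(tx))
  nmd <- stage("classify_nmd",
               classify_nmd(tx[tx$coding, ], utr_thresh = config$utr_thresh,
                            ejc_thresh = config$ejc_thresh))
  readr::write_tsv(nmd, out("nmd_annotation.tsv"))
  nmd_freq <- stage("nmd_frequency", nmd_frequency_by_age(nmd, ages))
  readr::write_tsv(nmd_freq, out("nmd_frequency.tsv"))
  res$transcripts <- tx; res$genes <- genes
  res$nmd <- nmd; res$nmd_freq <- nmd_freq

  ## peaks -------------------------------------------------------------------
  lib_tbl <- stage("library_sizes", readr::read_tsv(
    f$library_sizes, col_types = readr::cols(
      replicate = readr::col_character(),
      library_size = readr::col_double())))
  library_sizes <- stats::setNames(lib_tbl$library_size, lib_tbl$replicate)
  peaks <- stage("peaks", {
    bed <- read_bed(f$peaks_bed)
    counts <- readr::read_tsv(f$peak_counts, col_types = readr::cols(
      name = readr::col_character(), .default = readr::col_double()))
    dplyr::inner_join(bed, counts, by = "name")
  })
  concordance <- stage("replicate_concordance",
                       replicate_concordance(peaks, library_sizes,
                                             pseudocount = config$pseudocount))
  readr::write_tsv(concordance, out("replicate_concordance.tsv"))
  filtered <- stage("filter_peaks_rpm",
                    filter_peaks_rpm(peaks, library_sizes,
                                     threshold = config$rpm_threshold))
  readr::write_tsv(filtered, out("filtered_peaks.tsv"))
  res$peaks <- peaks; res$filtered_peaks <- filtered
  res$concordance <- concordance

  ## region classification and enrichment ------------------------------------
  peak_cls <- stage("classify_peaks",
                    classify_intervals(filtered, genes,
                                       proximal_bp = config$proximal_bp))
  readr::write_tsv(
    peak_cls[, c("chrom", "start", "end", "name", "nearest_gene",
                 "tss_distance", "region_class")],
    out("peak_classes.tsv"))
  presence <- stage("gene_region_presence",
                    gene_region_presence(peak_cls, genes))
  readr::write_tsv(presence, out("gene_region_flags.tsv"))
  peak_enrich <- stage("peak_enrichment", enrichment_by_age(presence, ages))
  readr::write_tsv(peak_enrich, out("peak_enrichment.tsv"))
  res$peak_classes <- peak_cls; res$presence <- presence
  res$peak_enrichment <- peak_enrich

  enh <- stage("enhancers", read_bed(f$enhancers_bed))
  enh_cls <- stage("classify_enhancers",
                   classify_intervals(enh, genes,
                                      proximal_bp = config$proximal_bp))
  readr::write_tsv(
    enh_cls[, c("chrom", "start", "end", "name", "nearest_gene",
                "tss_distance", "region_class")],
    out("enhancer_classes.tsv"))
  enh_presence <- stage("enhancer_presence",
                        gene_region_presence(enh_cls, genes))
  enh_enrich <- stage("enhancer_enrichment",
                      enrichment_by_age(enh_presence, ages))
  readr::write_tsv(enh_enrich, out("enhancer_enrichment.tsv"))
  venn <- stage("overlap", overlap_sets(filtered, enh))
  readr::write_tsv(venn, out("overlap_venn.tsv"))
  age_by_class <- stage("nearest_gene_age",
                        nearest_gene_age_by_class(enh_cls, ages))
  readr::write_tsv(dplyr::select(age_by_class, -"ages"),
                   out("enhancer_age_by_class.tsv"))
  res$enhancer_classes <- enh_cls; res$enhancer_enrichment <- enh_enrich
  res$overlap <- venn; res$age_by_class <- age_by_class

  ## metagene profiles per condition -----------------------------------------
  anchors <- dplyr::inner_join(
    genes[, c("gene_id", "chrom", "strand", "tss")],
    ages[, c("gene_id", "age_group")], by = "gene_id")
  res$metagene <- list()
  for (cond in names(f$coverage)) {
    track <- stage(paste0("coverage_", cond), read_bedgraph(f$coverage[[cond]]))
    prof <- stage(paste0("metagene_", cond),
                  metagene(track, anchors, window = config$window,
                           binsize = config$binsize))
    readr::write_tsv(prof, out(sprintf("metagene_%s.tsv", cond)))
    res$metagene[[cond]] <- prof
  }

  ## group comparisons -------------------------------------------------------
  comparisons <- list()
  exprs <- lapply(f$expression, read_expression)
  if (length(exprs) >= 1L) {
    wt_name <- if ("wild_type" %in% names(exprs)) "wild_type" else names(exprs)[1]
    comparisons$expression <- stage("compare_expression",
      compare_expression(exprs[[wt_name]], ages,
                         pseudocount = config$pseudocount))
    mut <- setdiff(names(exprs), wt_name)
    if (length(mut)) {
      comparisons$nmd_response <- stage("relative_change",
        relative_change(exprs[[wt_name]], exprs[[mut[1]]], ages,
                        pseudocount = config$pseudocount))
    }
  }
  if ("half_life" %in% names(f$metrics)) {
    comparisons$half_life <- stage("half_life",
      compare_metric(read_metric(f$metrics[["half_life"]]), ages,
                     transform = "log10", label = "mRNA half-life"))
  }
  if ("trap" %in% names(f$metrics)) {
    comparisons$trap <- stage("trap",
      compare_metric(read_metric(f$metrics[["trap"]]), ages,
                     label = "TRAP ribosome association"))
  }
  if (length(comparisons)) {
    readr::write_tsv(dplyr::bind_rows(lapply(comparisons, glance)),
                     out("group_comparisons.tsv"))
  }
  if (all(c("monosome_control", "monosome_null") %in% names(f$metrics))) {
    res$monosome <- stage("monosome_shift",
      monosome_shift(read_metric(f$metrics[["monosome_control"]]),
                     read_metric(f$metrics[["monosome_null"]]), ages))
    readr::write_tsv(res$monosome, out("monosome_shift.tsv"))
  }
  res$comparisons <- comparisons

  ## run log -----------------------------------------------------------------
  writeLines(c(
    paste0("genage version: ",
           as.character(utils::packageVersion("genage"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("data_dir: ", config$data_dir),
    sprintf("parameters: proximal_bp=%s window=%s binsize=%s rpm_threshold=%s utr_thresh=%s ejc_thresh=%s old_strata=%s young_strata=%s pseudocount=%s",
            config$proximal_bp, config$window, config$binsize,
            config$rpm_threshold, config$utr_thresh, config$ejc_thresh,
            paste(config$old_strata, collapse = ","),
            paste(young_strata, collapse = ","), config$pseudocount),
    paste0("conditions: ", paste(names(f$coverage), collapse = ", ")),
    paste0("n_genes: ", nrow(genes)),
    paste0("n_peaks: ", nrow(peaks), " (", nrow(filtered), " after RPM filter)")
  ), out("run_log.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
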