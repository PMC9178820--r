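#' Build the focal-species lineage from a species tree
#'
#' A phylostratigraphic lineage is the ordered series of nested clades on the
#' path from the root of a rooted species tree down to a focal leaf.  Clade 1
#' is the root clade (all species), clade `S` is the focal species alone, and
#' `S` is the number of phylostrata available for age assignment.
#'
#' @param tree A rooted tree: an [ape::phylo] object, a newick string, or the
#'   path to a newick file.  Quoted labels are supported by the newick reader.
#' @param focal_species Name of the focal leaf.
#'
#' @return An object of class `phylo_lineage`: a list with elements
#'   `clades` (list of character vectors, root first), `focal_species`,
#'   `n_strata`, and `strata` (named integer vector giving, for every species
#'   in the tree, the deepest clade index that still contains it).
#'
#' @details Polytomies are allowed; strata count nodes on the root-to-focal
#'   path, ignoring branch lengths.  A tree with a single leaf yields a
#'   lineage of length 1.
#'
#' @examples
#' lin <- phylo_lineage("((A,B),(C,focal));", "focal")
#' lin$n_strata            # 3
#' species_stratum(lin, c("A", "C", "focal"))
#' @export
phylo_lineage <- function(tree, focal_species) {
  phy <- as_phylo_tree(tree)
  tips <- phy$tip.label
  if (anyDuplicated(tips)) {
    rlang::abort("species tree has duplicated leaf names")
  }
  if (!focal_species %in% tips) {
    rlang::abort(paste0("focal species '", focal_species,
                        "' is not a leaf of the tree"))
  }
  if (length(tips) == 1L) {
    return(new_phylo_lineage(list(tips), focal_species))
  }
  focal_idx <- match(focal_species, tips)
  root <- length(tips) + 1L
  path <- ape::nodepath(phy, from = root, to = focal_idx)
  clades <- lapply(path, function(node) {
    if (node <= length(tips)) tips[node] else sort(descendant_tips(phy, node))
  })
  new_phylo_lineage(clades, focal_species)
}

# tips under an internal node, by edge traversal (handles polytomies)
descendant_tips <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  children <- phy$edge[, 2][phy$edge[, 1] == node]
  out <- character(0)
  while (length(children)) {
    is_tip <- children <= n_tip
    out <- c(out, phy$tip.label[children[is_tip]])
    internal <- children[!is_tip]
    children <- phy$edge[, 2][phy$edge[, 1] %in% internal]
  }
  out
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    txt <- if (file.exists(tree)) paste(readLines(tree), collapse = "") else tree
    phy <- ape::read.tree(text = txt)
    if (is.null(phy)) rlang::abort("could not parse newick tree")
    return(phy)
  }
  rlang::abort("`tree` must be a phylo object, newick string, or file path")
}

new_phylo_lineage <- function(clades, focal_species) {
  stopifnot(length(clades) >= 1L)
  all_sp <- clades[[1L]]
  strata <- vapply(all_sp, function(sp) {
    max(which(vapply(clades, function(cl) sp %in% cl, logical(1))))
  }, integer(1))
  structure(
    list(clades = clades, focal_species = focal_species,
         n_strata = length(clades), strata = strata),
    class = "phylo_lineage"
  )
}

#' @export
print.phylo_lineage <- function(x, ...) {
  cat("<phylo_lineage> focal species:", x$focal_species,
      "| strata:", x$n_strata, "\n")
  sizes <- vapply(x$clades, length, integer(1))
  cat("clade sizes (root -> focal):", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Stratum at which a species diverges from the focal lineage
#'
#' Returns, for each species, the largest lineage index `i` such that the
#' species belongs to clade `i` — the phylostratum a best hit in that species
#' supports.  The focal species itself maps to `S`, the most distant outgroups
#' map to 1.
#'
#' @param lineage A [phylo_lineage()] object.
#' @param species Character vector of species names.
#' @return Integer vector of strata, same length as `species`.
#' @export
species_stratum <- function(lineage, species) {
  stopifnot(inherits(lineage, "phylo_lineage"))
  unknown <- setdiff(unique(species), names(lineage$strata))
  if (length(unknown)) {
    rlang::abort(paste0("unknown species: ",
                        paste(unknown, collapse = ", ")))
  }
  unname(lineage$strata[species])
}

#' Assign phylostrata to proteins by the deepest-clade rule
#'
#' Each protein is assigned the phylostratum of the deepest (most basal)
#' lineage clade containing a species with a best hit, i.e. the minimum of
#' [species_stratum()] over its hit species.  Proteins with no hits at all are
#' assigned stratum `S` (the evolutionary youngest class).
#'
#' @param hits A data frame with columns `protein_id` and `subject_species`,
#'   one row per best hit.  Proteins may appear in `proteins` but not in
#'   `hits`; those have empty hit sets.
#' @param lineage A [phylo_lineage()] object.
#' @param proteins Optional character vector giving the full protein universe;
#'   defaults to the proteins present in `hits`.
#'
#' @return A tibble with columns `protein_id`, `phylostratum`, `n_hits`.
#' @export
assign_phylostratum <- function(hits, lineage, proteins = NULL) {
  stopifnot(inherits(lineage, "phylo_lineage"))
  hits <- tibble::as_tibble(hits)
  if (!all(c("protein_id", "subject_species") %in% names(hits))) {
    rlang::abort("`hits` needs columns protein_id and subject_species")
  }
  if (is.null(proteins)) proteins <- unique(hits$protein_id)
  s_max <- lineage$n_strata
  if (nrow(hits) == 0L) {
    return(tibble::tibble(protein_id = proteins,
                          phylostratum = rep(s_max, length(proteins)),
                          n_hits = 0L))
  }
  scored <- hits |>
    dplyr::mutate(.stratum = species_stratum(lineage, .data$subject_species)) |>
    dplyr::summarise(
      phylostratum = min(.data$.stratum),
      n_hits = dplyr::n(),
      .by = "protein_id"
    )
  tibble::tibble(protein_id = proteins) |>
    dplyr::left_join(scored, by = "protein_id") |>
    dplyr::mutate(
      phylostratum = as.integer(dplyr::coalesce(.data$phylostratum, s_max)),
      n_hits = dplyr::coalesce(.data$n_hits, 0L)
    )
}

#' Aggregate protein phylostrata to gene ages
#'
#' A gene's age is the oldest (minimum) stratum among its isoform proteins:
#' a single ancient homolog of any isoform establishes ancestry of the gene.
#'
#' @param protein_ages A data frame with columns `protein_id`,
#'   `phylostratum` (e.g. from [assign_phylostratum()]).
#' @param protein_to_gene A data frame with columns `protein_id`, `gene_id`
#'   mapping every protein to exactly one gene.
#' @return A tibble with columns `gene_id`, `phylostratum`, `n_proteins`.
#' @export
gene_ages <- function(protein_ages, protein_to_gene) {
  protein_ages <- tibble::as_tibble(protein_ages)
  protein_to_gene <- tibble::as_tibble(protein_to_gene)
  orphans <- setdiff(protein_ages$protein_id, protein_to_gene$protein_id)
  if (length(orphans)) {
    rlang::abort(paste0("proteins without a gene mapping: ",
                        paste(utils::head(orphans, 10), collapse = ", "),
                        if (length(orphans) > 10) " ..."))
  }
  if (anyDuplicated(protein_to_gene$protein_id)) {
    rlang::abort("each protein must map to exactly one gene")
  }
  protein_ages |>
    dplyr::inner_join(protein_to_gene[, c("protein_id", "gene_id")],
                      by = "protein_id") |>
    dplyr::summarise(
      phylostratum = min(.data$phylostratum),
      n_proteins = dplyr::n(),
      .by = "gene_id"
    ) |>
    dplyr::arrange(.data$gene_id)
}

#' Partition genes into old / young / other age groups
#'
#' @param ages A data frame with columns `gene_id`, `phylostratum`.
#' @param old_strata,young_strata Disjoint sets of strata defining the old and
#'   young groups (the reference analysis uses old = PS1, young = PS_max).
#' @return The input with an added factor column `age_group`
#'   (levels old/young/other); group counts are attached as attribute
#'   `group_counts` and printed groupwise by `dplyr::count()`.
#' @export
age_groups <- function(ages, old_strata = 1L, young_strata) {
  ages <- tibble::as_tibble(ages)
  if (length(intersect(old_strata, young_strata))) {
    rlang::abort("old_strata and young_strata must be disjoint")
  }
  out <- ages |>
    dplyr::mutate(age_group = factor(
      dplyr::case_when(
        .data$phylostratum %in% old_strata ~ "old",
        .data$phylostratum %in% young_strata ~ "young",
        TRUE ~ "other"
      ),
      levels = c("old", "young", "other")
    ))
  counts <- table(out$age_group)
  if (counts[["old"]] == 0L || counts[["young"]] == 0L) {
    rlang::warn("empty old or young group; downstream group tests will refuse to run")
  }
  attr(out, "group_counts") <- counts
  out
}

#' Read a protein best-hit table from TSV
#'
#' Expects columns `protein_id` and `subject_species`, one row per best hit.
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_hit_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    subject_species = readr::col_character()
  ))
}

#' Write a gene-age table to TSV
#'
#' Emits one row per protein with columns `gene_id`, `protein_id`,
#' `phylostratum` (the gene-level stratum).
#' @param protein_ages Output of [assign_phylostratum()].
#' @param protein_to_gene `protein_id` to `gene_id` mapping.
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_age_table <- function(protein_ages, protein_to_gene, path) {
  genes <- gene_ages(protein_ages, protein_to_gene)
  out <- tibble::as_tibble(protein_to_gene)[, c("gene_id", "protein_id")] |>
    dplyr::inner_join(genes[, c("gene_id", "phylostratum")], by = "gene_id") |>
    dplyr::arrange(.data$gene_id, .data$protein_id)
  readr::write_tsv(out, path)
  invisible(out)
}
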