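#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Mann-Whitney / Wilcoxon policy: exact p-value for small tie-free samples,
# normal approximation with continuity and tie correction otherwise.
mw_test <- function(x, y, paired = FALSE) {
  # degenerate inputs (all values tied, or all paired differences zero) carry
  # no evidence against the null; report p = 1 rather than NaN
  degenerate <- if (paired) all(x == y) else length(unique(c(x, y))) == 1L
  if (degenerate) {
    stat <- if (paired) c(V = 0) else c(W = length(x) * length(y) / 2)
    return(structure(list(statistic = stat, p.value = 1,
                          method = "Wilcoxon (degenerate: all ties)",
                          alternative = "two.sided"),
                     class = "htest"))
  }
  n_min <- if (paired) length(x) else min(length(x), length(y))
  has_ties <- if (paired) {
    d <- x - y; d <- d[d != 0]; anyDuplicated(abs(d)) > 0 || length(d) < length(x)
  } else anyDuplicated(c(x, y)) > 0
  exact <- n_min <= 8 && !has_ties
  suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact,
                       correct = TRUE, alternative = "two.sided")
  )
}

new_age_comparison <- function(comparison, groups_tbl, test, extra = list()) {
  structure(
    c(list(comparison = comparison, groups = groups_tbl, test = test), extra),
    class = "age_comparison"
  )
}

#' @export
print.age_comparison <- function(x, ...) {
  cat("<age_comparison>", x$comparison, "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy an age-group comparison
#'
#' @param x An `age_comparison` object.
#' @param ... Unused.
#' @return One row per group: `group`, `n`, `median`.
#' @method tidy age_comparison
#' @export
tidy.age_comparison <- function(x, ...) x$groups

#' One-row summary of an age-group comparison
#'
#' @param x An `age_comparison` object.
#' @param ... Unused.
#' @return Tibble with `comparison`, `statistic` (Mann-Whitney U or Wilcoxon
#'   V), `p_value`, `direction` (sign of young median minus old median:
#'   "young_higher", "young_lower" or "none") and group sizes.
#' @method glance age_comparison
#' @export
glance.age_comparison <- function(x, ...) {
  g <- x$groups
  med <- stats::setNames(g$median, g$group)
  diff <- unname(med["young"] - med["old"])
  tibble::tibble(
    comparison = x$comparison,
    statistic = unname(x$test$statistic),
    p_value = x$test$p.value,
    direction = if (is.na(diff) || diff == 0) "none"
                else if (diff > 0) "young_higher" else "young_lower",
    median_diff = diff,
    n_old = g$n[g$group == "old"],
    n_young = g$n[g$group == "young"]
  )
}

# shared worker: per-gene values -> old/young Mann-Whitney comparison
compare_groups <- function(values, label, extra = list()) {
  values <- values[values$age_group %in% c("old", "young"), ]
  split_vals <- split(values$value, droplevels(values$age_group))
  if (length(split_vals) < 2L || any(vapply(split_vals, length, 1L) < 2L)) {
    rlang::abort(paste0("need at least 2 genes in each of the old and young",
                        " groups for '", label, "'"))
  }
  old <- split_vals[["old"]]; young <- split_vals[["young"]]
  groups_tbl <- tibble::tibble(
    group = c("old", "young"),
    n = c(length(old), length(young)),
    median = c(stats::median(old), stats::median(young))
  )
  test <- mw_test(young, old)
  new_age_comparison(label, groups_tbl, test,
                     c(list(values = values), extra))
}

join_ages <- function(per_gene, ages) {
  ages <- tibble::as_tibble(ages)
  if (!"age_group" %in% names(ages)) {
    rlang::abort("`ages` must carry an age_group column (see age_groups())")
  }
  dplyr::inner_join(per_gene, ages[, c("gene_id", "age_group")], by = "gene_id")
}

#' Compare expression between old and young genes
#'
#' Per-gene expression is the mean TPM over the selected samples,
#' log10-transformed after adding a pseudocount; old and young groups are
#' compared with a two-sided Mann-Whitney test.
#'
#' @param expr Data frame with `gene_id` and one numeric TPM column per
#'   sample.
#' @param ages Gene ages with `age_group` (from [age_groups()]).
#' @param samples Character vector of sample columns (default: all numeric
#'   columns).
#' @param transform `"log10"` (default) or `"identity"`.  A monotone
#'   transform does not change the rank test, only the reported medians.
#' @param pseudocount Added to TPM before log10 (default 0.01).
#' @return An `age_comparison` object; see [tidy.age_comparison()] and
#'   [glance.age_comparison()].
#' @export
compare_expression <- function(expr, ages, samples = NULL,
                               transform = c("log10", "identity"),
                               pseudocount = 0.01) {
  transform <- match.arg(transform)
  expr <- tibble::as_tibble(expr)
  if (is.null(samples)) {
    samples <- names(expr)[vapply(expr, is.numeric, logical(1))]
    samples <- setdiff(samples, c("phylostratum"))
  }
  if (pseudocount <= 0 && transform == "log10") {
    rlang::abort("pseudocount must be positive for the log10 transform")
  }
  per_gene <- tibble::tibble(
    gene_id = expr$gene_id,
    value = rowMeans(as.data.frame(expr)[, samples, drop = FALSE])
  )
  if (transform == "log10") per_gene$value <- log10(per_gene$value + pseudocount)
  compare_groups(join_ages(per_gene, ages),
                 paste0("expression (", transform, " mean TPM)"))
}

#' Compare the expression response to a perturbation between age groups
#'
#' Computes per-gene log2((mutant + pc) / (wild type + pc)) from matched
#' expression tables (per-gene mean TPM over each table's samples) and
#' compares the ratios between old and young genes.  Genes absent from
#' either table are dropped to the intersection, with counts reported.
#'
#' @param expr_wt,expr_mut Expression tables as in [compare_expression()].
#' @param ages Gene ages with `age_group`.
#' @param pseudocount Added to both TPM values before the ratio (default
#'   0.01); when both values are 0 the ratio is exactly 0.
#' @return An `age_comparison`; element `n_dropped` counts genes outside the
#'   intersection of the two tables.
#' @export
relative_change <- function(expr_wt, expr_mut, ages, pseudocount = 0.01) {
  mean_tpm <- function(expr) {
    expr <- tibble::as_tibble(expr)
    samples <- setdiff(names(expr)[vapply(expr, is.numeric, logical(1))],
                       "phylostratum")
    tibble::tibble(gene_id = expr$gene_id,
                   tpm = rowMeans(as.data.frame(expr)[, samples, drop = FALSE]))
  }
  wt <- mean_tpm(expr_wt); mut <- mean_tpm(expr_mut)
  shared <- dplyr::inner_join(wt, mut, by = "gene_id",
                              suffix = c("_wt", "_mut"))
  n_dropped <- nrow(wt) + nrow(mut) - 2L * nrow(shared)
  per_gene <- tibble::tibble(
    gene_id = shared$gene_id,
    value = log2((shared$tpm_mut + pseudocount) / (shared$tpm_wt + pseudocount))
  )
  compare_groups(join_ages(per_gene, ages),
                 "relative change (log2 mutant/wild-type)",
                 extra = list(n_dropped = n_dropped))
}

#' Compare a per-gene metric between old and young genes
#'
#' Generic age-group comparison for per-gene metrics such as mRNA half-life,
#' TRAP ribosome association or monosome score.
#'
#' @param metric Data frame with `gene_id` and `value` (or a single other
#'   numeric column, taken as the metric).
#' @param ages Gene ages with `age_group`.
#' @param transform `"identity"` (default) or `"log10"`.
#' @param label Name of the metric for reporting.
#' @return An `age_comparison`.
#' @export
compare_metric <- function(metric, ages, transform = c("identity", "log10"),
                           label = "metric") {
  transform <- match.arg(transform)
  metric <- tibble::as_tibble(metric)
  if (!"value" %in% names(metric)) {
    num <- setdiff(names(metric)[vapply(metric, is.numeric, logical(1))],
                   "phylostratum")
    if (length(num) != 1L) rlang::abort("`metric` needs a `value` column")
    metric$value <- metric[[num]]
  }
  metric <- metric[is.finite(metric$value) | transform != "log10", ]
  per_gene <- metric[, c("gene_id", "value")]
  if (transform == "log10") {
    if (any(per_gene$value <= 0)) {
      rlang::abort("log10 transform requires positive metric values")
    }
    per_gene$value <- log10(per_gene$value)
  }
  compare_groups(join_ages(per_gene, ages),
                 paste0(label, " (", transform, ")"))
}

#' Paired within-group shift of a per-gene score between genotypes
#'
#' For each age group separately, compares a per-gene score (e.g. the
#' monosome score log2(monosome / polysome)) between a control and an
#' NMD-deficient genotype with a paired two-sided Wilcoxon signed-rank test.
#' Genes missing from either genotype are dropped and counted.
#'
#' @param metric_control,metric_null Data frames `gene_id`, `value` for the
#'   two genotypes.
#' @param ages Gene ages with `age_group`.
#' @param groups Age groups to test (default old and young).
#' @return Tibble with one row per group: `age_group`, `n`,
#'   `median_control`, `median_null`, `median_shift` (null minus control),
#'   `statistic`, `p_value`, `direction`; attribute `n_dropped`.
#' @export
monosome_shift <- function(metric_control, metric_null, ages,
                           groups = c("old", "young")) {
  ctrl <- tibble::as_tibble(metric_control)[, c("gene_id", "value")]
  null <- tibble::as_tibble(metric_null)[, c("gene_id", "value")]
  shared <- dplyr::inner_join(ctrl, null, by = "gene_id",
                              suffix = c("_control", "_null"))
  n_dropped <- nrow(ctrl) + nrow(null) - 2L * nrow(shared)
  joined <- join_ages(dplyr::rename(shared, value = "value_control"), ages) |>
    dplyr::rename(value_control = "value") |>
    dplyr::filter(.data$age_group %in% groups)
  out <- lapply(groups, function(g) {
    sub <- joined[joined$age_group == g, ]
    if (nrow(sub) < 2L) {
      rlang::abort(paste0("need at least 2 paired genes in group '", g, "'"))
    }
    tst <- mw_test(sub$value_null, sub$value_control, paired = TRUE)
    shift <- stats::median(sub$value_null - sub$value_control)
    tibble::tibble(
      age_group = g, n = nrow(sub),
      median_control = stats::median(sub$value_control),
      median_null = stats::median(sub$value_null),
      median_shift = shift,
      statistic = unname(tst$statistic),
      p_value = tst$p.value,
      direction = if (shift == 0) "none"
                  else if (shift > 0) "increase" else "decrease"
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Read a TSV expression matrix
#'
#' First column `gene_id`, remaining columns numeric sample TPMs.
#' @param path TSV file.
#' @return A tibble.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
}

#' Read a TSV per-gene metric table
#'
#' Columns `gene_id` and `value`.
#' @param path TSV file.
#' @return A tibble.
#' @export
read_metric <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), value = readr::col_double()))
}
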