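two_group_ages <- function(n_old, n_young) {
  age_groups(tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n_old + n_young)),
    phylostratum = c(rep(1L, n_old), rep(19L, n_young))), 1, 19)
}

metric_tbl <- function(old_vals, young_vals) {
  tibble::tibble(gene_id = sprintf("g%04d", seq_len(length(old_vals) +
                                                      length(young_vals))),
                 value = c(old_vals, young_vals))
}

test_that("small tie-free samples use the exact Mann-Whitney distribution", {
  # {1,2,3} young vs {4,5,6} old: U = 0, exact two-sided p = 2 * 1/C(6,3) = 0.1
  ages <- two_group_ages(3, 3)
  cmp <- compare_metric(metric_tbl(c(4, 5, 6), c(1, 2, 3)), ages)
  g <- glance(cmp)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 0.1)
  expect_equal(g$direction, "young_lower")
})

test_that("identical groups give p = 1 and no direction", {
  ages <- two_group_ages(20, 20)
  cmp <- compare_metric(metric_tbl(1:20, 1:20), ages)
  g <- glance(cmp)
  expect_equal(g$p_value, 1, tolerance = 1e-12)
  expect_equal(g$direction, "none")
  # fully degenerate input (a single shared value) is handled, not NaN
  cmp_d <- compare_metric(metric_tbl(rep(2, 10), rep(2, 10)),
                          two_group_ages(10, 10))
  expect_equal(glance(cmp_d)$p_value, 1)
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(31)
  ages <- two_group_ages(40, 40)
  vals <- metric_tbl(rexp(40, 1), rexp(40, 1.6))
  p_id <- glance(compare_metric(vals, ages, transform = "identity"))$p_value
  p_log <- glance(compare_metric(vals, ages, transform = "log10"))$p_value
  expect_equal(p_id, p_log)
})

test_that("expression comparison detects the planted log10 shift with direction", {
  set.seed(41)
  n <- 400
  ages <- two_group_ages(n, n)
  expr <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:(2 * n)),
    s1 = 10^c(rnorm(n, 1.5, 0.4), rnorm(n, 1.0, 0.4)),
    s2 = 10^c(rnorm(n, 1.5, 0.4), rnorm(n, 1.0, 0.4)))
  g <- glance(compare_expression(expr, ages))
  expect_lt(g$p_value, 0.01)
  expect_equal(g$direction, "young_lower")
  # reported direction always matches the sign of the median difference
  expect_lt(g$median_diff, 0)
  expect_error(compare_expression(expr[1:3, ], ages), "at least 2")
})

test_that("relative change handles nulls, planted shifts and zero TPM", {
  set.seed(51)
  n <- 300
  ages <- two_group_ages(n, n)
  wt <- tibble::tibble(gene_id = sprintf("g%04d", 1:(2 * n)),
                       s1 = 10^rnorm(2 * n, 1.2, 0.4))
  # mutant identical to wild type: all ratios zero, p = 1
  g0 <- glance(relative_change(wt, wt, ages))
  expect_equal(g0$p_value, 1)
  # planted 1.5x up-regulation of young genes in the mutant
  mut <- wt
  mut$s1[(n + 1):(2 * n)] <- mut$s1[(n + 1):(2 * n)] * 1.5
  g1 <- glance(relative_change(wt, mut, ages))
  expect_lt(g1$p_value, 0.01)
  expect_equal(g1$direction, "young_higher")
  # pseudocount shifts individual ratios slightly below log2(1.5)
  expect_equal(g1$median_diff, log2(1.5), tolerance = 1e-3)
  # both values zero: pseudocount makes the ratio exactly 0
  wt0 <- wt; mut0 <- mut
  wt0$s1[1] <- 0; mut0$s1[1] <- 0
  cmp <- relative_change(wt0, mut0, ages)
  expect_equal(cmp$values$value[cmp$values$gene_id == "g0001"], 0)
  # mismatched universes restrict to the intersection, with a count
  cut <- relative_change(wt[-(1:10), ], mut, ages)
  expect_equal(cut$n_dropped, 10L)
})

test_that("half-life-style metric comparison detects a planted scale shift", {
  set.seed(61)
  n <- 300
  ages <- two_group_ages(n, n)
  hl <- metric_tbl(10^rnorm(n, log10(4), 0.25),
                   10^rnorm(n, log10(4 * 0.7), 0.25))
  g <- glance(compare_metric(hl, ages, transform = "log10"))
  expect_lt(g$p_value, 0.01)
  expect_equal(g$direction, "young_lower")
})

test_that("paired monosome shift is group-specific with direction", {
  set.seed(71)
  n <- 300
  ages <- two_group_ages(n, n)
  ctrl <- metric_tbl(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5))
  nul <- ctrl
  nul$value <- nul$value + rnorm(2 * n, 0, 0.1) +
    c(rep(0, n), rep(-0.3, n))
  res <- monosome_shift(ctrl, nul, ages)
  young <- res[res$age_group == "young", ]
  old <- res[res$age_group == "old", ]
  expect_lt(young$p_value, 0.01)
  expect_equal(young$direction, "decrease")
  expect_gt(old$p_value, 0.05)
  # identical genotypes: p = 1 in both groups
  same <- monosome_shift(ctrl, ctrl, ages)
  expect_equal(same$p_value, c(1, 1))
  # a single gene per group is refused
  expect_error(monosome_shift(ctrl[c(1, n + 1), ], nul[c(1, n + 1), ],
                              ages[c(1, n + 1), ]), "at least 2")
})

test_that("comparisons are invariant under gene reordering", {
  set.seed(81)
  ages <- two_group_ages(50, 50)
  vals <- metric_tbl(rnorm(50), rnorm(50, 0.3))
  perm <- sample(100)
  g1 <- glance(compare_metric(vals, ages))
  g2 <- glance(compare_metric(vals[perm, ], ages))
  expect_equal(g1, g2)
})
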