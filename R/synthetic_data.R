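#' Configuration for the synthetic dataset generator
#'
#' Bundles every planted parameter of the toy genome: the age structure, the
#' age-dependent effect sizes (expression shift, TSS openness, enhancer
#' placement, NMD-feature probabilities, NMD-null response, translation
#' metrics), the peak count model and the genome layout.  Defaults encode the
#' age-dependent structure the package is designed to detect: young genes
#' have lower expression, more closed TSS chromatin that re-opens under
#' stress, more distal enhancers and more NMD features.
#'
#' @param seed Integer seed; the same seed reproduces every output
#'   bit-for-bit.
#' @param n_genes Number of genes (default 1250).
#' @param n_strata Number of phylostrata `S` (default 19).
#' @param fraction_old,fraction_young Fractions of genes planted in stratum 1
#'   and stratum `S` (defaults 0.4 and 0.4); the remainder is uniform over
#'   the intermediate strata so age gradients are testable.
#' @param n_chroms Number of chromosomes (default 2).
#' @param slot_bp Per-gene genomic slot (default 12000), guaranteeing
#'   unambiguous proximal/distal classification (TSS spacing >= 7 kb).
#' @param delta_log10_tpm Planted log10 TPM shift of young below old genes
#'   (default 0.5).
#' @param tpm_log10_mean_old,tpm_log10_sd Between-gene log10 TPM mean for old
#'   genes and SD (defaults 1.5, 0.4); per-sample noise SD is
#'   `sample_noise_sd` (0.1).
#' @param sample_noise_sd Within-gene per-sample log10 noise (default 0.1).
#' @param n_reps Expression replicates per genotype (default 2).
#' @param nmd_null_factor Fold up-regulation of young genes in the NMD-null
#'   genotype (default 1.5).
#' @param p_nmd_old,p_nmd_young Planted NMD-feature probabilities (defaults
#'   0.1, 0.4), interpolated linearly across strata.
#' @param tss_height_old,tss_height_young Gaussian TSS openness bump heights
#'   (defaults 3, 1); `tss_sd` is the bump SD in bp (300) over a `baseline`
#'   signal floor (0.5).
#' @param tss_sd,baseline,track_binsize,track_noise_sd Coverage track shape
#'   parameters: bump SD, signal floor, run-length bin (25 bp) and
#'   multiplicative log-normal noise SD per bin (0.05).
#' @param stress_factors Named vector of TSS re-opening factors applied to
#'   young-gene bumps per condition; the control is always factor 1 and the
#'   cold_12h condition deliberately has factor 1 (stress without
#'   re-opening).
#' @param p_proximal_old,p_proximal_young Probability of a TSS-proximal open
#'   chromatin peak (defaults 0.8, 0.3).
#' @param p_distal_old,p_distal_young Probability of a distal upstream
#'   enhancer (defaults 0.2, 0.6).
#' @param p_enh_proximal,p_enh_body Age-independent probabilities of a
#'   proximal or gene-body enhancer (defaults 0.3, 0.15).
#' @param p_enh_colocal Probability that an enhancer coincides with an open
#'   chromatin peak (default 0.65, the Venn-overlap plant).
#' @param peak_log10_rpm_mean,peak_log10_rpm_sd,replicate_rho Peak abundance
#'   model: per-peak log10 RPM drawn bivariate-normal across the two
#'   replicates with correlation `replicate_rho` (default 0.9), counts then
#'   Poisson-sampled around the per-replicate mean (a Poisson-lognormal,
#'   i.e. overdispersed counts correlated on the log scale).
#' @param library_sizes Named reads-per-replicate vector (default two
#'   replicates of 2e7).
#' @param half_life_old_h,half_life_young_scale,half_life_log10_sd mRNA
#'   half-life model: old-gene geometric mean in hours (4), young scale
#'   factor (0.7), log10 SD (0.25).
#' @param trap_old,trap_young_shift,trap_sd TRAP ribosome-association model
#'   (log2 units): old mean 1, young shift -0.5, SD 0.5.
#' @param monosome_sd,monosome_pair_sd,monosome_young_shift Monosome-score
#'   model: between-gene SD (0.5), genotype-pairing noise SD (0.1) and the
#'   planted decrease for young genes in the NMD-null genotype (-0.3).
#' @param p_second_isoform Probability that a gene has a second isoform
#'   (default 0.2).
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_genes = 1250L,
    n_strata = 19L,
    fraction_old = 0.4,
    fraction_young = 0.4,
    n_chroms = 2L,
    slot_bp = 12000L,
    delta_log10_tpm = 0.5,
    tpm_log10_mean_old = 1.5,
    tpm_log10_sd = 0.4,
    sample_noise_sd = 0.1,
    n_reps = 2L,
    nmd_null_factor = 1.5,
    p_nmd_old = 0.1,
    p_nmd_young = 0.4,
    tss_height_old = 3,
    tss_height_young = 1,
    tss_sd = 300,
    baseline = 0.5,
    track_binsize = 25L,
    track_noise_sd = 0.05,
    stress_factors = c(heat_3h = 2, cold_12h = 1),
    p_proximal_old = 0.8,
    p_proximal_young = 0.3,
    p_distal_old = 0.2,
    p_distal_young = 0.6,
    p_enh_proximal = 0.3,
    p_enh_body = 0.15,
    p_enh_colocal = 0.65,
    peak_log10_rpm_mean = 1.5,
    peak_log10_rpm_sd = 0.5,
    replicate_rho = 0.9,
    library_sizes = c(rep1 = 2e7, rep2 = 2e7),
    half_life_old_h = 4,
    half_life_young_scale = 0.7,
    half_life_log10_sd = 0.25,
    trap_old = 1,
    trap_young_shift = -0.5,
    trap_sd = 0.5,
    monosome_sd = 0.5,
    monosome_pair_sd = 0.1,
    monosome_young_shift = -0.3,
    p_second_isoform = 0.2) {
  cfg <- as.list(environment())
  probs <- c(cfg$fraction_old, cfg$fraction_young, cfg$p_nmd_old,
             cfg$p_nmd_young, cfg$p_proximal_old, cfg$p_proximal_young,
             cfg$p_distal_old, cfg$p_distal_young, cfg$p_enh_proximal,
             cfg$p_enh_body, cfg$p_enh_colocal)
  if (any(probs < 0 | probs > 1)) rlang::abort("probabilities must be in [0, 1]")
  if (cfg$fraction_old + cfg$fraction_young > 1) {
    rlang::abort("fraction_old + fraction_young must not exceed 1")
  }
  if (cfg$delta_log10_tpm < 0) rlang::abort("delta_log10_tpm must be >= 0")
  structure(cfg, class = "generator_config")
}

# linear interpolation of an age-dependent parameter across strata
stratum_weight <- function(stratum, n_strata) {
  if (n_strata == 1L) return(rep(0, length(stratum)))
  (stratum - 1) / (n_strata - 1)
}

# mRNA-space geometry for one transcript with a planted NMD status
plan_tx_geometry <- function(flagged) {
  utr5 <- sample(150:400, 1)
  cds_len <- 3L * sample(200:500, 1)
  stop_pos <- utr5 + cds_len
  if (flagged) {
    if (stats::runif(1) < 0.5) {          # long 3'UTR route
      n_exons <- sample(1:3, 1)
      utr3 <- sample(400:900, 1)
      d_last <- if (n_exons > 1) sample(-200:40, 1) else NA_integer_
    } else {                              # PTC route: stop > 50 nt before last junction
      n_exons <- sample(2:4, 1)
      d_last <- sample(51:250, 1)
      utr3 <- d_last + sample(30:300, 1)
    }
  } else {
    n_exons <- sample(1:3, 1)
    utr3 <- sample(120:340, 1)
    d_last <- if (n_exons > 1) sample(-150:40, 1) else NA_integer_
  }
  L <- utr5 + cds_len + utr3
  junctions <- integer(0)
  if (n_exons > 1) {
    last_j <- stop_pos + d_last
    extra <- n_exons - 2L
    if (extra > 0) {
      pool <- seq(50L, last_j - 50L, by = 10L)
      junctions <- sort(sample(pool, extra))
    }
    junctions <- c(junctions, last_j)
  }
  list(utr5 = utr5, cds_len = cds_len, utr3 = utr3, L = L,
       junctions = junctions, stop_pos = stop_pos)
}

# realize a planned transcript on the genome; returns exon/CDS coordinates
realize_tx <- function(geom, strand, body_start) {
  exon_lens <- diff(c(0L, geom$junctions, geom$L))
  n_ex <- length(exon_lens)
  introns <- if (n_ex > 1) sample(250:600, n_ex - 1, replace = TRUE) else integer(0)
  g_lens <- if (strand == "+") exon_lens else rev(exon_lens)
  g_introns <- if (strand == "+") introns else rev(introns)
  starts <- integer(n_ex); ends <- integer(n_ex)
  cur <- body_start
  for (k in seq_len(n_ex)) {
    starts[k] <- cur
    ends[k] <- cur + g_lens[k]
    cur <- ends[k] + if (k < n_ex) g_introns[k] else 0L
  }
  # map an mRNA offset (base index) to its genomic base
  cum <- cumsum(exon_lens)
  map_base <- function(o) {
    k <- findInterval(o, c(0, cum), rightmost.closed = FALSE)
    lo <- c(0, cum)[k]
    if (strand == "+") starts[k] + (o - lo)
    else {
      j <- n_ex - k + 1L
      ends[j] - 1L - (o - lo)
    }
  }
  cds_first <- map_base(geom$utr5)
  cds_last <- map_base(geom$utr5 + geom$cds_len - 1L)
  list(exon_starts = starts, exon_ends = ends,
       cds_start = min(cds_first, cds_last),
       cds_end = max(cds_first, cds_last) + 1L,
       body_start = starts[1], body_end = ends[n_ex])
}

#' Generate a synthetic dataset with planted age-dependent structure
#'
#' Builds a complete, self-consistent toy dataset: a species tree and
#' best-hit tables that recover the planted gene ages exactly under the
#' deepest-clade rule; a gene annotation whose transcript geometry realizes
#' the planted NMD features; open-chromatin peaks with correlated replicate
#' counts; enhancer intervals co-located with open chromatin at the planted
#' rate; per-condition coverage tracks with Gaussian TSS openness (old open,
#' young closed, young re-opened under stress); and expression/metric tables
#' with the planted age effects.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_dataset` with elements `tree_newick`,
#'   `hits`, `protein_map`, `transcripts`, `genes`, `peaks`,
#'   `library_sizes`, `enhancers`, `tracks` (named list of coverage tibbles,
#'   `control` plus one per stress condition), `expression` (named list:
#'   `wild_type`, `nmd_null`), `metrics` (named list: `half_life`, `trap`,
#'   `monosome_control`, `monosome_null`), `ground_truth` and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  S <- config$n_strata
  n <- config$n_genes

  ## ages -------------------------------------------------------------------
  n_old <- round(config$fraction_old * n)
  n_young <- round(config$fraction_young * n)
  n_mid <- n - n_old - n_young
  strata <- c(rep(1L, n_old), rep(S, n_young),
              if (n_mid > 0) sample(seq(2L, S - 1L), n_mid, replace = TRUE))
  strata <- sample(strata)                 # shuffle over genomic positions
  w <- stratum_weight(strata, S)

  ## genome layout ----------------------------------------------------------
  margin <- 4000L
  slots_per_chrom <- ceiling(n / config$n_chroms)
  chrom_len <- 2L * margin + slots_per_chrom * config$slot_bp
  chroms <- paste0("chr", seq_len(config$n_chroms))
  gene_id <- sprintf("gene%04d", seq_len(n))
  gene_chrom <- chroms[(seq_len(n) - 1L) %/% slots_per_chrom + 1L]
  slot_idx <- (seq_len(n) - 1L) %% slots_per_chrom
  body_anchor <- margin + slot_idx * config$slot_bp + 5000L
  strand <- sample(c("+", "-"), n, replace = TRUE)

  ## transcripts with planted NMD geometry ----------------------------------
  p_nmd <- config$p_nmd_old + w * (config$p_nmd_young - config$p_nmd_old)
  gene_nmd <- stats::runif(n) < p_nmd
  second_iso <- stats::runif(n) < config$p_second_isoform
  tx_rows <- vector("list", n + sum(second_iso))
  truth_geom <- vector("list", n)
  row <- 1L
  for (i in seq_len(n)) {
    n_iso <- 1L + second_iso[i]
    # gene-level NMD = OR over isoforms; plant the feature on isoform 1
    iso_flags <- c(gene_nmd[i], rep(FALSE, n_iso - 1L))
    for (k in seq_len(n_iso)) {
      geom <- plan_tx_geometry(iso_flags[k])
      real <- realize_tx(geom, strand[i], body_anchor[i])
      tx_rows[[row]] <- tibble::tibble(
        transcript_id = sprintf("%s.%d", gene_id[i], k),
        gene_id = gene_id[i],
        chrom = gene_chrom[i],
        strand = strand[i],
        exon_starts = list(real$exon_starts),
        exon_ends = list(real$exon_ends),
        cds_start = real$cds_start,
        cds_end = real$cds_end,
        coding = TRUE
      )
      if (k == 1L) truth_geom[[i]] <- list(geom = geom, real = real)
      row <- row + 1L
    }
  }
  transcripts <- dplyr::bind_rows(tx_rows)
  genes <- gene_table(transcripts)
  genes <- genes[match(gene_id, genes$gene_id), ]
  tss <- genes$tss

  ## species tree and hit tables --------------------------------------------
  outgroups <- sprintf("outgroup_%02d", seq_len(S - 1L))
  nwk <- "focal_sp"
  for (i in rev(seq_len(S - 1L))) nwk <- paste0("(", outgroups[i], ",", nwk, ")")
  tree_newick <- paste0(nwk, ";")
  protein_map <- transcripts[, c("transcript_id", "gene_id")] |>
    dplyr::rename(protein_id = "transcript_id")
  tx_strata <- strata[match(protein_map$gene_id, gene_id)]
  hit_rows <- lapply(seq_len(nrow(protein_map)), function(j) {
    a <- tx_strata[j]
    sp <- character(0)
    if (a < S) {
      deeper <- setdiff(seq_len(S - 1L), seq_len(a - 1L))  # a .. S-1
      extra <- deeper[stats::runif(length(deeper)) < 0.3]
      sp <- outgroups[sort(unique(c(a, extra)))]
      if (stats::runif(1) < 0.5) sp <- c(sp, "focal_sp")
    } else if (stats::runif(1) < 0.5) {
      sp <- "focal_sp"                    # self-hit only: still youngest
    }
    if (length(sp)) tibble::tibble(protein_id = protein_map$protein_id[j],
                                   subject_species = sp)
  })
  hits <- dplyr::bind_rows(hit_rows)

  ## peaks and enhancers -----------------------------------------------------
  p_prox <- config$p_proximal_old + w * (config$p_proximal_young - config$p_proximal_old)
  p_dist <- config$p_distal_old + w * (config$p_distal_young - config$p_distal_old)
  has_prox_peak <- stats::runif(n) < p_prox
  has_dist_enh <- stats::runif(n) < p_dist
  has_prox_enh <- stats::runif(n) < config$p_enh_proximal
  has_body_enh <- stats::runif(n) < config$p_enh_body

  up <- function(off1, off2) {            # strand-aware upstream interval
    s <- ifelse(strand == "+", tss - off2, tss + off1)
    cbind(s, s + (off2 - off1))
  }
  prox_iv <- up(500L, 900L)
  dist_iv <- up(2600L, 3000L)
  alt_iv <- up(3200L, 3600L)              # enhancer slot guaranteed peak-free
  prox_enh_iv <- up(1000L, 1400L)
  body_iv <- cbind(genes$start + 200L, genes$start + 600L)

  peak_list <- list(); enh_list <- list()
  enh_colocal <- stats::runif(n) < config$p_enh_colocal
  enh_colocal_p <- stats::runif(n) < config$p_enh_colocal
  enh_colocal_b <- stats::runif(n) < config$p_enh_colocal
  has_dist_peak <- has_dist_enh & enh_colocal  # forced open chromatin under enhancers
  for (i in seq_len(n)) {
    if (has_prox_peak[i]) {
      peak_list[[length(peak_list) + 1L]] <-
        c(gene_chrom[i], prox_iv[i, 1], prox_iv[i, 2])
    }
    if (has_dist_enh[i]) {
      slot <- if (enh_colocal[i]) dist_iv[i, ] else alt_iv[i, ]
      enh_list[[length(enh_list) + 1L]] <- c(gene_chrom[i], slot[1], slot[2])
      if (enh_colocal[i]) {
        peak_list[[length(peak_list) + 1L]] <-
          c(gene_chrom[i], dist_iv[i, 1], dist_iv[i, 2])
      }
    }
    if (has_prox_enh[i]) {
      enh_list[[length(enh_list) + 1L]] <-
        c(gene_chrom[i], prox_enh_iv[i, 1], prox_enh_iv[i, 2])
      if (enh_colocal_p[i]) {
        peak_list[[length(peak_list) + 1L]] <-
          c(gene_chrom[i], prox_enh_iv[i, 1], prox_enh_iv[i, 2])
      }
    }
    if (has_body_enh[i]) {
      enh_list[[length(enh_list) + 1L]] <-
        c(gene_chrom[i], body_iv[i, 1], body_iv[i, 2])
      if (enh_colocal_b[i]) {
        peak_list[[length(peak_list) + 1L]] <-
          c(gene_chrom[i], body_iv[i, 1], body_iv[i, 2])
      }
    }
  }
  to_iv_tbl <- function(lst, prefix) {
    m <- do.call(rbind, lst)
    tibble::tibble(chrom = m[, 1],
                   start = as.integer(m[, 2]), end = as.integer(m[, 3]),
                   name = sprintf("%s%04d", prefix, seq_len(nrow(m))))
  }
  peaks <- to_iv_tbl(peak_list, "peak")
  enhancers <- to_iv_tbl(enh_list, "enh")

  # correlated replicate counts: bivariate-normal log10 RPM, Poisson counts
  reps <- names(config$library_sizes)
  rho <- config$replicate_rho
  z1 <- stats::rnorm(nrow(peaks)); z2 <- stats::rnorm(nrow(peaks))
  l1 <- config$peak_log10_rpm_mean + config$peak_log10_rpm_sd * z1
  l2 <- config$peak_log10_rpm_mean +
    config$peak_log10_rpm_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  lmat <- cbind(l1, l2)
  for (r in seq_along(reps)) {
    lam <- 10^lmat[, min(r, 2L)] * config$library_sizes[r] / 1e6
    peaks[[reps[r]]] <- stats::rpois(nrow(peaks), lam)
  }

  ## coverage tracks ---------------------------------------------------------
  heights <- config$tss_height_old +
    w * (config$tss_height_young - config$tss_height_old)
  conditions <- c(control = 1, config$stress_factors)
  young <- strata == S
  tracks <- lapply(conditions, function(factor) {
    h <- ifelse(young, heights * factor, heights)
    build_track(chroms, chrom_len, gene_chrom, tss, h,
                config$tss_sd, config$baseline,
                config$track_binsize, config$track_noise_sd)
  })
  names(tracks) <- names(conditions)

  ## expression --------------------------------------------------------------
  mu <- config$tpm_log10_mean_old - w * config$delta_log10_tpm
  gene_mu <- stats::rnorm(n, mu, config$tpm_log10_sd)
  gene_mu_mut <- gene_mu + ifelse(young, log10(config$nmd_null_factor), 0)
  draw_expr <- function(mu_vec) {
    cols <- lapply(seq_len(config$n_reps), function(r)
      10^(mu_vec + stats::rnorm(n, 0, config$sample_noise_sd)))
    names(cols) <- paste0("sample", seq_len(config$n_reps))
    tibble::tibble(gene_id = gene_id, !!!cols)
  }
  expression <- list(wild_type = draw_expr(gene_mu),
                     nmd_null = draw_expr(gene_mu_mut))

  ## per-gene metrics --------------------------------------------------------
  hl_mu <- log10(config$half_life_old_h) + w * log10(config$half_life_young_scale)
  half_life <- tibble::tibble(
    gene_id = gene_id,
    value = 10^stats::rnorm(n, hl_mu, config$half_life_log10_sd))
  trap <- tibble::tibble(
    gene_id = gene_id,
    value = stats::rnorm(n, config$trap_old + w * config$trap_young_shift,
                         config$trap_sd))
  mono_ctrl <- stats::rnorm(n, 0, config$monosome_sd)
  mono_null <- mono_ctrl + stats::rnorm(n, 0, config$monosome_pair_sd) +
    ifelse(young, config$monosome_young_shift, 0)
  metrics <- list(
    half_life = half_life,
    trap = trap,
    monosome_control = tibble::tibble(gene_id = gene_id, value = mono_ctrl),
    monosome_null = tibble::tibble(gene_id = gene_id, value = mono_null)
  )

  ## ground truth ------------------------------------------------------------
  ground_truth <- tibble::tibble(
    gene_id = gene_id,
    chrom = gene_chrom,
    strand = strand,
    tss = tss,
    phylostratum = strata,
    age_group = factor(ifelse(strata == 1L, "old",
                              ifelse(strata == S, "young", "other")),
                       levels = c("old", "young", "other")),
    nmd_feature = gene_nmd,
    utr3_len = vapply(truth_geom, function(x) x$geom$utr3, numeric(1)),
    stop_to_last_ejc = vapply(truth_geom, function(x) {
      j <- x$geom$junctions
      if (length(j)) max(j) - x$geom$stop_pos else NA_real_
    }, numeric(1)),
    has_proximal_peak = has_prox_peak,
    has_distal_peak = has_dist_peak,
    has_distal_enhancer = has_dist_enh,
    has_proximal_enhancer = has_prox_enh,
    has_body_enhancer = has_body_enh,
    tss_height = heights,
    expr_log10_mu = gene_mu
  )

  structure(list(
    tree_newick = tree_newick,
    focal_species = "focal_sp",
    hits = hits,
    protein_map = protein_map,
    transcripts = transcripts,
    genes = genes,
    peaks = peaks,
    library_sizes = config$library_sizes,
    enhancers = enhancers,
    tracks = tracks,
    expression = expression,
    metrics = metrics,
    ground_truth = ground_truth,
    chrom_len = stats::setNames(rep(chrom_len, config$n_chroms), chroms),
    config = config
  ), class = "synthetic_dataset")
}

# Gaussian TSS openness bumps over a noise floor, run-length binned
build_track <- function(chroms, chrom_len, gene_chrom, tss, height,
                        tss_sd, baseline, binsize, noise_sd) {
  out <- vector("list", length(chroms))
  reach <- ceiling(4 * tss_sd / binsize)
  for (c_idx in seq_along(chroms)) {
    nb <- chrom_len %/% binsize
    centers <- (seq_len(nb) - 0.5) * binsize
    v <- rep(baseline, nb)
    idx <- which(gene_chrom == chroms[c_idx])
    for (i in idx) {
      b0 <- floor(tss[i] / binsize) + 1L
      span <- max(1L, b0 - reach):min(nb, b0 + reach)
      v[span] <- v[span] +
        height[i] * exp(-(centers[span] - tss[i])^2 / (2 * tss_sd^2))
    }
    if (noise_sd > 0) v <- v * exp(stats::rnorm(nb, 0, noise_sd))
    out[[c_idx]] <- tibble::tibble(
      chrom = chroms[c_idx],
      start = as.integer((seq_len(nb) - 1L) * binsize),
      end = as.integer(seq_len(nb) * binsize),
      value = v
    )
  }
  dplyr::bind_rows(out)
}

#' Retrieve the coverage track of one condition
#'
#' @param dataset A [generate_dataset()] result.
#' @param condition Condition name (`"control"` or one of the configured
#'   stress conditions).
#' @return The condition's coverage tibble.
#' @export
stress_condition <- function(dataset, condition) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!condition %in% names(dataset$tracks)) {
    rlang::abort(paste0("unknown condition '", condition, "'; available: ",
                        paste(names(dataset$tracks), collapse = ", ")))
  }
  dataset$tracks[[condition]]
}

#' Write a synthetic dataset to a directory of standard files
#'
#' Emits newick, TSV, GFF3, BED and bedGraph files that round-trip through
#' the package readers, plus the ground-truth table.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  writeLines(dataset$tree_newick, p("species_tree.nwk"))
  readr::write_tsv(dataset$hits, p("hits.tsv"))
  readr::write_tsv(dataset$protein_map, p("protein_map.tsv"))
  write_gff3(dataset$transcripts, p("annotation.gff3"))
  write_bed(dataset$peaks[, c("chrom", "start", "end", "name")], p("peaks.bed"))
  readr::write_tsv(
    dataset$peaks[, c("name", names(dataset$library_sizes))],
    p("peak_counts.tsv"))
  readr::write_tsv(
    tibble::tibble(replicate = names(dataset$library_sizes),
                   library_size = unname(dataset$library_sizes)),
    p("library_sizes.tsv"))
  write_bed(dataset$enhancers, p("enhancers.bed"))
  for (cond in names(dataset$tracks)) {
    write_bedgraph(dataset$tracks[[cond]],
                   p(sprintf("coverage_%s.bedGraph", cond)))
  }
  for (g in names(dataset$expression)) {
    readr::write_tsv(dataset$expression[[g]], p(sprintf("expression_%s.tsv", g)))
  }
  for (m in names(dataset$metrics)) {
    readr::write_tsv(dataset$metrics[[m]], p(sprintf("metric_%s.tsv", m)))
  }
  readr::write_tsv(dataset$ground_truth, p("ground_truth.tsv"))
  invisible(dir)
}
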