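# Seeded synthetic-cohort generator. Emulates the statistical structure the
# screen assumes: bimodal Infinium-like beta values, control samples, a
# replicate pair, MSI-linked global hypermethylation, doubling times
# anti-correlated with methylation, planted monotone-silenced and L-shaped
# genes, GGF-compliant promoter islands, and expression-linked survival.

#' Simulation configuration
#'
#' Defaults mirror the cohort the analysis is designed for: a panel of 30
#' cell lines profiled on a 27K-style array (about 2 probes per promoter),
#' an unmethylated control with mean beta 0.05 and an in-vitro methylated
#' control with mean 0.86, an MSI subgroup with globally elevated
#' methylation, 10% of genes silenced with a monotone negative
#' methylation-expression relation (Spearman rho around -0.8) and 1% with an
#' L-shaped (nonlinear) relation.
#'
#' @param n_samples_cellline,n_samples_tumor cohort sizes (controls and the
#'   replicate are appended on top of `n_samples_cellline`).
#' @param n_genes,probes_per_gene array design.
#' @param frac_silenced_monotone,frac_silenced_lshape planted class fractions
#'   (must sum to <= 1).
#' @param msi_fraction fraction of non-control samples labelled MSI.
#' @param msi_beta_shift target difference in mean beta, MSI minus MSS,
#'   applied as a shift of the high-methylation mixture weight so values stay
#'   in [0, 1].
#' @param control_means c(unmethylated, methylated) mean betas.
#' @param noise_sd_expr expression noise sd (log2 units).
#' @param slope_monotone log2 expression drop per unit beta for
#'   monotone-silenced genes.
#' @param island_fraction fraction of genes given a GGF-compliant promoter
#'   island.
#' @param sample_effect_sd sd of the per-sample global methylation factor.
#' @param growth_cor target correlation between mean beta and doubling time
#'   (negative: hypermethylated lines grow faster).
#' @param baseline_hazard events per day for the reference survival group.
#' @param hazard_ratio_low hazard multiplier for the low-expression group.
#' @param censoring_rate expected fraction censored (1 = all censored).
#' @param seed integer seed; mandatory, drives every stage deterministically.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples_cellline = 30L, n_samples_tumor = 0L,
                       n_genes = 2000L, probes_per_gene = 2L,
                       frac_silenced_monotone = 0.10,
                       frac_silenced_lshape = 0.01,
                       msi_fraction = 1 / 3, msi_beta_shift = 0.05,
                       control_means = c(0.05, 0.86),
                       noise_sd_expr = 1.0, slope_monotone = 6.2,
                       island_fraction = 0.662, sample_effect_sd = 0.15,
                       growth_cor = -0.5,
                       baseline_hazard = 1 / 1500, hazard_ratio_low = 3,
                       censoring_rate = 0.3, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  cfg <- list(n_samples_cellline = as.integer(n_samples_cellline),
              n_samples_tumor = as.integer(n_samples_tumor),
              n_genes = as.integer(n_genes),
              probes_per_gene = as.integer(probes_per_gene),
              frac_silenced_monotone = frac_silenced_monotone,
              frac_silenced_lshape = frac_silenced_lshape,
              msi_fraction = msi_fraction, msi_beta_shift = msi_beta_shift,
              control_means = control_means,
              noise_sd_expr = noise_sd_expr,
              slope_monotone = slope_monotone,
              island_fraction = island_fraction,
              sample_effect_sd = sample_effect_sd,
              growth_cor = growth_cor,
              baseline_hazard = baseline_hazard,
              hazard_ratio_low = hazard_ratio_low,
              censoring_rate = censoring_rate,
              seed = as.integer(seed))
  fr <- c(cfg$frac_silenced_monotone, cfg$frac_silenced_lshape,
          cfg$msi_fraction, cfg$island_fraction, cfg$censoring_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_silenced_monotone + cfg$frac_silenced_lshape > 1)
    stop("planted fractions sum to more than 1")
  if (any(cfg$control_means < 0 | cfg$control_means > 1))
    stop("control means must lie in [0, 1]")
  if (cfg$n_samples_cellline < 1 || cfg$n_genes < 1 || cfg$probes_per_gene < 1)
    stop("counts must be positive")
  structure(cfg, class = "sim_config")
}

# per-probe high-methylation propensity; Beta(0.2, 0.4) reproduces the
# 27K-like per-probe profile (about half the probes averaging < 0.2 and
# about 30% above 0.5)
PI_SHAPE1 <- 0.2
PI_SHAPE2 <- 0.4
BETA_CONC <- 10  # concentration of the low/high beta components

rbeta_mean <- function(n, mean, conc = BETA_CONC) {
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Simulate a methylation cohort
#'
#' Per-probe betas come from a two-component mixture: a low component (mean
#' 0.1) and a high component (mean 0.8), with a per-probe propensity for the
#' high component and a per-sample global factor. MSI samples receive an
#' increased high-component weight sized to shift their mean beta by
#' `msi_beta_shift`. One unmethylated control, one in-vitro methylated
#' control, and one technical replicate of the first sample are appended.
#' Doubling times are drawn anti-correlated with per-sample mean beta;
#' mutation flags are drawn at typical colorectal frequencies, independent
#' of methylation.
#'
#' @param cfg a [sim_config()].
#' @param gene_classes optional named character vector (`"null"`,
#'   `"monotone"`, `"lshape"` per gene) to reuse the planted truth of a
#'   previously generated cohort, e.g. for a validation cohort sharing the
#'   same silenced genes; by default classes are drawn from the config
#'   fractions.
#' @return list with `beta` ([beta_matrix()]), `samples`
#'   ([sample_annotation()]) and `probes` ([probe_annotation()]).
#' @export
simulate_methylation <- function(cfg, gene_classes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples_cellline
  n_probes <- cfg$n_genes * cfg$probes_per_gene
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  probe_ids <- sprintf("cg%05d", seq_len(n_probes))
  gene_of_probe <- rep(genes, each = cfg$probes_per_gene)

  if (!is.null(gene_classes)) {
    if (length(gene_classes) != cfg$n_genes)
      stop("gene_classes must cover all simulated genes")
    classes <- unname(gene_classes)
    names(gene_classes) <- genes
  } else {
    n_mono <- round(cfg$frac_silenced_monotone * cfg$n_genes)
    n_lsh <- round(cfg$frac_silenced_lshape * cfg$n_genes)
    classes <- rep("null", cfg$n_genes)
    planted <- sample.int(cfg$n_genes, n_mono + n_lsh)
    classes[planted[seq_len(n_mono)]] <- "monotone"
    if (n_lsh > 0) classes[planted[n_mono + seq_len(n_lsh)]] <- "lshape"
  }

  # planted genes get mid propensity so betas span the full range
  pi_probe <- stats::rbeta(n_probes, PI_SHAPE1, PI_SHAPE2)
  pi_probe[gene_of_probe %in% genes[classes != "null"]] <- 0.5

  sample_ids <- sprintf("S%03d", seq_len(n))
  msi <- rep("MSS", n)
  msi[sample.int(n, round(cfg$msi_fraction * n))] <- "MSI"
  s_fac <- pmax(0.2, stats::rnorm(n, 1, cfg$sample_effect_sd))
  dw <- cfg$msi_beta_shift / 0.7  # mean beta = 0.1 + 0.7 * weight

  w <- outer(pi_probe, s_fac)             # probes x samples
  w <- sweep(w, 2, ifelse(msi == "MSI", dw, 0), `+`)
  w <- pmin(pmax(w, 0), 1)
  high <- matrix(stats::runif(n_probes * n) < w, n_probes, n)
  vals <- matrix(rbeta_mean(n_probes * n, 0.1), n_probes, n)
  vals[high] <- rbeta_mean(sum(high), 0.8)

  ctrl_neg <- rbeta_mean(n_probes, cfg$control_means[1], conc = 20)
  ctrl_pos <- rbeta_mean(n_probes, cfg$control_means[2], conc = 20)
  repl <- pmin(pmax(vals[, 1] + stats::rnorm(n_probes, 0, 0.01), 0), 1)
  vals <- cbind(vals, ctrl_neg, ctrl_pos, repl)
  all_ids <- c(sample_ids, "CTRL_NEG", "CTRL_POS",
               paste0(sample_ids[1], "_rep"))
  dimnames(vals) <- list(probe_ids, all_ids)

  mean_beta <- colMeans(vals[, seq_len(n), drop = FALSE])
  z <- as.numeric(scale(mean_beta))
  rg <- cfg$growth_cor
  dt <- 30 + 8 * (rg * z + sqrt(max(0, 1 - rg^2)) * stats::rnorm(n))
  dt <- pmax(dt, 8)

  mut_freq <- c(APC = 0.7, BRAF = 0.1, TP53 = 0.6, KRAS = 0.4, PIK3CA = 0.2)
  mut <- lapply(mut_freq, function(f)
    c(ifelse(stats::runif(n) < f, "mut", "wt"), rep("unknown", 3)))
  names(mut) <- paste0("mut_", names(mut_freq))

  samples <- do.call(sample_annotation, c(list(
    sample_id = all_ids,
    cohort = "cell_line",
    msi_status = c(msi, rep("unknown", 3)),
    doubling_time = c(dt, NA, NA, NA),
    control_role = c(rep("none", n), "unmethylated_control",
                     "methylated_control",
                     paste0("replicate_of:", sample_ids[1]))), mut))

  probes <- probe_annotation(probe_ids, gene_of_probe,
                             chromosome = "chrS",
                             position = seq_len(n_probes) * 1000L)
  attr(probes, "gene_class") <- stats::setNames(classes, genes)
  list(beta = beta_matrix(vals), samples = samples, probes = probes)
}

#' Simulate expression coupled to methylation
#'
#' Null genes are independent of methylation. Monotone-silenced genes follow
#' a linear decrease in log2 expression with promoter beta plus Gaussian
#' noise (defaults give Spearman rho about -0.8 at n = 30). L-shaped genes
#' are expressed high only in a subset of the low-methylation (beta < 1/3)
#' samples and sit at a low floor otherwise, so the rank correlation is weak
#' while the scatter plot is L-shaped.
#'
#' @param cfg a [sim_config()].
#' @param meth output of [simulate_methylation()] (same config).
#' @return list with `expr` ([expression_matrix()] over the non-control
#'   samples) and `truth` (data.frame `gene_symbol`, `class`).
#' @export
simulate_expression <- function(cfg, meth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  classes <- attr(meth$probes, "gene_class")
  if (is.null(classes)) stop("meth must come from simulate_methylation")
  genes <- names(classes)
  keep <- meth$samples$control_role == "none"
  sample_ids <- meth$samples$sample_id[keep]
  aligned <- align_cohort(meth$beta,
                          expression_matrix(matrix(0, length(genes),
                                                   length(sample_ids),
                                                   dimnames = list(genes, sample_ids))),
                          meth$probes)
  gb <- aligned$beta[genes, sample_ids, drop = FALSE]
  n <- length(sample_ids)
  expr <- matrix(NA_real_, length(genes), n,
                 dimnames = list(genes, sample_ids))
  base_mu <- stats::runif(length(genes), 4, 10)
  for (i in seq_along(genes)) {
    cls <- classes[i]
    b <- gb[i, ]
    if (cls == "monotone") {
      expr[i, ] <- base_mu[i] + cfg$slope_monotone * (0.5 - b) +
        stats::rnorm(n, 0, cfg$noise_sd_expr)
    } else if (cls == "lshape") {
      low_meth <- b < 1 / 3
      on <- low_meth & stats::runif(n) < 0.6
      expr[i, ] <- 2 + stats::rnorm(n, 0, 0.4 * cfg$noise_sd_expr)
      expr[i, on] <- 8 + stats::rnorm(sum(on), 0, cfg$noise_sd_expr)
    } else {
      expr[i, ] <- base_mu[i] + stats::rnorm(n, 0, cfg$noise_sd_expr)
    }
  }
  list(expr = expression_matrix(expr),
       truth = data.frame(gene_symbol = genes, class = unname(classes),
                          stringsAsFactors = FALSE))
}

#' Simulate promoter sequences with planted CpG islands
#'
#' Background sequence has GC about 0.4 with every CpG dinucleotide removed,
#' so no island can be called outside the planted segment. Island genes get
#' an embedded 250 bp CpG-rich segment (GC >= 0.6, Obs/Exp CpG >= 1.0)
#' overlapping the TSS.
#'
#' @param cfg a [sim_config()].
#' @param gene_symbols genes to generate promoters for.
#' @return list with `promoters` (a [promoter_set()]) and `truth`
#'   (data.frame `gene_symbol`, `has_island`, `island_start`, `island_end`;
#'   0-based half-open).
#' @export
simulate_promoters <- function(cfg, gene_symbols) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  len <- 1500L; tss <- 1000L
  isl_start <- 900L; isl_len <- 250L
  n <- length(gene_symbols)
  has_isl <- stats::runif(n) < cfg$island_fraction
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- sim_background_seq(len)
    if (has_isl[i])
      substr(s, isl_start + 1L, isl_start + isl_len) <- sim_island_seq(isl_len)
    seqs[i] <- s
  }
  list(promoters = promoter_set(gene_symbols, seqs, tss),
       truth = data.frame(gene_symbol = gene_symbols, has_island = has_isl,
                          island_start = ifelse(has_isl, isl_start, NA),
                          island_end = ifelse(has_isl, isl_start + isl_len, NA),
                          stringsAsFactors = FALSE))
}

# GC ~ 0.4 background with all CpG dinucleotides broken (G after C -> A)
sim_background_seq <- function(len) {
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  cg <- which(x[-len] == "C" & x[-1] == "G")
  while (length(cg) > 0) {
    x[cg + 1L] <- "A"
    cg <- which(x[-len] == "C" & x[-1] == "G")
  }
  paste(x, collapse = "")
}

# CpG-rich island: emit "CG" with prob 0.17, else a skewed single base;
# yields GC ~ 0.62 and Obs/Exp ~ 2 over a 250 bp span
sim_island_seq <- function(len) {
  out <- character(0)
  while (sum(nchar(out)) < len) {
    out <- c(out, if (stats::runif(1) < 0.17) "CG" else
      sample(c("A", "C", "G", "T"), 1, prob = c(0.27, 0.23, 0.23, 0.27)))
  }
  substr(paste(out, collapse = ""), 1L, len)
}

#' Simulate survival linked to a marker gene
#'
#' Event times are exponential with the baseline hazard, multiplied by
#' `hazard_ratio_low` for samples whose marker expression is below the
#' cohort median. Censoring is independent exponential sized to the
#' configured censoring rate (`censoring_rate >= 1` censors every record).
#'
#' @param cfg a [sim_config()].
#' @param expr an [expression_matrix()].
#' @param marker_gene gene whose expression stratifies the hazard.
#' @param samples a [sample_annotation()] covering the expression samples.
#' @return `samples` with `survival_time` (days) and `event` filled for
#'   samples present in `expr`.
#' @export
simulate_survival <- function(cfg, expr, marker_gene, samples) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!marker_gene %in% rownames(expr))
    stop("marker gene '", marker_gene, "' not in expression matrix")
  set.seed(cfg$seed + 3L)
  ids <- intersect(samples$sample_id, colnames(expr))
  x <- unclass(expr)[marker_gene, ids]
  low <- x < stats::median(x, na.rm = TRUE)
  h <- cfg$baseline_hazard * ifelse(low, cfg$hazard_ratio_low, 1)
  t_event <- stats::rexp(length(ids), h)
  if (cfg$censoring_rate >= 1) {
    time <- stats::rexp(length(ids), cfg$baseline_hazard); ev <- 0L
  } else if (cfg$censoring_rate <= 0) {
    time <- t_event; ev <- 1L
  } else {
    hc <- cfg$baseline_hazard * cfg$censoring_rate / (1 - cfg$censoring_rate)
    t_cens <- stats::rexp(length(ids), hc)
    ev <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }
  i <- match(ids, samples$sample_id)
  samples$survival_time[i] <- time
  samples$event[i] <- rep_len(ev, length(ids))
  samples
}

#' Simulate a complete cohort bundle
#'
#' Runs all generator stages with one config: methylation (with controls and
#' replicate), expression with planted silenced genes, promoters with planted
#' islands, and survival driven by the first monotone-silenced gene (or the
#' first gene when none is planted).
#'
#' @param cfg a [sim_config()].
#' @param gene_classes optional planted truth to reuse, see
#'   [simulate_methylation()].
#' @return list with `beta`, `expr`, `samples`, `probes`, `promoters`,
#'   `truth_genes`, `truth_islands`, `marker_gene`.
#' @export
simulate_cohort <- function(cfg, gene_classes = NULL) {
  meth <- simulate_methylation(cfg, gene_classes = gene_classes)
  ex <- simulate_expression(cfg, meth)
  prom <- simulate_promoters(cfg, ex$truth$gene_symbol)
  marker <- ex$truth$gene_symbol[ex$truth$class == "monotone"][1]
  if (is.na(marker)) marker <- ex$truth$gene_symbol[1]
  samples <- simulate_survival(cfg, ex$expr, marker, meth$samples)
  list(beta = meth$beta, expr = ex$expr, samples = samples,
       probes = meth$probes, promoters = prom$promoters,
       truth_genes = ex$truth, truth_islands = prom$truth,
       marker_gene = marker)
}

#' Write a simulated cohort to a directory
#'
#' Emits beta.tsv, expression.tsv, probes.tsv, samples.tsv, promoters.fa,
#' truth_genes.tsv and truth_islands.tsv.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix(cohort$beta, p("beta.tsv"), feature_col = "probe_id")
  write_matrix(cohort$expr, p("expression.tsv"), feature_col = "gene_symbol")
  utils::write.table(as.data.frame(cohort$probes), p("probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohort$samples), p("samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_promoter_fasta(cohort$promoters, p("promoters.fa"))
  utils::write.table(cohort$truth_genes, p("truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth_islands, p("truth_islands.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
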