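# End-to-end orchestration: simulate/read -> QC -> associations -> screen ->
# islands -> term enrichment -> survival, with seeded determinism and a
# single summary report.

#' Survival stratified by a marker gene's expression
#'
#' Dichotomizes samples by the marker's expression (median split by default,
#' or lowest tertile vs the rest), fits Kaplan-Meier curves per group and
#' compares them by the log-rank test.
#'
#' @param expr an [expression_matrix()].
#' @param annot a [sample_annotation()] with `survival_time` and `event`.
#' @param marker_gene gene symbol present in `expr`.
#' @param rule `"median"` or `"tertile_low_vs_rest"`.
#' @return A `survival_strata`: list with `test` (log-rank `ms_test`),
#'   `km_low`, `km_high` ([km_estimate()] fits), `groups` (named label
#'   vector), `marker_gene`, `rule`.
#' @export
survival_stratify <- function(expr, annot, marker_gene,
                              rule = c("median", "tertile_low_vs_rest")) {
  rule <- match.arg(rule)
  if (!marker_gene %in% rownames(expr))
    stop("marker gene '", marker_gene, "' not in expression matrix")
  ids <- intersect(colnames(expr), annot$sample_id)
  a <- annot[match(ids, annot$sample_id), , drop = FALSE]
  ok <- !is.na(a$survival_time) & !is.na(a$event)
  ids <- ids[ok]; a <- a[ok, , drop = FALSE]
  x <- unclass(expr)[marker_gene, ids]
  cut <- if (rule == "median") stats::median(x, na.rm = TRUE) else
    stats::quantile(x, 1 / 3, na.rm = TRUE, names = FALSE)
  low <- x < cut
  if (sum(low) < 2 || sum(!low) < 2)
    stop("need at least 2 samples with survival data per expression group")
  test <- logrank_test(a$survival_time[low], a$event[low],
                       a$survival_time[!low], a$event[!low])
  structure(list(test = test,
                 km_low = km_estimate(a$survival_time[low], a$event[low]),
                 km_high = km_estimate(a$survival_time[!low], a$event[!low]),
                 groups = stats::setNames(ifelse(low, "low", "high"), ids),
                 marker_gene = marker_gene, rule = rule),
            class = "survival_strata")
}

#' @export
print.survival_strata <- function(x, ...) {
  n <- table(x$groups)
  cat(sprintf(paste0("survival by %s expression (%s split): ",
                     "low n=%d, high n=%d\n",
                     "  log-rank chi-square = %.3f, p = %s\n"),
              x$marker_gene, x$rule, n[["low"]], n[["high"]],
              x$test$statistic, format.pval(x$test$p_value, digits = 3)))
  invisible(x)
}

#' @param x a `survival_strata`.
#' @param ... passed to plot.
#' @rdname survival_stratify
#' @method plot survival_strata
#' @export
plot.survival_strata <- function(x, ...) {
  plot(x$km_high, ...)
  tt <- c(0, rep(x$km_low$time, each = 2))
  ss <- c(1, 1, rep(x$km_low$survival, each = 2)[-(2 * nrow(x$km_low))])
  graphics::lines(tt, ss, lty = 2)
  graphics::legend("bottomleft", legend = c("high", "low"), lty = c(1, 2))
  invisible(x)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory for all stage TSVs and the summary.
#' @param simulate if TRUE, generate the cohort with `sim` instead of
#'   reading input files.
#' @param sim a [sim_config()] (required when `simulate = TRUE`).
#' @param beta,expression,probes,samples,promoters input paths (ignored when
#'   simulating).
#' @param beta2,expression2,probes2 optional validation-cohort paths; when
#'   simulating, a second cohort is generated with a shifted seed.
#' @param gmt optional GMT annotation path for term enrichment.
#' @param q_threshold FDR threshold for screen and validation.
#' @param lshape an [lshape_config()].
#' @param ggf_window,ggf_gc_min,ggf_oe_min GGF island thresholds.
#' @param promoter_window c(upstream, downstream) bp for island association.
#' @param n_random_sets random baseline sets for island enrichment.
#' @param survival_marker marker gene (default: picked from screen results).
#' @param survival_rule dichotomization rule, see [survival_stratify()].
#' @param seed integer seed for every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = TRUE, sim = NULL,
                       beta = NULL, expression = NULL, probes = NULL,
                       samples = NULL, promoters = NULL,
                       beta2 = NULL, expression2 = NULL, probes2 = NULL,
                       gmt = NULL, q_threshold = 0.2,
                       lshape = lshape_config(),
                       ggf_window = 200L, ggf_gc_min = 0.5, ggf_oe_min = 0.6,
                       promoter_window = c(2000L, 500L),
                       n_random_sets = 10L,
                       survival_marker = NULL,
                       survival_rule = "median", seed) {
  if (missing(seed)) stop("run_config requires a seed")
  if (simulate && is.null(sim)) sim <- sim_config(seed = seed)
  stopifnot(q_threshold > 0, q_threshold <= 1, ggf_gc_min >= 0,
            ggf_gc_min <= 1, ggf_oe_min >= 0, n_random_sets >= 1)
  structure(list(out_dir = out_dir, simulate = simulate, sim = sim,
                 beta = beta, expression = expression, probes = probes,
                 samples = samples, promoters = promoters,
                 beta2 = beta2, expression2 = expression2, probes2 = probes2,
                 gmt = gmt, q_threshold = q_threshold, lshape = lshape,
                 ggf_window = as.integer(ggf_window),
                 ggf_gc_min = ggf_gc_min, ggf_oe_min = ggf_oe_min,
                 promoter_window = as.integer(promoter_window),
                 n_random_sets = as.integer(n_random_sets),
                 survival_marker = survival_marker,
                 survival_rule = survival_rule, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys match [run_config()] arguments; `sim:` and `lshape:` may
#' be nested maps of [sim_config()] / [lshape_config()] arguments.
#'
#' @param path YAML path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  if (!is.null(y$sim)) {
    if (is.null(y$sim$seed)) y$sim$seed <- y$seed
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$lshape)) {
    if (!is.null(y$lshape$weight_matrix))
      y$lshape$weight_matrix <- matrix(unlist(y$lshape$weight_matrix),
                                       3, 3, byrow = TRUE)
    y$lshape <- do.call(lshape_config, y$lshape)
  }
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

write_stage_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# methylscreen %s | seed=%d | q_threshold=%g | ggf=%d/%g/%g",
    as.character(utils::packageVersion("methylscreen")), cfg$seed,
    cfg$q_threshold, cfg$ggf_window, cfg$ggf_gc_min, cfg$ggf_oe_min), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate/read, QC, molecular-feature associations, the silencing
#' screen (with optional cross-cohort validation), island calling and
#' enrichment, optional term enrichment, and survival stratification.
#' Per-stage TSVs, a plain-text summary and a log are written under
#' `cfg$out_dir`; a stage failure aborts the run naming the stage.
#'
#' @param cfg a [run_config()].
#' @return A `run_report`: list with `qc`, `associations`, `screen`,
#'   `island_flags`, `enrichment`, `terms` (or NULL), `survival` (or NULL),
#'   `summary_path`, `log` (character vector).
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  note("seed=%d q_threshold=%g ggf=%d/%g/%g promoter_window=-%d/+%d",
       cfg$seed, cfg$q_threshold, cfg$ggf_window, cfg$ggf_gc_min,
       cfg$ggf_oe_min, cfg$promoter_window[1], cfg$promoter_window[2])

  co2 <- NULL
  if (cfg$simulate) {
    co <- stage("simulate", simulate_cohort(cfg$sim))
    if (!is.null(cfg$beta2) || isTRUE(attr(cfg, "simulate_cohort2"))) {
      sim2 <- cfg$sim; sim2$seed <- cfg$sim$seed + 1000L
      co2 <- stage("simulate", simulate_cohort(
        sim2, gene_classes = attr(co$probes, "gene_class")))
    }
    note("simulated cohort: %d probes x %d samples", nrow(co$beta),
         ncol(co$beta))
  } else {
    co <- stage("read_inputs", {
      for (p in c(cfg$beta, cfg$expression, cfg$probes, cfg$samples))
        if (!file.exists(p)) stop("input file not found: ", p)
      list(beta = read_matrix(cfg$beta, "beta"),
           expr = read_matrix(cfg$expression, "expression"),
           probes = read_probe_annotation(cfg$probes),
           samples = read_sample_annotation(cfg$samples),
           promoters = if (!is.null(cfg$promoters))
             read_promoter_fasta(cfg$promoters) else NULL,
           marker_gene = cfg$survival_marker)
    })
    if (!is.null(cfg$beta2)) {
      co2 <- stage("read_inputs", list(
        beta = read_matrix(cfg$beta2, "beta"),
        expr = read_matrix(cfg$expression2, "expression"),
        probes = read_probe_annotation(cfg$probes2)))
    }
  }

  qc <- stage("qc", qc_controls(co$beta, co$samples))
  note("qc: %d flags", length(qc$flags))

  assoc <- stage("associations", {
    out <- list()
    feats <- c("msi", paste0("mutation:", MUTATION_GENES))
    for (f in feats) {
      r <- tryCatch(feature_association(co$beta, co$samples, f),
                    error = function(e) NULL)
      if (!is.null(r)) out[[f]] <- r
    }
    g <- tryCatch(growth_association(co$beta, co$samples),
                  error = function(e) NULL)
    if (!is.null(g)) out[["doubling_time"]] <- g
    out
  })
  note("associations tested: %s", paste(names(assoc), collapse = ", "))

  scr <- stage("screen", silencing_screen(
    co$beta, co$expr, co$probes,
    beta2 = if (!is.null(co2)) co2$beta else NULL,
    expr2 = if (!is.null(co2)) co2$expr else NULL,
    probes2 = if (!is.null(co2)) co2$probes else NULL,
    q_threshold = cfg$q_threshold, lshape_cfg = cfg$lshape))
  note("screen: %d tested, %d candidates", scr$counts$n_tested,
       scr$counts$n_candidates)

  island_flags <- NULL; enr <- NULL
  if (!is.null(co$promoters)) {
    island_flags <- stage("islands", {
      calls <- ggf_scan(co$promoters, window_min = cfg$ggf_window,
                        gc_min = cfg$ggf_gc_min, oe_min = cfg$ggf_oe_min)
      write_stage_tsv(as.data.frame(calls),
                      file.path(cfg$out_dir, "islands.tsv"), cfg)
      associate_islands(calls, co$promoters, cfg$promoter_window)
    })
    scr$table$island_flag <- unname(island_flags[scr$table$gene_symbol])
    target <- scr$table$gene_symbol[
      if (!is.null(scr$validation)) scr$table$validated_flag %in% TRUE
      else scr$table$candidate_flag %in% TRUE]
    if (length(target) > 0) {
      enr <- stage("enrich", island_enrichment(
        island_flags[scr$table$gene_symbol], target,
        n_random_sets = cfg$n_random_sets, seed = cfg$seed))
      note("island enrichment: observed %.1f%% vs baseline %.1f%%",
           100 * enr$observed_fraction, 100 * enr$baseline_fraction)
    }
  }

  terms <- NULL
  if (!is.null(cfg$gmt)) {
    terms <- stage("terms", {
      target <- scr$table$gene_symbol[scr$table$candidate_flag %in% TRUE]
      enrich_terms(target, read_gmt(cfg$gmt), scr$table$gene_symbol,
                   q_threshold = cfg$q_threshold)
    })
  }

  surv <- NULL
  marker <- cfg$survival_marker
  if (is.null(marker)) marker <- co$marker_gene
  if (!is.null(marker) && !is.na(marker) &&
      any(!is.na(co$samples$survival_time))) {
    surv <- stage("survival", survival_stratify(
      co$expr, co$samples, marker, rule = cfg$survival_rule))
    note("survival (%s, %s split): log-rank p = %.4g", marker,
         cfg$survival_rule, surv$test$p_value)
  }

  write_stage_tsv(as.data.frame(scr$table),
                  file.path(cfg$out_dir, "screen.tsv"), cfg)
  summary_path <- file.path(cfg$out_dir, "summary.txt")
  writeLines(run_summary_text(cfg, qc, assoc, scr, enr, terms, surv),
             summary_path)
  writeLines(log, file.path(cfg$out_dir, "log.txt"))
  structure(list(qc = qc, associations = assoc, screen = scr,
                 island_flags = island_flags, enrichment = enr,
                 terms = terms, survival = surv,
                 summary_path = summary_path, log = log),
            class = "run_report")
}

run_summary_text <- function(cfg, qc, assoc, scr, enr, terms, surv) {
  out <- c(sprintf("methylscreen run summary (seed %d)", cfg$seed), "")
  out <- c(out, "[qc]",
           sprintf("  flags: %d", length(qc$flags)),
           paste0("  ", qc$flags))
  out <- c(out, "", "[associations]")
  for (nm in names(assoc)) {
    a <- assoc[[nm]]
    out <- c(out, sprintf("  %s: estimate=%.4f p=%.4g%s", nm, a$estimate,
                          a$p_value,
                          if (!is.null(attr(a, "higher")))
                            paste0(" (higher: ", attr(a, "higher"), ")")
                          else ""))
  }
  ct <- scr$counts
  out <- c(out, "", "[screen]",
           sprintf("  tested: %d", ct$n_tested),
           sprintf("  correlation hits: %d (%.2f%%)", ct$n_corr_hits,
                   100 * ct$frac_corr_hits),
           sprintf("  L-shape only: %d", ct$n_l_only),
           sprintf("  candidates: %d (%.2f%%)", ct$n_candidates,
                   100 * ct$frac_candidates))
  if (!is.null(scr$validation)) {
    v <- scr$validation
    out <- c(out,
             sprintf("  cohort-2 availability: %d/%d (%.1f%%)",
                     v$n_available, v$n_candidates,
                     100 * v$availability_fraction),
             sprintf("  validated: %d/%d (%.1f%%)", v$n_validated,
                     v$n_available, 100 * v$validated_fraction))
  }
  if (!is.null(enr)) {
    out <- c(out, "", "[islands]",
             sprintf("  observed island fraction: %.1f%%",
                     100 * enr$observed_fraction),
             sprintf("  resampled baseline (%d sets): %.1f%%",
                     enr$n_random_sets, 100 * enr$baseline_fraction),
             sprintf("  Fisher p: %.4g; hypergeometric p: %.4g",
                     enr$fisher$p_value, enr$hypergeom$p_value))
  }
  if (!is.null(terms)) {
    out <- c(out, "", "[terms]",
             sprintf("  enriched terms (q < %g): %d",
                     attr(terms, "q_threshold"), sum(terms$enriched)))
  }
  if (!is.null(surv)) {
    out <- c(out, "", "[survival]",
             sprintf("  marker %s (%s split): log-rank chi-square=%.3f p=%.4g",
                     surv$marker_gene, surv$rule, surv$test$statistic,
                     surv$test$p_value))
  }
  out
}
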