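# Cohort-level methylation summaries, control QC and molecular-feature
# association tests.

#' Summarise a methylation cohort
#'
#' Per-sample and per-probe mean betas (missing values ignored), the
#' cohort-wide range of sample means, and a histogram of per-probe means.
#' Histogram bins are closed on the left and open on the right, except the
#' top bin which is closed on both sides.
#'
#' @param beta a [beta_matrix()].
#' @param bins bin edges over [0, 1]; default width 0.1.
#' @return A `cohort_summary`: list with `sample_means`, `range`
#'   (min/max of sample means), `probe_means`, `histogram` (data.frame of
#'   bin edges and fraction of probes), `frac_below_02`, `frac_above_05`.
#' @export
summarize_cohort <- function(beta, bins = seq(0, 1, by = 0.1)) {
  if (nrow(beta) == 0 || ncol(beta) == 0) stop("empty beta matrix")
  v <- unclass(beta)
  sample_means <- colMeans(v, na.rm = TRUE)
  probe_means <- rowMeans(v, na.rm = TRUE)
  pm <- probe_means[!is.na(probe_means)]
  nb <- length(bins) - 1L
  counts <- integer(nb)
  for (i in seq_len(nb)) {
    counts[i] <- if (i < nb) sum(pm >= bins[i] & pm < bins[i + 1]) else
      sum(pm >= bins[i] & pm <= bins[i + 1])
  }
  structure(list(
    sample_means = sample_means,
    range = c(min = min(sample_means), max = max(sample_means)),
    probe_means = probe_means,
    histogram = data.frame(lower = bins[-length(bins)], upper = bins[-1],
                           fraction = counts / length(pm)),
    frac_below_02 = mean(pm < 0.2),
    frac_above_05 = mean(pm > 0.5)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0("cohort_summary: %d samples, %d probes\n",
                     "  sample mean beta range: %.3f - %.3f\n",
                     "  probes with mean < 0.2: %.1f%%; mean > 0.5: %.1f%%\n"),
              length(x$sample_means), length(x$probe_means),
              x$range["min"], x$range["max"],
              100 * x$frac_below_02, 100 * x$frac_above_05))
  invisible(x)
}

#' Control-sample and replicate QC
#'
#' Mean beta for each control sample and Pearson r over probes for each
#' replicate pair. Flags are raised when the unmethylated control mean
#' exceeds `neg_max`, a methylated control mean falls below `pos_min`, or a
#' replicate correlation falls below `r_min`.
#'
#' @param beta a [beta_matrix()].
#' @param annot a [sample_annotation()] covering the beta samples.
#' @param neg_max,pos_min,r_min QC thresholds.
#' @return A `qc_report`: list with `controls` (data.frame sample_id, role,
#'   mean_beta, flagged), `replicates` (data.frame sample_id, reference, r,
#'   flagged), and `flags` (character vector of raised flags).
#' @export
qc_controls <- function(beta, annot, neg_max = 0.15, pos_min = 0.7,
                        r_min = 0.95) {
  v <- unclass(beta)
  annot <- annot[annot$sample_id %in% colnames(v), , drop = FALSE]
  is_ctrl <- annot$control_role %in% c("unmethylated_control",
                                       "methylated_control")
  ctrl <- annot[is_ctrl, , drop = FALSE]
  flags <- character(0)
  controls <- data.frame(sample_id = character(0), role = character(0),
                         mean_beta = numeric(0), flagged = logical(0))
  if (nrow(ctrl) > 0) {
    mb <- colMeans(v[, ctrl$sample_id, drop = FALSE], na.rm = TRUE)
    bad <- ifelse(ctrl$control_role == "unmethylated_control",
                  mb > neg_max, mb < pos_min)
    controls <- data.frame(sample_id = ctrl$sample_id,
                           role = ctrl$control_role,
                           mean_beta = unname(mb), flagged = bad,
                           stringsAsFactors = FALSE)
    flags <- c(flags, sprintf("control %s (%s): mean beta %.3f out of range",
                              ctrl$sample_id[bad], ctrl$control_role[bad],
                              mb[bad]))
  }
  is_rep <- grepl("^replicate_of:", annot$control_role)
  reps <- annot[is_rep, , drop = FALSE]
  replicates <- data.frame(sample_id = character(0), reference = character(0),
                           r = numeric(0), flagged = logical(0))
  if (nrow(reps) > 0) {
    ref <- sub("^replicate_of:", "", reps$control_role)
    r <- vapply(seq_len(nrow(reps)), function(i) {
      if (!ref[i] %in% colnames(v)) return(NA_real_)
      pearson_test(v[, reps$sample_id[i]], v[, ref[i]])$estimate
    }, numeric(1))
    bad <- !is.na(r) & r < r_min
    replicates <- data.frame(sample_id = reps$sample_id, reference = ref,
                             r = r, flagged = bad, stringsAsFactors = FALSE)
    flags <- c(flags, sprintf("replicate %s vs %s: r = %.4f below %.2f",
                              reps$sample_id[bad], ref[bad], r[bad], r_min))
  }
  structure(list(controls = controls, replicates = replicates, flags = flags),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("methylation QC\n")
  if (nrow(x$controls) > 0) print.data.frame(x$controls, row.names = FALSE)
  if (nrow(x$replicates) > 0) print.data.frame(x$replicates, row.names = FALSE)
  if (length(x$flags) == 0) cat("  no flags raised\n")
  else cat(paste0("  FLAG: ", x$flags, "\n"), sep = "")
  invisible(x)
}

#' Association between global methylation and a molecular feature
#'
#' Two-sample t-test on per-sample mean beta between the two levels of a
#' feature: MSI vs MSS, or mutant vs wild type for one of the mutation-flag
#' genes. Samples with unknown status and control samples are excluded.
#'
#' @param beta a [beta_matrix()].
#' @param annot a [sample_annotation()].
#' @param feature `"msi"` or `"mutation:<GENE>"` (e.g. `"mutation:APC"`).
#' @param cohort restrict to `"cell_line"`, `"tumor"`, or `NULL` for all.
#' @param welch use Welch's t instead of pooled.
#' @return An `ms_test` with attributes `group_means` (named means) and
#'   `higher` (which level has the higher mean beta).
#' @export
feature_association <- function(beta, annot, feature = "msi", cohort = NULL,
                                welch = FALSE) {
  v <- unclass(beta)
  annot <- annot[annot$sample_id %in% colnames(v) &
                   annot$control_role == "none", , drop = FALSE]
  if (!is.null(cohort)) annot <- annot[annot$cohort %in% cohort, , drop = FALSE]
  if (feature == "msi") {
    lev <- c("MSI", "MSS"); grp <- annot$msi_status
  } else if (grepl("^mutation:", feature)) {
    g <- sub("^mutation:", "", feature)
    col <- paste0("mut_", g)
    if (!col %in% names(annot)) stop("no mutation flag for gene ", g)
    lev <- c("mut", "wt"); grp <- annot[[col]]
  } else stop("feature must be 'msi' or 'mutation:<GENE>'")
  mb <- colMeans(v[, annot$sample_id, drop = FALSE], na.rm = TRUE)
  a <- mb[grp == lev[1]]; b <- mb[grp == lev[2]]
  if (length(a) < 2 || length(b) < 2)
    stop(sprintf("need >=2 samples per %s level (%d vs %d)",
                 feature, length(a), length(b)))
  res <- two_sample_t(a, b, welch = welch)
  gm <- c(mean(a), mean(b)); names(gm) <- lev
  attr(res, "group_means") <- gm
  attr(res, "higher") <- lev[which.max(gm)]
  res
}

#' Association between global methylation and growth rate
#'
#' Correlation between per-sample mean beta and doubling time (pairwise
#' complete). A negative correlation means hypermethylated samples divide
#' faster.
#'
#' @param beta a [beta_matrix()].
#' @param annot a [sample_annotation()] with `doubling_time`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An `ms_test`.
#' @export
growth_association <- function(beta, annot, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- unclass(beta)
  annot <- annot[annot$sample_id %in% colnames(v) &
                   annot$control_role == "none", , drop = FALSE]
  mb <- colMeans(v[, annot$sample_id, drop = FALSE], na.rm = TRUE)
  dt <- annot$doubling_time
  if (method == "pearson") pearson_test(mb, dt) else spearman_test(mb, dt)
}
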