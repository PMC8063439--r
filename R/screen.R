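# Per-gene negative-correlation screen, L-shape heuristic, candidate union
# and cross-cohort validation.

#' L-shape heuristic configuration
#'
#' The detector partitions each gene's (beta, expression) scatter into a 3x3
#' grid on the unit square (expression min-max normalised per gene, beta
#' taken as is) and scores the occupancy pattern. The defaults reward the
#' two arms of an "L" -- the high-expression/low-methylation corner and,
#' most strongly, the low-expression/high-methylation corner that is the
#' direct evidence of silencing -- and heavily penalise
#' high-expression/high-beta points, which contradict it. Weights away from
#' the arms are zero or negative so that a scatter confined to the
#' low-methylation column (a promoter that is simply never methylated)
#' cannot reach the score threshold: an L-call requires the methylated,
#' silenced arm to be populated.
#'
#' @param x_cuts,y_cuts two strictly increasing cut points in (0, 1) for the
#'   beta and expression axes.
#' @param weight_matrix 3x3 weights, rows top-to-bottom by decreasing
#'   expression, columns left-to-right by increasing beta.
#' @param min_points genes with fewer points are reported untested.
#' @param max_topright_frac maximum tolerated fraction of points in the
#'   top-right (high expression, high beta) cell.
#' @param score_threshold minimum mean cell weight for a flag.
#' @return list of class `lshape_config`.
#' @export
lshape_config <- function(x_cuts = c(1 / 3, 2 / 3), y_cuts = c(1 / 3, 2 / 3),
                          weight_matrix = matrix(c(1, -1, -10,
                                                   -1, 0, -2,
                                                   0, 1, 3),
                                                 3, 3, byrow = TRUE),
                          min_points = 10L, max_topright_frac = 0.05,
                          score_threshold = 0.25) {
  stopifnot(length(x_cuts) == 2, length(y_cuts) == 2,
            all(diff(x_cuts) > 0), all(diff(y_cuts) > 0),
            all(x_cuts > 0 & x_cuts < 1), all(y_cuts > 0 & y_cuts < 1),
            is.matrix(weight_matrix), all(dim(weight_matrix) == 3),
            all(is.finite(weight_matrix)))
  structure(list(x_cuts = x_cuts, y_cuts = y_cuts,
                 weight_matrix = weight_matrix,
                 min_points = as.integer(min_points),
                 max_topright_frac = max_topright_frac,
                 score_threshold = score_threshold),
            class = "lshape_config")
}

#' Classify one methylation-expression scatter as L-shaped
#'
#' Expression is min-max normalised to [0, 1] over the gene; the unit square
#' is cut into a 3x3 grid. A point sitting exactly on a cut is assigned to
#' the lower-beta / lower-expression cell. The score is the cell-count
#' weighted mean sum(w_rc * n_rc) / N; the flag requires the score to reach
#' `score_threshold` and the top-right cell to hold at most
#' `max_topright_frac` of the points.
#'
#' @param beta,expression paired numeric vectors (incomplete pairs dropped).
#' @param cfg an [lshape_config()].
#' @return list with `score`, `flag`, `counts` (3x3 matrix, rows
#'   top-to-bottom), `n`. Fewer than `min_points` points gives
#'   `score = NA`, `flag = FALSE`, and `tested = FALSE`.
#' @export
lshape_classify <- function(beta, expression, cfg = lshape_config()) {
  cp <- complete_pairs(beta, expression)
  n <- cp$n
  empty <- matrix(0L, 3, 3)
  if (n < cfg$min_points)
    return(list(score = NA_real_, flag = FALSE, counts = empty, n = n,
                tested = FALSE))
  x <- cp$x
  rngy <- range(cp$y)
  y <- if (diff(rngy) == 0) rep(0, n) else (cp$y - rngy[1]) / diff(rngy)
  col <- 1L + (x > cfg$x_cuts[1]) + (x > cfg$x_cuts[2])
  row_bottom_up <- 1L + (y > cfg$y_cuts[1]) + (y > cfg$y_cuts[2])
  row <- 4L - row_bottom_up  # 1 = top (high expression)
  counts <- empty
  for (i in seq_len(n)) counts[row[i], col[i]] <- counts[row[i], col[i]] + 1L
  score <- sum(cfg$weight_matrix * counts) / n
  flag <- score >= cfg$score_threshold &&
    counts[1, 3] / n <= cfg$max_topright_frac
  list(score = score, flag = flag, counts = counts, n = n, tested = TRUE)
}

#' Genome-wide negative-correlation screen
#'
#' Spearman correlation between promoter methylation and expression per gene
#' over the aligned cohort, with one Benjamini-Hochberg adjustment over all
#' tested genes jointly. A gene is a significant-negative hit when rho < 0
#' and q < `q_threshold`. Genes with fewer than 4 complete pairs (or
#' degenerate ranks) are reported untested (NA rho/p/q). In per-probe
#' alignment mode each probe is screened and a gene inherits its most
#' significant probe before the adjustment.
#'
#' @param aligned an [align_cohort()] result.
#' @param q_threshold FDR threshold for the significant-negative call.
#' @return A `gene_screen` data frame: `gene_symbol`, `n_pairs`, `rho`, `p`,
#'   `q`, `sig_neg`, plus NA-initialised `lshape_score`, `lshape_flag`,
#'   `candidate_flag`, `validated_flag`, `island_flag` columns filled by
#'   later stages. Attributes: `q_threshold`, `n_tested`.
#' @export
correlation_screen <- function(aligned, q_threshold = 0.2) {
  stopifnot(inherits(aligned, "aligned_cohort"))
  rows <- rownames(aligned$beta)
  if (length(rows) == 0) stop("empty aligned cohort")
  res <- data.frame(row_id = rows,
                    gene_symbol = unname(aligned$gene_map[rows]),
                    n_pairs = NA_integer_, rho = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(rows)) {
    b <- aligned$beta[i, ]; e <- aligned$expr[i, ]
    ok <- is.finite(b) & is.finite(e)
    res$n_pairs[i] <- sum(ok)
    if (sum(ok) < 4) next
    st <- tryCatch(spearman_test(b[ok], e[ok]), error = function(e) NULL)
    if (is.null(st)) next
    res$rho[i] <- st$estimate
    res$p[i] <- st$p_value
  }
  if (aligned$aggregate == "per_probe") {
    # gene inherits its most significant probe
    keep <- unlist(lapply(split(seq_len(nrow(res)), res$gene_symbol),
                          function(ix) {
                            p <- res$p[ix]
                            if (all(is.na(p))) ix[1] else ix[which.min(p)]
                          }), use.names = FALSE)
    res <- res[sort(keep), , drop = FALSE]
  }
  res <- data.frame(gene_symbol = res$gene_symbol, n_pairs = res$n_pairs,
                    rho = res$rho, p = res$p, stringsAsFactors = FALSE)
  res$q <- bh_adjust(res$p)
  res$sig_neg <- !is.na(res$q) & res$rho < 0 & res$q < q_threshold
  res$lshape_score <- NA_real_
  res$lshape_flag <- NA
  res$candidate_flag <- NA
  res$validated_flag <- NA
  res$island_flag <- NA
  rownames(res) <- NULL
  structure(res, class = c("gene_screen", "data.frame"),
            q_threshold = q_threshold, n_tested = sum(!is.na(res$p)))
}

#' Apply the L-shape heuristic across a screen
#'
#' Runs [lshape_classify()] for every gene in the screen and fills
#' `lshape_score`/`lshape_flag`.
#'
#' @param screen a `gene_screen` from [correlation_screen()].
#' @param aligned the [align_cohort()] result the screen came from (mean
#'   aggregation mode).
#' @param cfg an [lshape_config()].
#' @return the updated `gene_screen`.
#' @export
lshape_screen <- function(screen, aligned, cfg = lshape_config()) {
  stopifnot(inherits(screen, "gene_screen"))
  for (i in seq_len(nrow(screen))) {
    g <- screen$gene_symbol[i]
    if (!g %in% rownames(aligned$beta)) next
    r <- lshape_classify(aligned$beta[g, ], aligned$expr[g, ], cfg)
    screen$lshape_score[i] <- r$score
    screen$lshape_flag[i] <- r$flag
  }
  screen
}

#' Combine correlation hits and L-shape hits into the candidate set
#'
#' Candidates are the union of significant-negative genes and L-shape
#' flagged genes that are not already significant (the L-only stratum is
#' disjoint from the correlation hits by construction).
#'
#' @param screen a `gene_screen` with correlation and L-shape columns filled.
#' @return the screen with `candidate_flag` set and a `screen_counts`
#'   attribute: `n_tested`, `n_corr_hits`, `n_l_only`, `n_candidates`,
#'   `frac_corr_hits`, `frac_candidates` (fractions of the tested universe).
#' @export
build_candidates <- function(screen) {
  stopifnot(inherits(screen, "gene_screen"))
  corr_hit <- screen$sig_neg %in% TRUE
  l_only <- (screen$lshape_flag %in% TRUE) & !corr_hit
  screen$candidate_flag <- corr_hit | l_only
  n_tested <- attr(screen, "n_tested")
  attr(screen, "screen_counts") <- list(
    n_tested = n_tested,
    n_corr_hits = sum(corr_hit),
    n_l_only = sum(l_only),
    n_candidates = sum(screen$candidate_flag),
    frac_corr_hits = sum(corr_hit) / n_tested,
    frac_candidates = sum(screen$candidate_flag) / n_tested)
  screen
}

#' Validate candidates in a second cohort
#'
#' Restricts the candidate list to genes with usable data (>= 4 complete
#' pairs) in the second cohort, re-runs the Spearman screen with a fresh
#' Benjamini-Hochberg adjustment within that restricted set, and calls a
#' candidate validated when rho < 0 and q < `q_threshold` there.
#'
#' @param screen a `gene_screen` with `candidate_flag` set.
#' @param aligned2 the second cohort, aligned independently.
#' @param q_threshold FDR threshold in the validation cohort.
#' @return the screen with `validated_flag` filled (NA for candidates with
#'   no usable cohort-2 data) and a `validation` attribute:
#'   `n_candidates`, `n_available`, `availability_fraction`, `n_validated`,
#'   `validated_fraction` (of the available stratum), and the per-gene
#'   cohort-2 table.
#' @export
cross_cohort_validate <- function(screen, aligned2, q_threshold = 0.2) {
  stopifnot(inherits(screen, "gene_screen"))
  cand <- screen$gene_symbol[screen$candidate_flag %in% TRUE]
  if (length(cand) == 0) stop("no candidates to validate")
  res2 <- correlation_screen(aligned2, q_threshold = q_threshold)
  res2 <- res2[res2$gene_symbol %in% cand & !is.na(res2$p), , drop = FALSE]
  if (nrow(res2) == 0) stop("no candidate has usable data in cohort 2")
  # fresh BH within the restricted candidate set
  res2$q <- bh_adjust(res2$p)
  res2$validated <- res2$rho < 0 & res2$q < q_threshold
  screen$validated_flag <- NA
  i <- match(res2$gene_symbol, screen$gene_symbol)
  screen$validated_flag[i] <- res2$validated
  attr(screen, "validation") <- list(
    n_candidates = length(cand),
    n_available = nrow(res2),
    availability_fraction = nrow(res2) / length(cand),
    n_validated = sum(res2$validated),
    validated_fraction = sum(res2$validated) / nrow(res2),
    cohort2 = res2)
  screen
}

#' Run the full silencing screen on one or two cohorts
#'
#' Convenience wrapper: aligns cohort 1, runs the correlation screen, applies
#' the L-shape heuristic, builds the candidate set, and (when a second
#' cohort is given) validates the candidates there.
#'
#' @param beta,expr,probes cohort-1 matrices and probe annotation.
#' @param beta2,expr2,probes2 optional validation cohort.
#' @param q_threshold FDR threshold used in both cohorts.
#' @param lshape_cfg an [lshape_config()].
#' @param aggregate probe-to-gene aggregation mode, see [align_cohort()].
#' @return A `silencing_screen`: list with `table` (the `gene_screen`),
#'   `counts`, `validation` (or NULL), `aligned`.
#' @export
silencing_screen <- function(beta, expr, probes,
                             beta2 = NULL, expr2 = NULL, probes2 = NULL,
                             q_threshold = 0.2,
                             lshape_cfg = lshape_config(),
                             aggregate = "mean") {
  aligned <- align_cohort(beta, expr, probes, aggregate = aggregate)
  scr <- correlation_screen(aligned, q_threshold = q_threshold)
  al_mean <- if (aggregate == "mean") aligned else
    align_cohort(beta, expr, probes, aggregate = "mean")
  scr <- lshape_screen(scr, al_mean, lshape_cfg)
  scr <- build_candidates(scr)
  validation <- NULL
  if (!is.null(beta2)) {
    aligned2 <- align_cohort(beta2, expr2, probes2, aggregate = aggregate)
    scr <- cross_cohort_validate(scr, aligned2, q_threshold = q_threshold)
    validation <- attr(scr, "validation")
  }
  structure(list(table = scr, counts = attr(scr, "screen_counts"),
                 validation = validation, aligned = aligned,
                 q_threshold = q_threshold),
            class = "silencing_screen")
}

#' @export
print.silencing_screen <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(paste0(
    "silencing screen: %d genes tested\n",
    "  significant negative correlation (q < %g): %d (%.1f%%)\n",
    "  L-shape only: %d\n",
    "  candidates: %d (%.1f%%)\n"),
    ct$n_tested, x$q_threshold, ct$n_corr_hits, 100 * ct$frac_corr_hits,
    ct$n_l_only, ct$n_candidates, 100 * ct$frac_candidates))
  if (!is.null(x$validation)) {
    v <- x$validation
    cat(sprintf(paste0(
      "  cohort 2: data available for %d of %d candidates (%.1f%%)\n",
      "  validated: %d of %d (%.1f%%)\n"),
      v$n_available, v$n_candidates, 100 * v$availability_fraction,
      v$n_validated, v$n_available, 100 * v$validated_fraction))
  }
  invisible(x)
}

#' @method summary silencing_screen
#' @export
summary.silencing_screen <- function(object, ...) {
  print(object)
  tab <- object$table
  top <- tab[order(tab$q), , drop = FALSE]
  cat("\ntop genes by q:\n")
  print(utils::head(top[, c("gene_symbol", "n_pairs", "rho", "p", "q",
                            "candidate_flag")], 10), row.names = FALSE)
  invisible(object)
}
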