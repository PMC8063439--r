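# Gardiner-Garden-Frommer CpG island calling over promoter sequences,
# island-gene association, and resampling enrichment.

#' GC fraction of a window
#'
#' (#C + #G) / (non-N length); N bases are excluded from both numerator and
#' denominator.
#'
#' @param window DNA string over A/C/G/T/N.
#' @return fraction in [0, 1] (NaN for an all-N window).
#' @examples
#' gc_fraction("ANGC")  # 2/3
#' @export
gc_fraction <- function(window) {
  if (nchar(window) == 0) stop("empty window")
  ch <- strsplit(toupper(window), "")[[1]]
  nn <- sum(ch != "N")
  sum(ch %in% c("C", "G")) / nn
}

#' Observed/expected CpG ratio of a window
#'
#' (#CG dinucleotides x window length) / (#C x #G), with CG counted at every
#' overlapping position; defined as 0 when the window has no C or no G.
#'
#' @param window DNA string.
#' @return non-negative ratio.
#' @examples
#' obs_exp_cpg("CGCG")  # 2
#' @export
obs_exp_cpg <- function(window) {
  if (nchar(window) == 0) stop("empty window")
  ch <- strsplit(toupper(window), "")[[1]]
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  if (nc == 0 || ng == 0) return(0)
  n <- length(ch)
  ncg <- sum(ch[-n] == "C" & ch[-1] == "G")
  ncg * n / (nc * ng)
}

#' Scan a sequence for Gardiner-Garden-Frommer CpG islands
#'
#' Slides windows of `window_min` bp (step `step`); a window qualifies when
#' its GC fraction is at least `gc_min` and its Obs/Exp CpG ratio at least
#' `oe_min`. Overlapping or adjacent qualifying windows are merged into
#' maximal islands. Because a union of qualifying windows need not itself
#' satisfy the thresholds, each merged island re-reports GC and Obs/Exp over
#' its full span together with a `merged_pass` column; islands are reported
#' under the union-of-windows convention either way.
#'
#' @param sequence one DNA string, or a [promoter_set()] (each sequence is
#'   scanned and results carry `gene_symbol`).
#' @param window_min,gc_min,oe_min,step GGF parameters (classical defaults
#'   200 bp, 50% GC, 0.6 Obs/Exp).
#' @return data.frame of class `island_calls`: `start`, `end` (0-based
#'   half-open within the sequence), `gc_fraction`, `obs_exp` (merged span),
#'   `merged_pass`, and `gene_symbol` when a promoter set was given.
#'   Sequences shorter than `window_min` yield no calls.
#' @export
ggf_scan <- function(sequence, window_min = 200L, gc_min = 0.5,
                     oe_min = 0.6, step = 1L) {
  if (inherits(sequence, "promoter_set")) {
    out <- lapply(seq_len(nrow(sequence)), function(i) {
      df <- ggf_scan(sequence$sequence[i], window_min, gc_min, oe_min, step)
      if (nrow(df) > 0) df$gene_symbol <- sequence$gene_symbol[i]
      df
    })
    out <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
    if (is.null(out))
      out <- data.frame(start = integer(0), end = integer(0),
                        gc_fraction = numeric(0), obs_exp = numeric(0),
                        merged_pass = logical(0), gene_symbol = character(0))
    class(out) <- c("island_calls", "data.frame")
    return(out)
  }
  ch <- strsplit(toupper(sequence), "")[[1]]
  L <- length(ch)
  empty <- structure(data.frame(start = integer(0), end = integer(0),
                                gc_fraction = numeric(0),
                                obs_exp = numeric(0),
                                merged_pass = logical(0)),
                     class = c("island_calls", "data.frame"))
  if (L < window_min) return(empty)
  cum_c <- cumsum(ch == "C"); cum_g <- cumsum(ch == "G")
  cum_n <- cumsum(ch == "N")
  is_cg <- c(ch[-L] == "C" & ch[-1] == "G", FALSE)
  cum_cg <- cumsum(is_cg)
  at <- function(cum, i) {
    i <- pmin(i, L)
    out <- numeric(length(i))
    ok <- i >= 1
    out[ok] <- cum[i[ok]]
    out
  }
  starts <- seq(1L, L - window_min + 1L, by = step)
  ends <- starts + window_min - 1L
  nc <- at(cum_c, ends) - at(cum_c, starts - 1L)
  ng <- at(cum_g, ends) - at(cum_g, starts - 1L)
  nn <- at(cum_n, ends) - at(cum_n, starts - 1L)
  ncg <- at(cum_cg, ends - 1L) - at(cum_cg, starts - 1L)
  non_n <- window_min - nn
  gc <- ifelse(non_n > 0, (nc + ng) / non_n, NaN)
  oe <- ifelse(nc > 0 & ng > 0, ncg * window_min / (nc * ng), 0)
  ok <- !is.na(gc) & gc >= gc_min & oe >= oe_min
  if (!any(ok)) return(empty)
  qs <- starts[ok]; qe <- ends[ok]
  merged <- merge_intervals(qs - 1L, qe)  # to 0-based half-open
  span <- substring(sequence, merged$start + 1L, merged$end)
  gcm <- vapply(span, gc_fraction, numeric(1), USE.NAMES = FALSE)
  oem <- vapply(span, obs_exp_cpg, numeric(1), USE.NAMES = FALSE)
  structure(data.frame(start = merged$start, end = merged$end,
                       gc_fraction = gcm, obs_exp = oem,
                       merged_pass = gcm >= gc_min & oem >= oe_min),
            class = c("island_calls", "data.frame"))
}

# merge overlapping or book-ended [start, end) intervals (inputs sorted by
# start)
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Flag genes whose promoter window overlaps a CpG island
#'
#' A gene is island-associated when any called island overlaps
#' [tss - upstream, tss + downstream) in its promoter sequence coordinates;
#' the window is truncated at the sequence edges.
#'
#' @param islands an `island_calls` data frame with `gene_symbol` (from
#'   [ggf_scan()] on a promoter set).
#' @param promoters the [promoter_set()] that was scanned (provides
#'   `tss_offset` and lengths).
#' @param promoter_window c(upstream, downstream) bp around the TSS.
#' @return named logical vector over the promoter set's genes.
#' @export
associate_islands <- function(islands, promoters,
                              promoter_window = c(2000L, 500L)) {
  stopifnot(inherits(promoters, "promoter_set"))
  flags <- stats::setNames(rep(FALSE, nrow(promoters)),
                           promoters$gene_symbol)
  if (nrow(islands) == 0) return(flags)
  for (i in seq_len(nrow(promoters))) {
    g <- promoters$gene_symbol[i]
    tss <- promoters$tss_offset[i]
    len <- nchar(promoters$sequence[i])
    lo <- max(0L, tss - promoter_window[1])
    hi <- min(len, tss + promoter_window[2])
    isl <- islands[islands$gene_symbol == g, , drop = FALSE]
    flags[g] <- any(isl$start < hi & isl$end > lo)
  }
  flags
}

#' Resampling enrichment of island association in a gene set
#'
#' Compares the island-associated fraction in a target gene set against the
#' mean fraction over `n_random_sets` same-size random draws (without
#' replacement) from the universe. The Fisher exact test uses the 2x2 table
#' of observed flagged/unflagged counts against the resampled baseline
#' expressed as counts of the same set size. Because a small number of
#' random sets is a noisy baseline, the exact hypergeometric comparison of
#' the target against the full universe is always computed as a cross-check.
#'
#' @param flags named logical vector: island association per universe gene.
#' @param target_set character vector of genes, subset of the universe.
#' @param n_random_sets number of random baseline sets.
#' @param seed integer seed for the draws.
#' @return An `enrichment_report`: list with `n_target`, `observed_fraction`,
#'   `baseline_fraction`, `universe_fraction`, `fisher` (vs resampled
#'   baseline), `hypergeom` (vs universe complement), `n_random_sets`.
#' @export
island_enrichment <- function(flags, target_set, n_random_sets = 10L, seed) {
  if (missing(seed)) stop("island_enrichment requires a seed")
  universe <- names(flags)
  if (is.null(universe)) stop("flags must be named by gene")
  if (!all(target_set %in% universe))
    stop("target_set must be a subset of the flag universe")
  nt <- length(target_set)
  if (nt == 0 || nt > length(universe))
    stop("target set size out of range")
  set.seed(seed)
  base_fracs <- vapply(seq_len(n_random_sets), function(i)
    mean(flags[sample(universe, nt)]), numeric(1))
  baseline <- mean(base_fracs)
  obs_flag <- sum(flags[target_set])
  exp_flag <- round(baseline * nt)
  fisher <- fisher_exact_2x2(matrix(c(obs_flag, nt - obs_flag,
                                      exp_flag, nt - exp_flag),
                                    2, 2, byrow = TRUE))
  rest <- setdiff(universe, target_set)
  hyper <- fisher_exact_2x2(matrix(c(obs_flag, nt - obs_flag,
                                     sum(flags[rest]),
                                     length(rest) - sum(flags[rest])),
                                   2, 2, byrow = TRUE))
  structure(list(n_target = nt, observed_fraction = obs_flag / nt,
                 baseline_fraction = baseline,
                 universe_fraction = mean(flags),
                 fisher = fisher, hypergeom = hyper,
                 n_random_sets = n_random_sets),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(paste0(
    "island enrichment: %d target genes\n",
    "  observed island fraction: %.1f%%\n",
    "  resampled baseline (%d sets): %.1f%% (universe %.1f%%)\n",
    "  Fisher vs baseline: p = %s; hypergeometric vs universe: p = %s\n"),
    x$n_target, 100 * x$observed_fraction, x$n_random_sets,
    100 * x$baseline_fraction, 100 * x$universe_fraction,
    format.pval(x$fisher$p_value, digits = 3),
    format.pval(x$hypergeom$p_value, digits = 3)))
  invisible(x)
}
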