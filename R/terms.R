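# Generic annotation-term over-representation for candidate gene lists.

#' Read term annotations from a GMT-style file
#'
#' One term per line: `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return list of terms, each `list(term_id, term_name, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    list(term_id = f[1], term_name = f[2], genes = unique(f[-(1:2)]))
  })
}

#' Term over-representation by Fisher's exact test
#'
#' For each term, a 2x2 Fisher exact test of membership in the target set
#' against membership in the term (both intersected with the universe),
#' followed by one Benjamini-Hochberg adjustment across all tested terms.
#' Enrichment is one-sided by construction: a term is called enriched only
#' when q < `q_threshold` and the odds ratio exceeds 1. This is plain
#' Fisher over-representation; no EASE-style count correction is applied.
#'
#' @param target character vector of genes (subset of `universe`).
#' @param annotations list of terms as returned by [read_gmt()].
#' @param universe background gene set.
#' @param q_threshold FDR threshold for the enriched call.
#' @return data.frame of class `term_enrichment`: `term_id`, `term_name`,
#'   `n_term`, `n_overlap`, `odds_ratio`, `p`, `q`, `enriched`; sorted by p.
#' @export
enrich_terms <- function(target, annotations, universe, q_threshold = 0.2) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  target <- unique(target)
  if (!all(target %in% universe))
    stop("target genes must belong to the universe")
  rows <- lapply(annotations, function(tm) {
    genes <- intersect(tm$genes, universe)
    a <- length(intersect(target, genes))
    b <- length(target) - a
    cc <- length(genes) - a
    d <- length(universe) - length(target) - cc
    ft <- fisher_exact_2x2(matrix(c(a, b, cc, d), 2, 2, byrow = TRUE))
    data.frame(term_id = tm$term_id, term_name = tm$term_name,
               n_term = length(genes), n_overlap = a,
               odds_ratio = ft$estimate, p = ft$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$enriched <- res$q < q_threshold & !is.na(res$odds_ratio) &
    res$odds_ratio > 1
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("term_enrichment", "data.frame"),
            q_threshold = q_threshold)
}
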