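# Domain containers and TSV/FASTA readers-writers.
#
# Matrices are stored features-in-rows, samples-in-columns, mirroring the
# on-disk layout (first row = sample ids, first column = feature ids).
# Coordinates are 0-based half-open everywhere.

#' Beta-value matrix (CpG probes x samples)
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   dimnames; values in [0, 1], NA allowed.
#' @return A `beta_matrix` (a classed matrix).
#' @export
beta_matrix <- function(values) {
  values <- as.matrix(values)
  check_ids(rownames(values), "probe")
  check_ids(colnames(values), "sample")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s': %g",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]))
  structure(values, class = c("beta_matrix", class(matrix())))
}

#' Log2 expression matrix (genes x samples)
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames; NA allowed.
#' @return An `expression_matrix` (a classed matrix).
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  check_ids(rownames(values), "gene")
  check_ids(colnames(values), "sample")
  structure(values, class = c("expression_matrix", class(matrix())))
}

check_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop(sprintf("missing %s identifiers", what))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop(sprintf("duplicated %s identifier: '%s'", what, dup[1]))
  invisible(ids)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Probe annotation table
#'
#' @param probe_id,gene_symbol,chromosome,position equal-length vectors;
#'   `position` is a 0-based coordinate in bp. A gene may own several probes;
#'   probe ids must be unique.
#' @return data.frame of class `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, gene_symbol,
                             chromosome = NA_character_,
                             position = NA_integer_) {
  check_ids(probe_id, "probe")
  df <- data.frame(probe_id = as.character(probe_id),
                   gene_symbol = as.character(gene_symbol),
                   chromosome = as.character(chromosome),
                   position = as.integer(position),
                   stringsAsFactors = FALSE)
  if (any(!is.na(df$position) & df$position < 0))
    stop("positions must be non-negative (0-based)")
  class(df) <- c("probe_annotation", "data.frame")
  df
}

MUTATION_GENES <- c("APC", "BRAF", "TP53", "KRAS", "PIK3CA")

#' Sample annotation table
#'
#' Per-sample metadata: cohort (`cell_line`/`tumor`), MSI status
#' (`MSI`/`MSS`/`unknown`), per-gene mutation flags (`mut`/`wt`/`unknown`
#' columns `mut_APC`, `mut_BRAF`, `mut_TP53`, `mut_KRAS`, `mut_PIK3CA`),
#' doubling time (hours), control role (`none`, `unmethylated_control`,
#' `methylated_control`, or `replicate_of:<sample_id>`), and survival
#' (`survival_time` days, `event` 0/1).
#'
#' @param sample_id unique identifiers; remaining arguments are recycled
#'   per-sample vectors with the defaults shown.
#' @param cohort,msi_status,doubling_time,control_role,survival_time,event
#'   per-sample fields.
#' @param ... mutation flag vectors named `mut_<GENE>`.
#' @return data.frame of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, cohort = "cell_line",
                              msi_status = "unknown",
                              doubling_time = NA_real_,
                              control_role = "none",
                              survival_time = NA_real_, event = NA_integer_,
                              ...) {
  check_ids(sample_id, "sample")
  n <- length(sample_id)
  df <- data.frame(sample_id = as.character(sample_id),
                   cohort = rep_len(cohort, n),
                   msi_status = rep_len(msi_status, n),
                   doubling_time = rep_len(as.numeric(doubling_time), n),
                   control_role = rep_len(control_role, n),
                   survival_time = rep_len(as.numeric(survival_time), n),
                   event = rep_len(as.integer(event), n),
                   stringsAsFactors = FALSE)
  dots <- list(...)
  for (g in MUTATION_GENES) {
    col <- paste0("mut_", g)
    df[[col]] <- if (col %in% names(dots)) rep_len(dots[[col]], n) else "unknown"
  }
  if (!all(df$cohort %in% c("cell_line", "tumor")))
    stop("cohort must be 'cell_line' or 'tumor'")
  if (!all(df$msi_status %in% c("MSI", "MSS", "unknown")))
    stop("msi_status must be MSI, MSS or unknown")
  if (any(!is.na(df$survival_time) & df$survival_time < 0))
    stop("survival_time must be >= 0")
  if (!all(is.na(df$event) | df$event %in% c(0L, 1L)))
    stop("event must be 0, 1 or NA")
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Promoter sequence set
#'
#' @param gene_symbol character vector of gene symbols.
#' @param sequence DNA strings over A/C/G/T/N (upper-cased on construction).
#' @param tss_offset 0-based index of the TSS within each sequence.
#' @return data.frame of class `promoter_set` with columns `gene_symbol`,
#'   `sequence`, `tss_offset`.
#' @export
promoter_set <- function(gene_symbol, sequence, tss_offset = 0L) {
  check_ids(gene_symbol, "gene")
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) == 0)) stop("empty promoter sequence")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    ch <- regmatches(sequence[bad][1],
                     regexpr("[^ACGTN]", sequence[bad][1]))
    stop(sprintf("illegal character '%s' in sequence for gene '%s'",
                 ch, gene_symbol[bad][1]))
  }
  tss_offset <- rep_len(as.integer(tss_offset), length(sequence))
  if (any(tss_offset < 0 | tss_offset >= nchar(sequence)))
    stop("tss_offset must satisfy 0 <= tss_offset < sequence length")
  df <- data.frame(gene_symbol = as.character(gene_symbol),
                   sequence = sequence, tss_offset = tss_offset,
                   stringsAsFactors = FALSE)
  class(df) <- c("promoter_set", "data.frame")
  df
}

#' Read a beta-value or expression matrix from TSV
#'
#' Layout: first row sample ids, first column feature ids, tab-separated.
#' Blank cells become NA. Beta matrices reject values outside [0, 1].
#'
#' @param path file path.
#' @param kind `"beta"` or `"expression"`.
#' @return `beta_matrix` or `expression_matrix`.
#' @export
read_matrix <- function(path, kind = c("beta", "expression")) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs a feature column plus >=1 sample")
  ids <- raw[[1]]
  check_ids(ids, if (kind == "beta") "probe" else "gene")
  check_ids(colnames(raw)[-1], "sample")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals == ""] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, , drop = FALSE]]))
  dimnames(num) <- list(ids, colnames(vals))
  if (kind == "beta") beta_matrix(num) else expression_matrix(num)
}

#' Write a matrix to TSV (round-trip safe)
#'
#' @param x a `beta_matrix` or `expression_matrix` (any named matrix works).
#' @param path output path.
#' @param feature_col header of the first (feature id) column.
#' @export
write_matrix <- function(x, path, feature_col = "feature_id") {
  df <- data.frame(rownames(x), format(unclass(x), digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[df == "NA"] <- ""
  colnames(df) <- c(feature_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe and sample annotation tables from TSV
#'
#' `read_probe_annotation` requires columns `probe_id` and `gene_symbol`
#' (`chromosome`, `position` optional); `read_sample_annotation` requires
#' `sample_id`, all other [sample_annotation()] columns optional.
#'
#' @param path TSV path.
#' @return the corresponding annotation object.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% names(df)))
    stop("probe annotation needs columns: ", paste(need, collapse = ", "))
  probe_annotation(df$probe_id, df$gene_symbol,
                   chromosome = if ("chromosome" %in% names(df)) df$chromosome else NA,
                   position = if ("position" %in% names(df)) df$position else NA)
}

#' @rdname read_probe_annotation
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("sample annotation needs a sample_id column")
  get <- function(col, default) if (col %in% names(df)) df[[col]] else default
  args <- list(sample_id = df$sample_id,
               cohort = get("cohort", "cell_line"),
               msi_status = get("msi_status", "unknown"),
               doubling_time = get("doubling_time", NA_real_),
               control_role = get("control_role", "none"),
               survival_time = get("survival_time", NA_real_),
               event = get("event", NA_integer_))
  for (g in MUTATION_GENES) {
    col <- paste0("mut_", g)
    if (col %in% names(df)) args[[col]] <- df[[col]]
  }
  do.call(sample_annotation, args)
}

#' Read promoter sequences from FASTA
#'
#' Headers are `>GENE [tss=<int>]`; a missing `tss=` key defaults to 0.
#' Sequences are upper-cased and restricted to A/C/G/T/N.
#'
#' @param path FASTA path (multi-line records allowed).
#' @return a [promoter_set()].
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path)
  if (any(Biostrings::width(ss) == 0))
    stop("empty FASTA record: ", names(ss)[Biostrings::width(ss) == 0][1])
  headers <- names(ss)
  gene <- sub("\\s.*$", "", headers)
  tss <- rep(0L, length(headers))
  has_tss <- grepl("tss=[0-9]+", headers)
  tss[has_tss] <- as.integer(sub(".*tss=([0-9]+).*", "\\1",
                                 headers[has_tss]))
  promoter_set(gene, as.character(ss), tss)
}

#' Write promoter sequences to FASTA
#'
#' @param promoters a [promoter_set()].
#' @param path output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- sprintf("%s tss=%d", promoters$gene_symbol,
                       promoters$tss_offset)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Pair promoter methylation with expression per gene
#'
#' Maps probes to genes via the annotation, restricts to samples present in
#' both matrices and to genes with at least one probe and an expression row,
#' and summarises each gene's promoter methylation per sample.
#'
#' With `aggregate = "mean"` (default) a gene's promoter beta in a sample is
#' the unweighted mean of its probes' non-missing betas; a sample contributes
#' only if at least one probe is non-missing. With `aggregate = "per_probe"`
#' every probe is kept as its own row (downstream screens then assign a gene
#' its most significant probe).
#'
#' @param beta a [beta_matrix()].
#' @param expr an [expression_matrix()].
#' @param probes a [probe_annotation()].
#' @param aggregate `"mean"` or `"per_probe"`.
#' @return An `aligned_cohort`: list with `beta` and `expr` matrices over the
#'   same rows/columns (rows genes, or probes in per-probe mode with a
#'   `gene_map`), `samples`, `genes`, and retention counts
#'   (`n_promoters_annotated`, `n_genes_retained`, `retained_fraction`).
#' @export
align_cohort <- function(beta, expr, probes, aggregate = c("mean", "per_probe")) {
  aggregate <- match.arg(aggregate)
  samples <- intersect(colnames(beta), colnames(expr))
  if (length(samples) == 0) stop("no samples shared between beta and expression")
  probes <- probes[probes$probe_id %in% rownames(beta), , drop = FALSE]
  annotated_genes <- unique(probes$gene_symbol)
  genes <- intersect(annotated_genes, rownames(expr))
  if (length(genes) == 0) stop("no genes shared via the probe annotation")
  probes <- probes[probes$gene_symbol %in% genes, , drop = FALSE]
  b <- unclass(beta)[probes$probe_id, samples, drop = FALSE]
  if (aggregate == "mean") {
    g <- factor(probes$gene_symbol, levels = genes)
    bsum <- rowsum(ifelse(is.na(b), 0, b), g, na.rm = FALSE)
    bn <- rowsum((!is.na(b)) + 0, g)
    bm <- bsum / bn
    bm[bn == 0] <- NA_real_
    rows <- genes
    gene_map <- stats::setNames(genes, genes)
  } else {
    bm <- b
    rows <- probes$probe_id
    gene_map <- stats::setNames(probes$gene_symbol, probes$probe_id)
  }
  e <- unclass(expr)[gene_map[rows], samples, drop = FALSE]
  rownames(e) <- rows
  structure(list(beta = bm, expr = e, samples = samples, genes = genes,
                 gene_map = gene_map, aggregate = aggregate,
                 n_promoters_annotated = length(annotated_genes),
                 n_genes_retained = length(genes),
                 retained_fraction = length(genes) / length(annotated_genes)),
            class = "aligned_cohort")
}

#' @export
print.aligned_cohort <- function(x, ...) {
  cat(sprintf(paste0("aligned_cohort: %d genes x %d samples (%s mode)\n",
                     "  %d of %d annotated promoters retained (%.2f%%)\n"),
              x$n_genes_retained, length(x$samples), x$aggregate,
              x$n_genes_retained, x$n_promoters_annotated,
              100 * x$retained_fraction))
  invisible(x)
}
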