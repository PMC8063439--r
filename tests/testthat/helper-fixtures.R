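# Small in-code fixtures shared across the suite.

tiny_beta <- function() {
  beta_matrix(matrix(c(0.1, 0.9, 0.2, 0.8), 2, 2,
                     dimnames = list(c("cg1", "cg2"), c("S1", "S2"))))
}

# minimal two-gene cohort: geneA has two probes, geneB one
tiny_cohort <- function() {
  b <- beta_matrix(matrix(c(0.2, 0.4, 0.1,
                            0.6, 0.8, 0.9,
                            0.3, 0.5, 0.7), 3, 3, byrow = TRUE,
                          dimnames = list(c("cg1", "cg2", "cg3"),
                                          c("S1", "S2", "S3"))))
  e <- expression_matrix(matrix(c(5, 4, 3,
                                  8, 7, 6), 2, 3, byrow = TRUE,
                                dimnames = list(c("geneA", "geneB"),
                                                c("S1", "S2", "S3"))))
  p <- probe_annotation(c("cg1", "cg2", "cg3"),
                        c("geneA", "geneA", "geneB"))
  list(beta = b, expr = e, probes = p)
}

small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(list(n_samples_cellline = 20L, n_genes = 120L,
                                 probes_per_gene = 2L, seed = seed),
                            list(...))
  do.call(sim_config, args)
}

# independent brute-force GGF oracle: enumerate every window with the scalar
# primitives, then merge qualifying intervals with a simple sweep
ggf_brute <- function(s, window_min = 200L, gc_min = 0.5, oe_min = 0.6) {
  L <- nchar(s)
  if (L < window_min) return(data.frame(start = integer(0), end = integer(0)))
  qual <- list()
  for (st in 1:(L - window_min + 1)) {
    w <- substr(s, st, st + window_min - 1)
    if (gc_fraction(w) >= gc_min && obs_exp_cpg(w) >= oe_min)
      qual[[length(qual) + 1]] <- c(st - 1L, st - 1L + window_min)
  }
  if (length(qual) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  iv <- do.call(rbind, qual)
  out <- list(iv[1, ])
  for (i in seq_len(nrow(iv))[-1]) {
    last <- out[[length(out)]]
    if (iv[i, 1] <= last[2])
      out[[length(out)]] <- c(last[1], max(last[2], iv[i, 2]))
    else out[[length(out) + 1]] <- iv[i, ]
  }
  iv <- do.call(rbind, out)
  data.frame(start = iv[, 1], end = iv[, 2])
}

random_gc_seq <- function(len, p_gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2)),
        collapse = "")
}
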