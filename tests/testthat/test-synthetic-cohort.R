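# Generator: determinism, control anchoring, planted structure.

test_that("generation is deterministic given the seed and varies across seeds", {
  cfg <- small_sim(seed = 5)
  a <- simulate_methylation(cfg)
  b <- simulate_methylation(cfg)
  expect_identical(unclass(a$beta), unclass(b$beta))
  ea <- simulate_expression(cfg, a)
  eb <- simulate_expression(cfg, b)
  expect_identical(unclass(ea$expr), unclass(eb$expr))

  other <- simulate_methylation(small_sim(seed = 6))
  expect_false(identical(unclass(a$beta), unclass(other$beta)))
})

test_that("control samples hit their anchored means and the replicate correlates", {
  meth <- simulate_methylation(sim_config(seed = 11))
  v <- unclass(meth$beta)
  roles <- meth$samples$control_role
  neg <- meth$samples$sample_id[roles == "unmethylated_control"]
  pos <- meth$samples$sample_id[roles == "methylated_control"]
  expect_lt(abs(mean(v[, neg]) - 0.05), 0.02)
  expect_lt(abs(mean(v[, pos]) - 0.86), 0.03)

  rep_i <- grepl("^replicate_of:", roles)
  ref <- sub("^replicate_of:", "", roles[rep_i])
  r <- pearson_test(v[, meth$samples$sample_id[rep_i]], v[, ref])$estimate
  expect_gt(r, 0.99)
})

test_that("msi_beta_shift = 0 leaves MSI and MSS exchangeable", {
  reps <- 40
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    m <- simulate_methylation(sim_config(n_samples_cellline = 20L,
                                         n_genes = 60L, probes_per_gene = 1L,
                                         msi_beta_shift = 0, seed = 100 + i))
    pvals[i] <- feature_association(m$beta, m$samples, "msi")$p_value
  }
  # under the null the rejection rate stays near alpha
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals), 0.25)
})

test_that("planted monotone genes approach rho = -1 as noise vanishes", {
  cfg <- small_sim(seed = 2, noise_sd_expr = 1e-9)
  meth <- simulate_methylation(cfg)
  ex <- simulate_expression(cfg, meth)
  al <- align_cohort(meth$beta, ex$expr,
                     meth$probes)
  mono <- ex$truth$gene_symbol[ex$truth$class == "monotone"]
  rhos <- vapply(mono, function(g)
    spearman_test(al$beta[g, colnames(ex$expr)],
                  al$expr[g, colnames(ex$expr)])$estimate, numeric(1))
  expect_true(all(rhos < -0.999))
})

test_that("null-gene screen p-values are approximately uniform", {
  cfg <- sim_config(n_samples_cellline = 30L, n_genes = 1000L,
                    probes_per_gene = 1L, frac_silenced_monotone = 0,
                    frac_silenced_lshape = 0, seed = 21)
  meth <- simulate_methylation(cfg)
  ex <- simulate_expression(cfg, meth)
  al <- align_cohort(meth$beta, ex$expr, meth$probes)
  scr <- correlation_screen(al)
  p <- scr$p[!is.na(scr$p)]
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_dev <- max(abs(vapply(grid, function(g) mean(p <= g) - g, numeric(1))))
  expect_lt(ecdf_dev, 0.05)
})

test_that("planted island segments satisfy GGF and are found by the scanner", {
  cfg <- small_sim(seed = 3, n_genes = 30L, island_fraction = 0.5)
  pr <- simulate_promoters(cfg, sprintf("G%02d", 1:30))
  truth <- pr$truth
  calls <- ggf_scan(pr$promoters)
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_symbol[i]
    hits <- calls[calls$gene_symbol == g, , drop = FALSE]
    if (truth$has_island[i]) {
      expect_true(any(hits$start < truth$island_end[i] &
                        hits$end > truth$island_start[i]))
    } else {
      expect_equal(nrow(hits), 0)  # CpG-free background
    }
  }

  all_isl <- simulate_promoters(small_sim(seed = 4, island_fraction = 1),
                                sprintf("H%02d", 1:10))
  expect_true(all(all_isl$truth$has_island))
})

test_that("survival generator respects the censoring edge cases", {
  cfg <- small_sim(seed = 8, censoring_rate = 1)
  meth <- simulate_methylation(cfg)
  ex <- simulate_expression(cfg, meth)
  g <- ex$truth$gene_symbol[1]
  sa <- simulate_survival(cfg, ex$expr, g, meth$samples)
  done <- !is.na(sa$event)
  expect_true(all(sa$event[done] == 0))
  km <- km_estimate(sa$survival_time[done], sa$event[done])
  expect_equal(nrow(km), 0)  # curve never drops

  cfg0 <- small_sim(seed = 8, censoring_rate = 0)
  sa0 <- simulate_survival(cfg0, ex$expr, g, meth$samples)
  expect_true(all(sa0$event[!is.na(sa0$event)] == 1))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(seed = 1, frac_silenced_monotone = 0.8,
                          frac_silenced_lshape = 0.3), "sum to more than 1")
  expect_error(sim_config(seed = 1, msi_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(seed = 1, control_means = c(0.05, 1.2)),
               "control means")
  expect_error(sim_config(n_samples_cellline = 5), "seed")
})
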