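# Correlation screen, L-shape heuristic, candidate union, validation.

test_that("lshape_classify scores corner-and-floor patterns as L", {
  cfg <- lshape_config()
  # 20 points in the top-left cell, 20 in the bottom-right cell
  beta <- c(runif(20, 0, 0.3), runif(20, 0.75, 1))
  expr <- c(runif(20, 9, 10), runif(20, 0, 0.5))
  r <- lshape_classify(beta, expr, cfg)
  expect_equal(r$counts[1, 1], 20)
  expect_equal(r$counts[3, 3], 20)
  # default corner weights give (w11*20 + w33*20)/40 = 2
  expect_equal(r$score, 2)
  expect_true(r$flag)

  # all points in the top-right cell: vetoed by max_topright_frac
  r2 <- lshape_classify(runif(30, 0.8, 1), runif(30, 9, 10), cfg)
  expect_false(r2$flag)

  # fewer than min_points: untested, not an error
  r3 <- lshape_classify(runif(5), runif(5), cfg)
  expect_false(r3$tested)
  expect_true(is.na(r3$score))
})

test_that("lshape_classify rarely flags unstructured scatters", {
  set.seed(31)
  flags <- replicate(200, lshape_classify(runif(40), runif(40))$flag)
  expect_lte(mean(flags), 0.05)
  # low-methylation-only clouds (no methylated arm) are not L
  flags2 <- replicate(200,
    lshape_classify(runif(40, 0, 0.3), rnorm(40))$flag)
  expect_lte(mean(flags2), 0.05)
})

test_that("lshape grid ties go to the lower-beta / lower-expression cell", {
  cfg <- lshape_config(min_points = 4L)
  # beta exactly at the first cut stays in column 1; normalized expression
  # at a cut stays in the lower row
  beta <- c(1 / 3, 1 / 3, 0.9, 0.9)
  expr <- c(3, 3, 0, 9)  # min-max: 1/3, 1/3, 0, 1
  r <- lshape_classify(beta, expr, cfg)
  expect_equal(r$counts[3, 1], 2)  # boundary expression in the bottom row
  expect_equal(sum(r$counts[, 1]), 2)
})

test_that("lshape score is invariant to duplicating the point set", {
  set.seed(33)
  beta <- runif(25); expr <- rnorm(25)
  r1 <- lshape_classify(beta, expr)
  r2 <- lshape_classify(rep(beta, 2), rep(expr, 2))
  expect_equal(r2$score, r1$score)
  expect_equal(r2$counts, 2L * r1$counts)
})

test_that("correlation_screen flags only negative correlations under FDR", {
  cfg <- small_sim(seed = 41, n_genes = 300L)
  meth <- simulate_methylation(cfg)
  ex <- simulate_expression(cfg, meth)
  # plant one strongly positive gene
  al <- align_cohort(meth$beta, ex$expr, meth$probes)
  g_pos <- ex$truth$gene_symbol[ex$truth$class == "null"][1]
  e2 <- unclass(ex$expr)
  e2[g_pos, ] <- 5 + 6 * al$beta[g_pos, colnames(e2)]
  scr <- correlation_screen(align_cohort(meth$beta, expression_matrix(e2),
                                         meth$probes))
  row_pos <- scr[scr$gene_symbol == g_pos, ]
  expect_gt(row_pos$rho, 0.9)
  expect_false(row_pos$sig_neg)  # sign rule: positive is never a hit
  expect_true(all(scr$q >= scr$p, na.rm = TRUE))

  expect_error(correlation_screen(structure(
    list(beta = matrix(0, 0, 0), expr = matrix(0, 0, 0),
         gene_map = character(0), aggregate = "mean"),
    class = "aligned_cohort")), "empty")
})

test_that("BH is applied once over the tested universe (order invariance)", {
  cfg <- small_sim(seed = 43, n_genes = 150L)
  meth <- simulate_methylation(cfg)
  ex <- simulate_expression(cfg, meth)
  al <- align_cohort(meth$beta, ex$expr, meth$probes)
  scr <- correlation_screen(al)

  perm <- sample(nrow(al$beta))
  al2 <- al
  al2$beta <- al$beta[perm, , drop = FALSE]
  al2$expr <- al$expr[perm, , drop = FALSE]
  scr2 <- correlation_screen(al2)
  i <- match(scr$gene_symbol, scr2$gene_symbol)
  expect_equal(scr2$q[i], scr$q)
})

test_that("build_candidates forms a disjoint union with correct counts", {
  cfg <- small_sim(seed = 45, n_genes = 400L)
  meth <- simulate_methylation(cfg)
  ex <- simulate_expression(cfg, meth)
  al <- align_cohort(meth$beta, ex$expr, meth$probes)
  scr <- build_candidates(lshape_screen(correlation_screen(al), al))
  ct <- attr(scr, "screen_counts")
  expect_equal(ct$n_candidates, ct$n_corr_hits + ct$n_l_only)
  # L-only stratum excludes correlation hits by construction
  expect_false(any(scr$sig_neg & (scr$lshape_flag %in% TRUE) &
                     !scr$candidate_flag))
  expect_equal(sum(scr$candidate_flag), ct$n_candidates)

  # empty L set: candidates are exactly the correlation hits
  scr_noL <- scr
  scr_noL$lshape_flag <- FALSE
  ct2 <- attr(build_candidates(scr_noL), "screen_counts")
  expect_equal(ct2$n_candidates, ct$n_corr_hits)
})

test_that("cross-cohort validation restricts, re-adjusts and counts strata", {
  cfg <- sim_config(n_samples_cellline = 25L, n_genes = 500L, seed = 47)
  co1 <- simulate_methylation(cfg); e1 <- simulate_expression(cfg, co1)
  cfg2 <- sim_config(n_samples_cellline = 25L, n_genes = 500L, seed = 1047)
  shared <- attr(co1$probes, "gene_class")
  co2 <- simulate_methylation(cfg2, gene_classes = shared)
  e2 <- simulate_expression(cfg2, co2)

  al1 <- align_cohort(co1$beta, e1$expr, co1$probes)
  scr <- build_candidates(lshape_screen(correlation_screen(al1), al1))
  al2 <- align_cohort(co2$beta, e2$expr, co2$probes)
  scr <- cross_cohort_validate(scr, al2)
  v <- attr(scr, "validation")
  expect_equal(v$n_available, sum(!is.na(scr$validated_flag)))
  expect_lte(v$n_validated, v$n_available)
  expect_equal(v$availability_fraction, v$n_available / v$n_candidates)

  # same planted truth in both cohorts: monotone candidates mostly validate
  mono <- e1$truth$gene_symbol[e1$truth$class == "monotone"]
  mono_cand <- intersect(mono, scr$gene_symbol[scr$candidate_flag])
  expect_gt(mean(scr$validated_flag[match(mono_cand, scr$gene_symbol)],
                 na.rm = TRUE), 0.85)

  # a candidate absent from cohort 2 lands in the unavailable stratum
  keep <- rownames(al2$beta) != mono_cand[1]
  al2b <- al2
  al2b$beta <- al2$beta[keep, , drop = FALSE]
  al2b$expr <- al2$expr[keep, , drop = FALSE]
  al2b$gene_map <- al2$gene_map[keep]
  scr_b <- cross_cohort_validate(scr, al2b)
  expect_true(is.na(scr_b$validated_flag[match(mono_cand[1],
                                               scr_b$gene_symbol)]))
  expect_equal(attr(scr_b, "validation")$n_available, v$n_available - 1)
})
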