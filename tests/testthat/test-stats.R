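# Statistical primitives against hand-computed values and independent
# base-R / survival-package cross-checks.

test_that("spearman_test reproduces hand-computed rho and handles ties", {
  expect_equal(spearman_test(1:4, c(8, 6, 4, 2))$estimate, -1)
  expect_equal(spearman_test(1:4, c(8, 6, 4, 2))$p_value, 0)

  r <- spearman_test(1:4, c(2, 1, 4, 3))
  expect_equal(r$estimate, 0.6)  # 1 - 6*4/(4*15)
  expect_equal(r$p_value, 2 * pt(-0.6 * sqrt(2 / (1 - 0.36)), df = 2))

  # average-rank tie handling: ranks of (1,1,2,3) are (1.5,1.5,3,4)
  rt <- spearman_test(c(1, 1, 2, 3), c(4, 3, 2, 1))
  expect_equal(rt$estimate,
               cor(c(1.5, 1.5, 3, 4), c(4, 3, 2, 1)))

  expect_error(spearman_test(1:3, 3:1), "4 complete pairs")
  expect_error(spearman_test(rep(1, 5), 1:5), "zero variance")
})

test_that("spearman equals Pearson on average ranks (oracle property)", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- round(rnorm(n), 1)  # rounding induces ties
    y <- round(rnorm(n), 1)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    r <- spearman_test(x, y)
    expect_equal(r$estimate, cor(rank(x), rank(y)))
    expect_equal(r$estimate,
                 suppressWarnings(cor.test(x, y, method = "spearman"))$estimate,
                 ignore_attr = TRUE)
  }
})

test_that("spearman exact permutation p agrees with the t approximation", {
  set.seed(9)
  x <- rnorm(7); y <- rnorm(7)
  pe <- spearman_test(x, y, exact = TRUE)$p_value
  pt_ <- spearman_test(x, y)$p_value
  expect_lt(abs(pe - pt_), 0.15)
  # exact p equals the permutation null enumerated by cor.test for small n
  expect_equal(pe, cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("bh_adjust matches the hand step-up and classical rejection sets", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"))
    # classical step-up at level alpha: reject 1..k*, k* = max{k: p_(k) <= alpha k/m}
    alpha <- runif(1, 0.05, 0.5)
    m <- length(p)
    ps <- sort(p)
    k <- which(ps <= alpha * seq_len(m) / m)
    classical <- if (length(k) == 0) rep(FALSE, m) else p <= ps[max(k)]
    expect_equal(q <= alpha, classical)
  }
})

test_that("two_sample_t reproduces the pooled-variance formula", {
  r0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), -3.674)
  expect_equal(r$p_value, 2 * pt(-abs(r$statistic), 4))
  expect_equal(round(r$p_value, 4), 0.0213)

  rs <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rs$statistic, -r$statistic)
  expect_equal(rs$p_value, r$p_value)

  # cross-check against t.test, pooled and Welch
  set.seed(3)
  a <- rnorm(12); b <- rnorm(9, 0.5)
  expect_equal(two_sample_t(a, b)$p_value,
               t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(two_sample_t(a, b, welch = TRUE)$p_value,
               t.test(a, b)$p.value)
})

test_that("fisher_exact_2x2 matches closed forms and full enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  ext <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(ext$p_value, 2 / choose(20, 10))
  expect_equal(ext$estimate, Inf)
  expect_equal(fisher_exact_2x2(matrix(c(6, 3, 2, 4), 2, byrow = TRUE))$estimate,
               (6 * 4) / (3 * 2))
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")

  # enumeration oracle over all tables with fixed margins, n <= 60
  enum_p <- function(a, b, c_, d) {
    m <- a + b; n2 <- c_ + d; k <- a + c_; n <- m + n2
    supp <- max(0, k - n2):min(k, m)
    pr <- choose(m, supp) * choose(n2, k - supp) / choose(n, k)
    obs <- choose(m, a) * choose(n2, k - a) / choose(n, k)
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  set.seed(11)
  for (i in 1:100) {
    tb <- as.vector(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
    if (sum(tb[c(1, 2)]) == 0 || sum(tb[c(3, 4)]) == 0) next
    ours <- fisher_exact_2x2(matrix(tb, 2, 2, byrow = TRUE))$p_value
    expect_equal(ours, enum_p(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-12)
    expect_equal(ours,
                 fisher.test(matrix(tb, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("pearson_test reproduces hand values", {
  expect_equal(pearson_test(1:5, 2 * (1:5) + 1)$estimate, 1)
  expect_equal(pearson_test(1:5, 2 * (1:5) + 1)$p_value, 0)
  expect_equal(pearson_test(1:5, -(1:5))$estimate, -1)
  r <- pearson_test(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$estimate, 0.5)
  expect_equal(r$p_value, cor.test(c(1, 2, 3), c(1, 3, 2))$p.value)
})

test_that("km_estimate is the product-limit estimate", {
  f <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(f$survival, c(0.5, 0))

  all_cens <- km_estimate(c(3, 5, 7), c(0, 0, 0))
  expect_equal(nrow(all_cens), 0)  # curve stays at 1

  f2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(f2$time, c(1, 3))
  expect_equal(f2$survival, c(2 / 3, 0))

  skip_if_not_installed("survival")
  set.seed(5)
  t_ <- rexp(40); e_ <- rbinom(40, 1, 0.7)
  sf <- survival::survfit(survival::Surv(t_, e_) ~ 1)
  ours <- km_estimate(t_, e_)
  ref <- summary(sf, times = ours$time)
  expect_equal(ours$survival, ref$surv, tolerance = 1e-12)
})

test_that("logrank_test matches survival::survdiff", {
  r0 <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # strongly separated groups
  rs <- logrank_test(1:10, rep(1, 10), 1:10 + 50, rep(1, 10))
  expect_lt(rs$p_value, 0.05)

  # single event total: one hypergeometric table
  r1 <- logrank_test(c(5, 6), c(1, 0), c(7, 8), c(0, 0))
  expect_true(is.finite(r1$statistic))

  skip_if_not_installed("survival")
  set.seed(8)
  for (i in 1:20) {
    ta <- rexp(15); ea <- rbinom(15, 1, 0.8)
    tb <- rexp(18, 0.6); eb <- rbinom(18, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    sd_ <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(15, 18)))
    ours <- logrank_test(ta, ea, tb, eb)
    expect_equal(ours$statistic, sd_$chisq, tolerance = 1e-10)
  }
})
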