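# Self-contained statistical primitives. Each is written out explicitly so it
# can be checked against brute-force oracles; base R offers equivalents
# (cor.test, p.adjust, fisher.test, survival::survdiff) which the test suite
# uses as independent cross-checks.

#' Construct a hypothesis-test result
#'
#' Light container used by all tests in the package.
#'
#' @param statistic test statistic.
#' @param p_value two-sided p-value in [0, 1].
#' @param estimate point estimate (e.g. rho, r, mean difference, odds ratio).
#' @param n number of observations (or pairs) used.
#' @param df degrees of freedom, if applicable.
#' @param method short method label.
#' @return An object of class `ms_test`.
#' @keywords internal
ms_test <- function(statistic, p_value, estimate = NA_real_, n = NA_integer_,
                    df = NA_real_, method = "test") {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = statistic, p_value = p_value, estimate = estimate,
                 n = n, df = df, method = method),
            class = "ms_test")
}

#' @export
print.ms_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      " estimate =", format(x$estimate, digits = 4),
      " p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

# pairwise deletion of incomplete pairs
complete_pairs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman rank correlation test
#'
#' Rank correlation computed as the Pearson product-moment correlation of
#' average ranks (ties receive their mean rank). The two-sided p-value uses the
#' t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
#' freedom; a perfect monotone relation (|rho| = 1) gets p = 0. For small
#' samples an exact permutation p-value over all n! rank orders is available.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @param exact if `TRUE` and n <= 9, compute the exact permutation p-value
#'   instead of the t approximation.
#' @return An `ms_test` with `estimate` = rho.
#' @examples
#' spearman_test(1:4, c(8, 6, 4, 2))$estimate  # -1
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  cp <- complete_pairs(x, y)
  if (cp$n < 4) stop("spearman_test needs at least 4 complete pairs")
  rx <- rank(cp$x, ties.method = "average")
  ry <- rank(cp$y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("spearman_test undefined: zero variance in ranks")
  rho <- stats::cor(rx, ry)
  n <- cp$n
  if (exact && n <= 9) {
    p <- spearman_perm_p(rx, ry, rho)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  ms_test(statistic = rho * sqrt((n - 2) / max(1 - rho^2, 1e-300)),
          p_value = p, estimate = rho, n = n, df = n - 2,
          method = "Spearman rank correlation")
}

# exact permutation p for |rho| >= observed, enumerating all orders of y-ranks
spearman_perm_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- permutations_all(n)
  rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    rest <- setdiff(seq_len(n), k)
    out[r + seq_len(rows), 1L] <- k
    out[r + seq_len(rows), -1L] <- matrix(rest[sub], rows, n - 1L)
    r <- r + rows
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Classical step-up adjustment: sort p ascending, q_(i) = p_(i) * m / i,
#' enforce monotone non-decreasing from the largest p downwards, cap at 1,
#' and return values in the original order. `NA` entries are passed through
#' and do not count towards m.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted p-values (q-values), same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  q
}

#' Two-sample t-test
#'
#' Pooled-variance Student's t by default; Welch's unequal-variance form
#' optionally. Two-sided p from the t distribution.
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @param welch use Welch's approximation instead of the pooled variance.
#' @return An `ms_test`; `estimate` is mean(a) - mean(b).
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) stop("two_sample_t undefined: zero variance in both groups")
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    tstat <- d / sqrt(se2)
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) {
      if (d == 0) return(ms_test(0, 1, 0, na + nb, na + nb - 2,
                                 "Student's t (pooled)"))
      stop("two_sample_t undefined: zero pooled variance with unequal means")
    }
    df <- na + nb - 2
    tstat <- d / sqrt(sp2 * (1 / na + 1 / nb))
  }
  ms_test(tstat, 2 * stats::pt(-abs(tstat), df), estimate = d,
          n = na + nb, df = df,
          method = if (welch) "Welch's t" else "Student's t (pooled)")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the probability of the observed table (a relative tolerance of 1e-7
#' guards against floating-point ties). The reported odds ratio is the sample
#' cross-product ratio ad/bc (Inf when bc = 0), not the conditional MLE that
#' `fisher.test` reports.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return An `ms_test`; `estimate` is the odds ratio.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (any(dim(tab) != 2)) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row-1 margin
  n2 <- cc + d        # row-2 margin
  k <- a + cc         # column-1 margin
  if (m + n2 == 0) stop("table has no observations")
  lo <- max(0, k - n2); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  orat <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  ms_test(statistic = a, p_value = p, estimate = orat,
          n = m + n2, method = "Fisher's exact test (2x2)")
}

#' Pearson product-moment correlation test
#'
#' @param x,y paired numeric vectors; incomplete pairs dropped; at least 3
#'   complete pairs required.
#' @return An `ms_test` with `estimate` = r.
#' @export
pearson_test <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 3) stop("pearson_test needs at least 3 complete pairs")
  if (stats::sd(cp$x) == 0 || stats::sd(cp$y) == 0)
    stop("pearson_test undefined: zero variance")
  r <- stats::cor(cp$x, cp$y)
  n <- cp$n
  if (abs(r) >= 1 - 1e-12) {
    p <- 0; tstat <- sign(r) * Inf
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  ms_test(tstat, p, estimate = r, n = n, df = n - 2,
          method = "Pearson correlation")
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times non-negative event/censoring times.
#' @param events 0/1 indicators (1 = event, 0 = censored).
#' @return An object of class `km_fit`: a data frame with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `survival`); the curve starts at
#'   S(0) = 1 and censored times never drop it.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  ok <- is.finite(times) & !is.na(events)
  times <- times[ok]; events <- events[ok]
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  ut <- sort(unique(times[events == 1]))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_fit", "data.frame"),
            n = length(times), n_events = sum(events))
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate:", attr(x, "n"), "subjects,",
      attr(x, "n_events"), "events\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @param x a `km_fit`.
#' @param ... passed to `plot`.
#' @rdname km_estimate
#' @method plot km_fit
#' @export
plot.km_fit <- function(x, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-(2 * nrow(x))])
  if (nrow(x) == 0) { tt <- c(0, 1); ss <- c(1, 1) }
  graphics::plot(tt, ss, type = "l", ylim = c(0, 1),
                 xlab = "time", ylab = "survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Chi-square(1) statistic from the sum of observed-minus-expected events in
#' group A over all distinct event times, with the hypergeometric variance at
#' each table.
#'
#' @param times_a,events_a,times_b,events_b per-group times and 0/1 event
#'   indicators.
#' @return An `ms_test`; `estimate` is the summed O - E for group A.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0)
    stop("both groups must be non-empty")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  ut <- sort(unique(times[events == 1]))
  oe <- 0; v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d <- sum(times == t & events == 1)
    d_a <- sum(times == t & events == 1 & grp_a)
    oe <- oe + d_a - d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(ms_test(0, 1, estimate = oe, n = length(times), df = 1,
                             method = "log-rank"))
  chisq <- oe^2 / v
  ms_test(chisq, stats::pchisq(chisq, df = 1, lower.tail = FALSE),
          estimate = oe, n = length(times), df = 1, method = "log-rank")
}
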