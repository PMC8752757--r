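#' Two-sample t-test with degenerate-input handling
#'
#' Unpaired two-sided t-test between two groups of (log-scale) measurements,
#' the comparison used throughout the expression figures. The pooled-variance
#' Student form is the default; the Welch form is available via `welch = TRUE`.
#'
#' Degenerate inputs are resolved rather than raised: when both groups are
#' constant and equal the statistic is 0 with p = 1; when both are constant but
#' unequal the statistic is signed infinite with p = 0 and a warning.
#'
#' @param x,y Numeric vectors, each of length >= 2, finite.
#' @param welch Use the Welch (unequal-variance) form instead of pooled.
#' @return A `test_result` list: `statistic`, `p_value`, `df`, `effect`
#'   (difference of means, `mean(x) - mean(y)`).
#' @export
student_t <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) {
      return(test_result(statistic = 0, p_value = 1,
                         df = length(x) + length(y) - 2, effect = 0))
    }
    warning("zero variance in both groups with unequal means; p = 0")
    return(test_result(statistic = sign(d) * Inf, p_value = 0,
                       df = length(x) + length(y) - 2, effect = d))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              df = unname(ht$parameter), effect = mean(x) - mean(y))
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way ANOVA, used to test whether mean expression
#' differs across copy-number categories. Groups with fewer than 2 members are
#' dropped with a message (near-empty categories such as amplification are
#' common in copy-number cohorts).
#'
#' @param groups List of numeric vectors, one per category.
#' @return A `test_result`: `statistic` (F), `p_value`, `df` (numerator df),
#'   `effect` (F again, the conventional effect column for this test).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    message("dropping ", sum(sizes < 2), " group(s) with < 2 members")
    groups <- groups[sizes >= 2]
  }
  if (length(groups) < 2) stop("fewer than 2 usable groups after dropping singletons")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  # all observations identical: no variance to partition, F defined as 0
  if (stats::var(values) == 0) {
    return(test_result(statistic = 0, p_value = 1,
                       df = length(groups) - 1, effect = 0))
  }
  ht <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              df = unname(ht$parameter[["num df"]]),
              effect = unname(ht$statistic))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A `test_result`: `statistic` (the t transform), `p_value`, `df`,
#'   `effect` (r).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance in input")
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              df = unname(ht$parameter), effect = unname(ht$estimate))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values in the original input order; the adjustment behind every
#' "FDR < 0.05" threshold in the pipeline.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return List with `raw_p` and `q` (same length and order).
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  list(raw_p = p, q = stats::p.adjust(p, method = "BH"))
}

#' Kaplan-Meier survival estimator
#'
#' Product-limit estimate as a right-continuous step function; censored
#' records shrink the risk set without a step.
#'
#' @param time Non-negative follow-up times.
#' @param event Event flags (1 = event, 0 = censored).
#' @return List: `time` (distinct event times), `surv` (S(t) just after each),
#'   `n_risk`, `n_event`, and `fn`, a vectorized step function of time.
#' @export
km_estimator <- function(time, event) {
  stopifnot(length(time) > 0, length(time) == length(event), all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  tt <- fit$time[keep]
  ss <- fit$surv[keep]
  fn <- stats::stepfun(if (length(tt)) tt else 0,
                       c(1, if (length(ss)) ss else 1), right = FALSE)
  list(time = tt, surv = ss,
       n_risk = fit$n.risk[keep], n_event = fit$n.event[keep], fn = fn)
}

#' Two-group log-rank test
#'
#' 1-df chi-square from summed observed minus expected events over distinct
#' event times, with the tie-aware hypergeometric variance.
#'
#' @param time,event As in [km_estimator()].
#' @param group Two-level group labels (any type with exactly 2 levels among
#'   non-empty groups).
#' @return A `test_result`: `statistic` (chi-square), `p_value`, `df` = 1,
#'   `effect` (observed - expected events in the second group level).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0)) stop("need two non-empty groups")
  if (sum(event) == 0) {
    warning("no events in either group; log-rank p = 1")
    return(test_result(statistic = 0, p_value = 1, df = 1, effect = 0))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  test_result(statistic = unname(sd$chisq),
              p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
              df = 1, effect = unname(sd$obs[2] - sd$exp[2]))
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p by the conventional exact definition (sum of all tables with
#' point probability at most the observed one). The odds ratio is the sample
#' odds ratio, with a 0.5 continuity correction when any cell is zero.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return A `test_result`: `statistic` (odds ratio), `p_value`, `df` absent
#'   (NA), `effect` (odds ratio).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a margin of the 2x2 table is zero")
  }
  p <- stats::fisher.test(tab)$p.value
  cc <- if (any(cells == 0)) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c + cc))
  test_result(statistic = or, p_value = min(p, 1), df = NA_real_, effect = or)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= overlap) when `draws` items are taken without replacement from a
#' universe containing `set_size` marked items; the enrichment p-value used by
#' the gene-set overlay and the motif enrichment ranking.
#'
#' @param overlap Observed marked items among the draws.
#' @param set_size Marked items in the universe.
#' @param universe Universe size.
#' @param draws Number of items drawn.
#' @return Upper-tail probability.
#' @export
hypergeom_tail <- function(overlap, set_size, universe, draws) {
  ok <- overlap >= 0 && set_size <= universe && draws <= universe &&
    overlap <= min(set_size, draws)
  if (!ok) stop("inconsistent hypergeometric counts")
  stats::phyper(overlap - 1, set_size, universe - set_size, draws,
                lower.tail = FALSE)
}

#' Quantile normalization of a count/intensity matrix
#'
#' Forces every column (sample) to share the distribution of across-column
#' rank means; ties within a column receive the mean of their rank values.
#' This is the normalization applied to ATAC peak raw counts before
#' differential scoring.
#'
#' @param m Non-negative finite numeric matrix, peaks x samples.
#' @return Matrix of the same dimension and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(is.finite(m)), all(m >= 0))
  if (ncol(m) < 2) {
    warning("single column: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Xenograft tumor volume
#'
#' Standard caliper formula: volume = 0.5 x a x b^2 with long diameter `a`
#' and short diameter `b`, in mm.
#'
#' @param a Long diameter (mm), `a >= b`.
#' @param b Short diameter (mm), positive.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(a, b) {
  stopifnot(all(b > 0))
  if (any(b > a)) stop("short diameter exceeds long diameter (a, b swapped?)")
  0.5 * a * b^2
}

test_result <- function(statistic, p_value, df = NA_real_, effect = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 effect = effect), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("statistic = %.6g, p = %.4g, df = %s, effect = %.6g\n",
              x$statistic, x$p_value,
              ifelse(is.na(x$df), "-", format(x$df)), x$effect))
  invisible(x)
}
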