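#' Split a survival cohort at an expression quantile
#'
#' Labels the `round-half-up(high_fraction * n)` samples with the largest
#' expression "high" and the rest "low". With n = 425 and high_fraction 0.3
#' this yields the 128 high / 297 low split used for the overall-survival
#' curves. Ties in expression are broken by a stable sort on
#' (expression, sample_id), so the split is deterministic under row
#' permutation.
#'
#' @param cohort Data frame with columns `sample_id`, `time`, `event`, `expr`.
#' @param high_fraction Fraction of samples labeled high, in (0, 1).
#' @return Character vector of labels (`"low"`/`"high"`) aligned with the
#'   cohort rows.
#' @export
quantile_split <- function(cohort, high_fraction) {
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "time", "event", "expr") %in% names(cohort)),
            all(is.finite(cohort$expr)),
            high_fraction > 0, high_fraction < 1)
  n <- nrow(cohort)
  # round half up; the 1e-9 absorbs binary-representation error (0.7 * 425
  # evaluates a hair below 297.5)
  n_high <- floor(high_fraction * n + 0.5 + 1e-9)
  if (n_high == 0 || n_high == n) stop("high_fraction leaves an empty group")
  ord <- order(cohort$expr, cohort$sample_id, decreasing = TRUE, method = "radix")
  labels <- rep("low", n)
  labels[ord[seq_len(n_high)]] <- "high"
  labels
}

#' Cut-point scan over candidate split ratios
#'
#' The cut-off selection procedure for expression-based survival splits: for
#' each candidate ratio (default 30%, 50%, 70%), cut the cohort at that
#' expression quantile — a ratio `f` divides the fraction `f` of samples into
#' the low group and `1 - f` into the high group, so the 70% ratio on a
#' 425-sample cohort gives the 297 low / 128 high split — run the log-rank
#' test on each split, and select the ratio with the smallest p (ties to the
#' smallest ratio). All per-ratio results are reported, with BH-adjusted q
#' across the scanned ratios, so the selection optimism of picking the best
#' split post hoc is visible rather than hidden.
#'
#' @param cohort As in [quantile_split()].
#' @param fractions Candidate low-group fractions (cut quantiles).
#' @return List: `per_fraction` (data.frame with `fraction`, `n_low`,
#'   `n_high`, `chisq`, `p`, `q`), `selected_fraction`, `selected_p`,
#'   `labels` (the split at the selected fraction).
#' @export
scan_cutpoints <- function(cohort, fractions = c(0.3, 0.5, 0.7)) {
  stopifnot(length(fractions) >= 1)
  fractions <- sort(fractions)
  rows <- lapply(fractions, function(f) {
    lab <- quantile_split(cohort, 1 - f)
    lr <- suppressWarnings(logrank_test(cohort$time, cohort$event, lab))
    data.frame(fraction = f, n_low = sum(lab == "low"),
               n_high = sum(lab == "high"),
               chisq = lr$statistic, p = lr$p_value)
  })
  per <- do.call(rbind, rows)
  per$q <- bh_fdr(per$p)$q
  sel <- per$fraction[which.min(per$p)]  # which.min takes the first minimum
  list(per_fraction = per, selected_fraction = sel,
       selected_p = min(per$p),
       labels = quantile_split(cohort, 1 - sel))
}

#' Kaplan-Meier curves and risk table for a labeled cohort
#'
#' Per-group product-limit curves with numbers at risk at requested
#' timepoints, in a plot-ready long format.
#'
#' @param cohort As in [quantile_split()].
#' @param labels Group labels from [quantile_split()].
#' @param risk_times Timepoints for the numbers-at-risk table (default:
#'   quartiles of follow-up).
#' @return List: `curves` (data.frame `group`, `time`, `surv`), `km` (named
#'   list of [km_estimator()] results), `risk_table` (data.frame `group`,
#'   `time`, `n_risk`).
#' @export
km_curves <- function(cohort, labels,
                      risk_times = stats::quantile(cohort$time, c(0, .25, .5, .75, 1))) {
  stopifnot(nrow(cohort) == length(labels))
  groups <- sort(unique(labels))
  if (any(table(labels) == 0) || length(groups) < 2) stop("empty group")
  km <- lapply(stats::setNames(groups, groups), function(g) {
    km_estimator(cohort$time[labels == g], cohort$event[labels == g])
  })
  curves <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, time = c(0, km[[g]]$time), surv = c(1, km[[g]]$surv))
  }))
  risk <- do.call(rbind, lapply(groups, function(g) {
    tg <- cohort$time[labels == g]
    data.frame(group = g, time = as.numeric(risk_times),
               n_risk = vapply(risk_times, function(tp) sum(tg >= tp), numeric(1)))
  }))
  rownames(curves) <- rownames(risk) <- NULL
  list(curves = curves, km = km, risk_table = risk)
}
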