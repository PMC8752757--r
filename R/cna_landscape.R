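CNA_CATEGORIES <- c(-2L, -1L, 0L, 1L, 2L)
CNA_CATEGORY_NAMES <- c(`-2` = "deep deletion", `-1` = "deletion",
                        `0` = "duplicate", `1` = "gain", `2` = "amplification")

check_cna_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "gene", "category", "linear_cn", "expr")
                %in% names(cohort)))
  if (!all(cohort$category %in% CNA_CATEGORIES)) {
    stop("unknown CNA category code (expected -2..+2)")
  }
  if (anyDuplicated(cohort[c("sample_id", "gene")])) {
    stop("more than one record per (sample, gene)")
  }
  invisible(cohort)
}

#' Copy-number category profile for one gene
#'
#' Fraction of samples in each discrete CNA category (amplification +2, gain
#' +1, duplicate 0, deletion -1, deep deletion -2) — the pie-chart summary of
#' a locus.
#'
#' @param cohort Long-format CNA data frame: `sample_id`, `gene`, `category`,
#'   `linear_cn`, `expr`.
#' @param gene Gene symbol.
#' @return Named numeric vector over "-2".."2", summing to 1.
#' @export
category_pie <- function(cohort, gene) {
  check_cna_cohort(cohort)
  sub <- cohort[cohort$gene == gene, ]
  if (nrow(sub) == 0) stop("no records for gene ", gene)
  counts <- table(factor(sub$category, levels = CNA_CATEGORIES))
  stats::setNames(as.numeric(counts) / nrow(sub), names(counts))
}

#' Expression by copy-number category
#'
#' One-way ANOVA of log2 expression across CNA categories for one gene
#' (categories with < 2 samples are dropped by the ANOVA kernel), with
#' per-category mean and SD summaries.
#'
#' @inheritParams category_pie
#' @return List: `anova` (a `test_result`), `summary` (data.frame `category`,
#'   `n`, `mean`, `sd`).
#' @export
expression_by_category <- function(cohort, gene) {
  check_cna_cohort(cohort)
  sub <- cohort[cohort$gene == gene, ]
  if (nrow(sub) == 0) stop("no records for gene ", gene)
  groups <- split(sub$expr, factor(sub$category, levels = CNA_CATEGORIES))
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2) stop("fewer than 2 CNA categories present")
  summ <- data.frame(category = as.integer(names(groups)),
                     n = vapply(groups, length, integer(1)),
                     mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, stats::sd, numeric(1)),
                     row.names = NULL)
  list(anova = one_way_anova(unname(groups)), summary = summ)
}

#' Correlation between two loci
#'
#' Pearson correlation (with two-sided p) between values of two genes across
#' shared samples: relative linear copy number vs linear copy number
#' (`cn_cn`, the neighboring-locus test), copy number vs expression
#' (`cn_expr`), or expression vs expression (`expr_expr`).
#'
#' @inheritParams category_pie
#' @param gene_a,gene_b Gene symbols.
#' @param mode Which value pair to correlate.
#' @return A `test_result` from [pearson_r()].
#' @export
locus_correlation <- function(cohort, gene_a, gene_b,
                              mode = c("cn_cn", "cn_expr", "expr_expr")) {
  mode <- match.arg(mode)
  check_cna_cohort(cohort)
  a <- cohort[cohort$gene == gene_a, ]
  b <- cohort[cohort$gene == gene_b, ]
  shared <- intersect(a$sample_id, b$sample_id)
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  a <- a[match(shared, a$sample_id), ]
  b <- b[match(shared, b$sample_id), ]
  va <- if (mode == "expr_expr") a$expr else a$linear_cn
  vb <- if (mode == "cn_cn") b$linear_cn else b$expr
  pearson_r(va, vb)
}

#' Amplification / deep-deletion frequency comparison within a gene family
#'
#' Per-gene frequencies of amplification (+2) and deep (bi-allelic) deletion
#' (-2) across a gene family, with all pairwise 2x2 Fisher exact tests per
#' event type and BH adjustment across pairs. This is the comparison used to
#' contrast alteration patterns among paralogs (e.g. the AKT family).
#'
#' @inheritParams category_pie
#' @param family Character vector of >= 2 family gene symbols.
#' @return List: `frequencies` (data.frame `gene`, `n_amp`, `n_deepdel`,
#'   `n_total`), `pairwise` (data.frame `gene_a`, `gene_b`, `event`,
#'   `odds_ratio`, `p`, `q`), `missing` (family members absent from the
#'   cohort).
#' @export
family_frequency_compare <- function(cohort, family) {
  check_cna_cohort(cohort)
  present <- intersect(family, unique(cohort$gene))
  missing <- setdiff(family, present)
  if (length(missing)) message("family member(s) missing from cohort: ",
                               paste(missing, collapse = ", "))
  if (length(present) < 2) stop("fewer than 2 family members with records")
  freq <- do.call(rbind, lapply(present, function(g) {
    cat_g <- cohort$category[cohort$gene == g]
    data.frame(gene = g, n_amp = sum(cat_g == 2L),
               n_deepdel = sum(cat_g == -2L), n_total = length(cat_g))
  }))
  pairs <- utils::combn(present, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    fa <- freq[freq$gene == pr[1], ]; fb <- freq[freq$gene == pr[2], ]
    do.call(rbind, lapply(c(amp = "n_amp", deepdel = "n_deepdel"), function(col) {
      # neither gene carries the event: nothing to compare, p = 1 by convention
      if (fa[[col]] + fb[[col]] == 0) {
        ft <- list(effect = 1, p_value = 1)
      } else {
        ft <- fisher_exact_2x2(fa[[col]], fa$n_total - fa[[col]],
                               fb[[col]], fb$n_total - fb[[col]])
      }
      data.frame(gene_a = pr[1], gene_b = pr[2],
                 event = if (col == "n_amp") "amplification" else "deep_deletion",
                 odds_ratio = ft$effect, p = ft$p_value)
    }))
  }))
  pw$q <- NA_real_
  for (ev in unique(pw$event)) {
    pw$q[pw$event == ev] <- bh_fdr(pw$p[pw$event == ev])$q
  }
  rownames(freq) <- rownames(pw) <- NULL
  list(frequencies = freq, pairwise = pw, missing = missing)
}
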