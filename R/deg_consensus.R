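#' Construct an expression dataset
#'
#' Container for a genes x samples log2 expression matrix with a two-group
#' design (control vs case), the unit of the cross-dataset screen.
#'
#' @param dataset_id Character label.
#' @param values Numeric matrix, rownames = gene symbols, colnames = sample
#'   ids. Duplicate gene symbols are allowed here and collapsed at DE time.
#' @param group Character vector per sample, values in `c("control", "case")`.
#' @return An `expression_dataset` list.
#' @export
expression_dataset <- function(dataset_id, values, group) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)),
            length(group) == ncol(values),
            all(group %in% c("control", "case")))
  if (!all(c("control", "case") %in% group)) stop("both groups must be non-empty")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  structure(list(dataset_id = dataset_id, values = values,
                 group = as.character(group)),
            class = "expression_dataset")
}

#' Per-gene differential expression between case and control
#'
#' Gene-wise unpaired t-tests (pooled Student by default, Welch on request) on
#' a log2 expression matrix, with Benjamini-Hochberg q-values and a
#' deterministic significance rank: ascending p, ties broken by descending
#' absolute log2 fold change, then by symbol. Duplicate gene symbols
#' (microarray probes mapping to one gene) are collapsed to the most
#' significant entry before ranking. Genes with zero variance in both groups
#' get p = 1 and are counted in a message.
#'
#' @param ds An [expression_dataset()].
#' @param method `"student"` (pooled variance) or `"welch"`.
#' @return A `data.frame` DEG table: `gene`, `log2fc` (case - control),
#'   `stat`, `p`, `q`, `rank`.
#' @export
differential_expression <- function(ds, method = c("student", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "expression_dataset"))
  case <- ds$values[, ds$group == "case", drop = FALSE]
  ctrl <- ds$values[, ds$group == "control", drop = FALSE]
  n_flat <- 0L
  res <- t(vapply(seq_len(nrow(ds$values)), function(i) {
    x <- case[i, ]; y <- ctrl[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
      n_flat <<- n_flat + 1L
      return(c(mean(x) - mean(y), 0, 1))
    }
    tr <- suppressWarnings(student_t(x, y, welch = method == "welch"))
    c(tr$effect, tr$statistic, tr$p_value)
  }, numeric(3)))
  if (n_flat > 0) message(n_flat, " gene(s) with zero variance in both groups; p set to 1")
  tab <- data.frame(gene = rownames(ds$values), log2fc = res[, 1],
                    stat = res[, 2], p = res[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  # collapse duplicate symbols to the most significant probe
  ord0 <- order(tab$p, -abs(tab$log2fc), tab$gene)
  tab <- tab[ord0, ]
  tab <- tab[!duplicated(tab$gene), ]
  tab$q <- bh_fdr(tab$p)$q
  ord <- order(tab$p, -abs(tab$log2fc), tab$gene)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Top-k cross-dataset consensus of DEG tables
#'
#' The screening step: intersect the top-k genes (by significance rank) of
#' each DEG table and keep only genes whose fold-change direction agrees
#' across all tables. Candidates are ordered by their worst (maximum)
#' per-dataset rank, best first.
#'
#' @param tables List of >= 2 DEG tables from [differential_expression()].
#' @param k Top-list size (the screen used k = 100).
#' @return List: `k`, `candidate_genes` (ordered), `per_dataset_ranks`
#'   (data.frame gene x dataset), `direction` (named sign vector),
#'   `excluded_discordant` (top-k-everywhere genes dropped for sign conflict).
#' @export
top_k_consensus <- function(tables, k) {
  stopifnot(length(tables) >= 2, k >= 1)
  common <- Reduce(intersect, lapply(tables, `[[`, "gene"))
  if (k > length(common)) stop("k exceeds the number of shared gene symbols")
  tops <- lapply(tables, function(t) t$gene[t$rank <= k])
  inter <- Reduce(intersect, tops)
  signs <- vapply(tables, function(t) {
    sign(t$log2fc)[match(inter, t$gene)]
  }, numeric(length(inter)))
  signs <- matrix(signs, nrow = length(inter))
  concord <- apply(signs, 1, function(s) all(s == s[1]) && all(s != 0))
  kept <- inter[concord]
  ranks <- vapply(tables, function(t) t$rank[match(kept, t$gene)],
                  numeric(length(kept)))
  ranks <- matrix(ranks, nrow = length(kept),
                  dimnames = list(kept, vapply(seq_along(tables), function(i) {
                    paste0("dataset", i)
                  }, character(1))))
  worst <- apply(ranks, 1, max)
  ord <- order(worst, kept)
  list(k = k,
       candidate_genes = kept[ord],
       per_dataset_ranks = as.data.frame(ranks[ord, , drop = FALSE]),
       direction = stats::setNames(signs[concord, 1][ord], kept[ord]),
       excluded_discordant = inter[!concord])
}

#' Direction-consistency cross-check against an external table
#'
#' Offline stand-in for surveying an independent cohort (e.g. an RNA-seq
#' compendium): keep candidates whose fold-change sign agrees with a
#' user-supplied external sign map, and report discordant and unchecked genes.
#'
#' @param table A DEG table.
#' @param external Named numeric vector of signs (+1 / -1) keyed by symbol.
#' @return List: `consistent` (gene vector), `discordant` (data.frame with
#'   both signs), `unchecked` (genes absent from the external map).
#' @export
direction_consistency_check <- function(table, external) {
  g <- table$gene
  internal <- stats::setNames(sign(table$log2fc), g)
  shared <- intersect(g, names(external))
  agree <- shared[internal[shared] == sign(external[shared])]
  disagree <- setdiff(shared, agree)
  list(consistent = agree,
       discordant = data.frame(gene = disagree,
                               internal_sign = unname(internal[disagree]),
                               external_sign = unname(sign(external[disagree])),
                               stringsAsFactors = FALSE),
       unchecked = setdiff(g, shared))
}

#' Gene-set overlay on a DEG table
#'
#' Tests whether a curated gene set (e.g. Hippo signature genes or YAP/TAZ
#' direct targets) is enriched among significantly regulated genes in the
#' stated direction: a hypergeometric upper-tail p for membership among genes
#' with q < `q_cutoff` and the requested sign, plus a one-sided rank-sum test
#' comparing the set's t statistics against the rest of the table.
#'
#' @param table A DEG table.
#' @param gene_set Character vector of symbols.
#' @param direction `"down"` or `"up"`.
#' @param q_cutoff Significance threshold on the BH q-value.
#' @return List: `hypergeom_p`, `ranksum_p`, `overlap`, `n_hits`, `set_size`
#'   (after intersecting with the table universe), `universe`, and
#'   `annotated` (the table with an `in_set` flag, volcano-ready).
#' @export
gene_set_overlay <- function(table, gene_set, direction = c("down", "up"),
                             q_cutoff = 0.05) {
  direction <- match.arg(direction)
  set_in <- intersect(gene_set, table$gene)
  if (length(set_in) == 0) stop("gene set does not intersect the table universe")
  want_sign <- if (direction == "down") -1 else 1
  hits <- table$gene[table$q < q_cutoff & sign(table$log2fc) == want_sign]
  overlap <- length(intersect(set_in, hits))
  hp <- hypergeom_tail(overlap, length(set_in), nrow(table), length(hits))
  in_set <- table$gene %in% set_in
  alt <- if (direction == "down") "less" else "greater"
  rs <- stats::wilcox.test(table$stat[in_set], table$stat[!in_set],
                           alternative = alt, exact = FALSE)$p.value
  table$in_set <- in_set
  list(hypergeom_p = hp, ranksum_p = rs, overlap = overlap,
       n_hits = length(hits), set_size = length(set_in),
       universe = nrow(table), annotated = table)
}
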