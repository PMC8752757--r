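DNA_BASES <- c("A", "C", "G", "T")

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text dialect: a `>ID name` header followed by four
#' bracketed count rows labeled A/C/G/T (in any order; rows are normalized to
#' A,C,G,T).
#'
#' @param path File path.
#' @return Named list of `pfm` objects: `motif_id`, `name`, `counts`
#'   (4 x L matrix with rownames A,C,G,T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (h in seq_along(heads)) {
    block <- lines[(bounds[h] + 1):(bounds[h + 1] - 1)]
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[h]]), "\\s+")[[1]]
    motif_id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else motif_id
    if (length(block) != 4) stop("motif ", motif_id, ": expected 4 count rows")
    rows <- lapply(block, function(ln) {
      base <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", ln))
      nums <- regmatches(ln, gregexpr("[0-9]+\\.?[0-9]*", ln))[[1]]
      list(base = base, counts = as.numeric(nums))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, DNA_BASES)) stop("motif ", motif_id, ": bad row labels")
    lens <- vapply(rows, function(r) length(r$counts), integer(1))
    if (length(unique(lens)) != 1) stop("motif ", motif_id, ": row length mismatch")
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(counts) <- bases
    counts <- counts[DNA_BASES, , drop = FALSE]
    if (any(colSums(counts) == 0)) stop("motif ", motif_id, ": all-zero column")
    out[[motif_id]] <- structure(list(motif_id = motif_id, name = name,
                                      counts = counts), class = "pfm")
  }
  out
}

#' Write position frequency matrices in JASPAR format
#'
#' @param pfms List of `pfm` objects (as from [read_jaspar()]).
#' @param path Output file.
#' @export
write_jaspar <- function(pfms, path) {
  lines <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$motif_id, " ", p$name),
      vapply(DNA_BASES, function(b) {
        paste0(b, "  [ ", paste(format(p$counts[b, ], trim = TRUE),
                                collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

pfm_log_odds <- function(pfm, pseudocount = 0.5, background = rep(0.25, 4)) {
  counts <- pfm$counts
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  log2(sweep(probs, 1, background, "/"))
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(strsplit(x, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# windowed log-odds scores for a base-index vector (NA = N, scores 0)
score_strand <- function(idx, lod) {
  L <- ncol(lod)
  n <- length(idx)
  if (n < L) return(numeric(0))
  nw <- n - L + 1
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    v <- lod[, j][idx[j:(j + nw - 1)]]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

seq_base_index <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% c(DNA_BASES, "N"))) stop("sequence has non-ACGTN characters")
  match(chars, DNA_BASES)
}

#' Scan a DNA sequence with a position frequency matrix
#'
#' Log2-odds scoring of every window on both strands against the PFM (with a
#' per-cell pseudocount and a background base distribution); a window is a hit
#' when its score reaches `threshold_frac` of the maximum attainable score.
#' `N` bases score as background (log-odds 0).
#'
#' @param seq DNA string over A,C,G,T,N (case-insensitive).
#' @param pfm A `pfm` object.
#' @param pseudocount Added to every count cell.
#' @param background Base probabilities for A,C,G,T.
#' @param threshold_frac Fraction of the maximum score required for a hit.
#' @return Data frame: `position` (1-based start on the forward strand),
#'   `strand` (`+`/`-`), `score`.
#' @export
pwm_scan <- function(seq, pfm, pseudocount = 0.5,
                     background = rep(0.25, 4), threshold_frac = 0.8) {
  seq <- toupper(seq)
  lod <- pfm_log_odds(pfm, pseudocount, background)
  L <- ncol(lod)
  if (nchar(seq) < L) {
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  max_score <- sum(apply(lod, 2, max))
  fwd <- score_strand(seq_base_index(seq), lod)
  rev <- score_strand(seq_base_index(revcomp(seq)), lod)
  # map reverse-strand window k (on the reverse sequence) back to forward start
  n <- nchar(seq)
  hitf <- which(fwd >= threshold_frac * max_score)
  hitr <- which(rev >= threshold_frac * max_score)
  out <- rbind(
    if (length(hitf)) data.frame(position = hitf, strand = "+", score = fwd[hitf]),
    if (length(hitr)) data.frame(position = n - L + 2 - hitr, strand = "-",
                                 score = rev[hitr])
  )
  if (is.null(out)) out <- data.frame(position = integer(0),
                                      strand = character(0), score = numeric(0))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peak x motif occurrence matrix
#'
#' Binary matrix with entry 1 when a peak's sequence carries at least one
#' [pwm_scan()] hit for the motif.
#'
#' @param peaks PeakSet data frame with columns `peak_id` and `sequence`
#'   (plus BED-style `chrom`, `start`, `end`).
#' @param pfms List of `pfm` objects.
#' @param pseudocount,background,threshold_frac As in [pwm_scan()].
#' @return Integer matrix, peaks x motifs, dimnames from peak and motif ids.
#' @export
peak_motif_matrix <- function(peaks, pfms, pseudocount = 0.5,
                              background = rep(0.25, 4), threshold_frac = 0.8) {
  miss <- peaks$peak_id[is.na(peaks$sequence) | !nzchar(peaks$sequence)]
  if (length(miss)) stop("peaks without sequence: ", paste(miss, collapse = ", "))
  seqs <- toupper(peaks$sequence)
  fwd_idx <- lapply(seqs, seq_base_index)
  rev_idx <- lapply(revcomp(seqs), seq_base_index)
  m <- vapply(pfms, function(p) {
    lod <- pfm_log_odds(p, pseudocount, background)
    thr <- threshold_frac * sum(apply(lod, 2, max))
    vapply(seq_along(seqs), function(i) {
      as.integer(any(score_strand(fwd_idx[[i]], lod) >= thr) ||
                   any(score_strand(rev_idx[[i]], lod) >= thr))
    }, integer(1))
  }, integer(nrow(peaks)))
  m <- matrix(m, nrow = nrow(peaks),
              dimnames = list(peaks$peak_id,
                              vapply(pfms, `[[`, character(1), "motif_id")))
  m
}

#' Differential accessibility score per peak
#'
#' Quantile-normalizes the raw peak count matrix across samples, then scores
#' each peak as the mean log2(normalized + 1) difference, condition minus
#' control.
#'
#' @param counts Peaks x samples non-negative matrix.
#' @param condition Per-sample labels, values in `c("control", "condition")`.
#' @return Named numeric vector of signed scores per peak.
#' @export
differential_peaks <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  stopifnot(length(condition) == ncol(counts),
            all(condition %in% c("control", "condition")),
            all(c("control", "condition") %in% condition))
  qn <- log2(quantile_normalize(counts) + 1)
  rowMeans(qn[, condition == "condition", drop = FALSE]) -
    rowMeans(qn[, condition == "control", drop = FALSE])
}

#' Module-map-style motif enrichment ranking
#'
#' Integrates a peak x motif occurrence matrix with per-peak differential
#' accessibility scores into a per-motif significance ranking — a declared
#' simplification of the Genomica Module Map integration: for each motif, a
#' hypergeometric upper-tail p of motif occurrence among the top `top_frac`
#' peaks (up direction) and among the bottom `top_frac` (down direction),
#' BH-adjusted across motifs within each direction. The signed score is
#' `-log10(q)` carrying the sign of the dominant (smaller-q) direction, and
#' rows are ranked by decreasing significance (ties by motif id).
#'
#' @param pm Binary peaks x motifs matrix (rows aligned with `peak_scores`).
#' @param peak_scores Signed per-peak scores from [differential_peaks()].
#' @param top_frac Fraction of peaks in each tail.
#' @return Data frame: `motif_id`, `occurrence_count`, `direction`,
#'   `enrichment_p`, `q`, `signed_score`, ordered most significant first.
#' @export
module_map_enrichment <- function(pm, peak_scores, top_frac = 0.05) {
  pm <- as.matrix(pm)
  stopifnot(nrow(pm) == length(peak_scores))
  n <- nrow(pm)
  n_top <- ceiling(top_frac * n)
  if (n_top < 10) stop("top fraction yields < 10 peaks; provide more peaks")
  ord <- order(peak_scores, decreasing = TRUE)
  top_idx <- ord[seq_len(n_top)]
  bot_idx <- ord[(n - n_top + 1):n]
  occ <- colSums(pm)
  p_up <- vapply(seq_len(ncol(pm)), function(j) {
    hypergeom_tail(sum(pm[top_idx, j]), occ[j], n, n_top)
  }, numeric(1))
  p_dn <- vapply(seq_len(ncol(pm)), function(j) {
    hypergeom_tail(sum(pm[bot_idx, j]), occ[j], n, n_top)
  }, numeric(1))
  q_up <- bh_fdr(p_up)$q
  q_dn <- bh_fdr(p_dn)$q
  down_dominates <- q_dn < q_up | (q_dn == q_up & p_dn < p_up)
  q <- ifelse(down_dominates, q_dn, q_up)
  res <- data.frame(motif_id = colnames(pm),
                    occurrence_count = as.integer(occ),
                    direction = ifelse(down_dominates, "down", "up"),
                    enrichment_p = ifelse(down_dominates, p_dn, p_up),
                    q = q,
                    signed_score = -log10(pmax(q, .Machine$double.xmin)) *
                      ifelse(down_dominates, -1, 1),
                    stringsAsFactors = FALSE)
  res <- res[order(-abs(res$signed_score), res$motif_id), ]
  rownames(res) <- NULL
  res
}
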