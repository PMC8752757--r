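require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read an expression matrix with its group sidecar
#'
#' The expression contract: a TSV whose first column holds gene symbols and
#' whose header holds sample ids, plus a two-column sidecar
#' (`sample_id`, `group` with values control/case).
#'
#' @param matrix_path,group_path File paths.
#' @param dataset_id Label for the dataset (defaults to the matrix file name).
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(matrix_path, group_path,
                                dataset_id = basename(matrix_path)) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("expression matrix needs >= 2 sample columns")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", matrix_path)
  grp <- utils::read.delim(group_path, stringsAsFactors = FALSE)
  require_columns(grp, c("sample_id", "group"), "group file")
  if (anyDuplicated(grp$sample_id)) stop("duplicate sample ids in ", group_path)
  if (!setequal(grp$sample_id, colnames(m))) {
    stop("group file samples do not match matrix columns")
  }
  expression_dataset(dataset_id, m,
                     grp$group[match(colnames(m), grp$sample_id)])
}

#' Write an expression dataset to the TSV contract
#'
#' @param ds An [expression_dataset()].
#' @param matrix_path,group_path Output paths.
#' @export
write_expression_tsv <- function(ds, matrix_path, group_path) {
  out <- data.frame(gene = rownames(ds$values), ds$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = colnames(ds$values),
                                group = ds$group),
                     group_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Read / write a survival cohort TSV
#'
#' Columns: `sample_id`, `time`, `event`, `expr`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_survival_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("sample_id", "time", "event", "expr"), "survival table")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in ", path)
  if (any(is.na(tab$time))) stop("missing follow-up times in ", path)
  tab
}

#' @rdname read_survival_tsv
#' @param cohort Data frame to write.
#' @export
write_survival_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a long-format CNA cohort TSV
#'
#' Columns: `sample_id`, `gene`, `category`, `linear_cn`, `expr`.
#'
#' @param path File path.
#' @return Data frame (validated by the CNA cohort checks).
#' @export
read_cna_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("sample_id", "gene", "category", "linear_cn", "expr"),
                  "CNA table")
  check_cna_cohort(tab)
  tab
}

#' @rdname read_cna_tsv
#' @param cohort Data frame to write.
#' @export
write_cna_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a DEG table TSV
#'
#' Columns: `gene`, `log2fc`, `stat`, `p`, `q`, `rank`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_deg_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("gene", "log2fc", "stat", "p", "q", "rank"),
                  "DEG table")
  tab
}

#' @rdname read_deg_tsv
#' @param table Data frame to write.
#' @export
write_deg_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene set (one symbol per line)
#'
#' @param path File path.
#' @return Character vector (case preserved, blank lines dropped).
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_set
#' @param genes Character vector to write.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings returning / accepting a plain named
#' character vector; written sequences are wrapped at 60 columns.
#'
#' @param path File path.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read / write BED peak intervals
#'
#' BED convention: 0-based half-open intervals, tab-separated, no header;
#' columns chrom, start, end and optionally name. Malformed records error
#' with their line number.
#'
#' @param path File path.
#' @return Data frame: `chrom`, `start`, `end`, `peak_id`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3) stop("BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) stop("BED line ", i, ": non-integer coordinates")
    if (end <= start) stop("BED line ", i, ": end <= start")
    data.frame(chrom = f[1], start = start, end = end,
               peak_id = if (length(f) >= 4) f[4] else paste0("peak", i),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname read_bed
#' @param peaks Data frame with `chrom`, `start`, `end` and optionally
#'   `peak_id`.
#' @export
write_bed <- function(peaks, path) {
  require_columns(peaks, c("chrom", "start", "end"), "peak table")
  cols <- peaks[, intersect(c("chrom", "start", "end", "peak_id"),
                            names(peaks)), drop = FALSE]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a peak count matrix TSV
#'
#' First column `peak_id`, remaining columns one per sample.
#'
#' @param path File path.
#' @return Numeric matrix with peak rownames.
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  require_columns(tab, "peak_id", "count matrix")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$peak_id
  m
}

#' @rdname read_counts_tsv
#' @param counts Matrix to write.
#' @export
write_counts_tsv <- function(counts, path) {
  out <- data.frame(peak_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
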