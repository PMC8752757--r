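MOTIF_GAP <- "-"

#' Extract phosphosite sequence windows
#'
#' For each (protein, position) phosphosite, take the 11-residue window at
#' offsets -5..+5 around the phosphorylated serine/threonine, padding with a
#' gap symbol where the window overhangs a terminus. Positions are 1-based.
#'
#' @param proteome Named character vector of protein sequences (or a
#'   `Biostrings::AAStringSet`).
#' @param sites Data frame with columns `protein_id`, `position`.
#' @param flank Residues on each side of the site (default 5).
#' @return Data frame: `protein_id`, `position`, `residue`, `window`.
#' @export
extract_windows <- function(proteome, sites, flank = 5L) {
  seqs <- as_protein_vector(proteome)
  out <- lapply(seq_len(nrow(sites)), function(i) {
    id <- sites$protein_id[i]; pos <- sites$position[i]
    if (!id %in% names(seqs)) stop("unknown protein: ", id)
    s <- seqs[[id]]
    if (pos < 1 || pos > nchar(s)) stop("position out of bounds for ", id)
    res <- substr(s, pos, pos)
    if (!res %in% c("S", "T")) {
      stop("site ", id, ":", pos, " is ", res, ", not S/T")
    }
    chars <- vapply((pos - flank):(pos + flank), function(p) {
      if (p < 1 || p > nchar(s)) MOTIF_GAP else substr(s, p, p)
    }, character(1))
    data.frame(protein_id = id, position = pos, residue = res,
               window = paste(chars, collapse = ""), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Infer a kinase-substrate consensus motif from aligned windows
#'
#' Column-wise consensus over aligned phosphosite windows: an offset where all
#' (non-gap) residues agree becomes a fixed position; 2 to `max_class`
#' distinct residues become a bracketed residue class, ordered by decreasing
#' frequency with ties broken by first occurrence across the
#' lexicographically ordered windows; more
#' distinct residues than `max_class` become the wildcard `x`. The central
#' offset is the designated phospho-position, rendered with a trailing `*`.
#'
#' @param windows Character vector of equal-width windows (odd width), or the
#'   data frame from [extract_windows()].
#' @param max_class Largest residue-class size before collapsing to wildcard.
#' @return A `consensus_motif`: list with `positions` (per offset a list of
#'   `type` in fixed/class/wildcard and `residues`), `phospho_index`.
#' @export
infer_consensus <- function(windows, max_class = 3L) {
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) < 2) stop("need at least 2 windows")
  w <- unique(nchar(windows))
  if (length(w) != 1) stop("windows differ in width")
  # canonicalize: the frequency tie-break below uses first occurrence, so
  # order the windows lexicographically to stay permutation-invariant
  mat <- do.call(rbind, strsplit(sort(windows, method = "radix"), ""))
  positions <- lapply(seq_len(w), function(j) {
    col <- mat[, j]
    col <- col[col != MOTIF_GAP]
    tabs <- table(col)
    # decreasing frequency, ties by first occurrence among the windows
    ord <- order(-as.numeric(tabs), match(names(tabs), col))
    resid <- names(tabs)[ord]
    if (length(resid) == 1) {
      list(type = "fixed", residues = resid)
    } else if (length(resid) <= max_class) {
      list(type = "class", residues = resid)
    } else {
      list(type = "wildcard", residues = character(0))
    }
  })
  structure(list(positions = positions, phospho_index = (w + 1L) / 2L),
            class = "consensus_motif")
}

#' Render a consensus motif in bracket notation
#'
#' Fixed positions print their residue, classes print as `[...]`, wildcards as
#' `x`; the phospho-position carries a trailing `*` (e.g.
#' `LxRxxS*[AVM]Pxx[ILV]`).
#'
#' @param m A `consensus_motif`.
#' @return Single character string.
#' @export
render_motif <- function(m) {
  stopifnot(inherits(m, "consensus_motif"))
  parts <- vapply(seq_along(m$positions), function(i) {
    p <- m$positions[[i]]
    s <- switch(p$type,
                fixed = p$residues,
                class = paste0("[", paste(p$residues, collapse = ""), "]"),
                wildcard = "x")
    if (!is.na(m$phospho_index) && i == m$phospho_index) paste0(s, "*") else s
  }, character(1))
  paste(parts, collapse = "")
}

#' Parse bracket motif notation
#'
#' Inverse of [render_motif()]: `x` is a wildcard (exactly one arbitrary
#' residue), brackets enclose a residue class, a trailing `*` marks the
#' phospho-position. Patterns without a `*` (such as the 14-3-3 binding motif
#' `R[ST]xSxP`) parse with `phospho_index = NA`.
#'
#' @param text Motif string.
#' @return A `consensus_motif`.
#' @export
parse_motif <- function(text) {
  chars <- strsplit(text, "")[[1]]
  positions <- list(); phospho <- NA_integer_
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      positions[[length(positions) + 1]] <- list(type = "wildcard",
                                                 residues = character(0))
      i <- i + 1
    } else if (ch == "[") {
      j <- i + 1
      while (j <= length(chars) && chars[j] != "]") {
        if (chars[j] == "[") stop("nested bracket at column ", j)
        j <- j + 1
      }
      if (j > length(chars)) stop("unclosed bracket opened at column ", i)
      if (j == i + 1) stop("empty bracket at column ", i)
      positions[[length(positions) + 1]] <-
        list(type = "class", residues = chars[(i + 1):(j - 1)])
      i <- j + 1
    } else if (ch == "]") {
      stop("unmatched closing bracket at column ", i)
    } else if (ch == "*") {
      if (length(positions) == 0) stop("'*' before any position at column ", i)
      phospho <- length(positions)
      i <- i + 1
    } else if (grepl("^[A-Z]$", ch)) {
      positions[[length(positions) + 1]] <- list(type = "fixed", residues = ch)
      i <- i + 1
    } else {
      stop("unexpected character '", ch, "' at column ", i)
    }
  }
  structure(list(positions = positions, phospho_index = phospho),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(render_motif(x), "\n")
  invisible(x)
}

# does the window of `seq` anchored so that motif position `anchor` sits on
# `pos` satisfy every fixed/class position? Non-wildcard positions falling
# outside the sequence fail (conservative terminal handling).
motif_matches_at <- function(s, pos, motif, anchor) {
  n <- nchar(s)
  for (i in seq_along(motif$positions)) {
    p <- motif$positions[[i]]
    if (p$type == "wildcard") next
    sp <- pos + (i - anchor)
    if (sp < 1 || sp > n) return(FALSE)
    if (!substr(s, sp, sp) %in% p$residues) return(FALSE)
  }
  TRUE
}

#' Scan a proteome for consensus-motif matches
#'
#' Reports every target residue (serine by default) whose aligned sequence
#' context satisfies all fixed and class positions of the motif. Overlapping
#' matches are all reported; windows truncated by a terminus fail any
#' non-wildcard position falling outside the sequence.
#'
#' @param proteome Named character vector of sequences (or `AAStringSet`).
#' @param motif A `consensus_motif` with a phospho-position.
#' @param target_residues Residues eligible as the phosphosite.
#' @return Data frame: `protein_id`, `position`, `window` (the aligned
#'   subsequence, gap-padded at termini).
#' @export
scan_proteome <- function(proteome, motif, target_residues = "S") {
  stopifnot(inherits(motif, "consensus_motif"), !is.na(motif$phospho_index))
  seqs <- as_protein_vector(proteome)
  width <- length(motif$positions)
  anchor <- motif$phospho_index
  hits <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    chars <- strsplit(s, "")[[1]]
    cand <- which(chars %in% target_residues)
    ok <- cand[vapply(cand, function(pos) motif_matches_at(s, pos, motif, anchor),
                      logical(1))]
    if (!length(ok)) return(NULL)
    win <- vapply(ok, function(pos) {
      idx <- pos + (seq_len(width) - anchor)
      paste(ifelse(idx < 1 | idx > length(chars), MOTIF_GAP, chars[pmax(pmin(idx, length(chars)), 1)]),
            collapse = "")
    }, character(1))
    data.frame(protein_id = id, position = ok, window = win,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(protein_id = character(0), position = integer(0),
                       window = character(0), stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  hits
}

#' Annotate motif matches with mass-spec confirmation and 14-3-3 co-match
#'
#' Flags each candidate site as (a) present in a list of mass-spec-confirmed
#' phosphosites and (b) also matching a secondary motif — by default the
#' 14-3-3 binding pattern `R[ST]xSxP`, anchored with its second serine (the
#' 4th symbol) on the candidate phosphosite, i.e. covering offsets -3..+2.
#'
#' @param matches Output of [scan_proteome()].
#' @param proteome The scanned proteome (needed to test the secondary motif).
#' @param ms_confirmed_sites Data frame `protein_id`, `position` (may be empty).
#' @param secondary_motif A `consensus_motif`; its anchor is its
#'   `phospho_index` when set, otherwise its 4th position (the mode-1 14-3-3
#'   convention).
#' @return `matches` with logical columns `confirmed_by_ms`, `matches_14_3_3`.
#' @export
annotate_matches <- function(matches, proteome,
                             ms_confirmed_sites = NULL,
                             secondary_motif = parse_motif("R[ST]xSxP")) {
  seqs <- as_protein_vector(proteome)
  key <- paste(matches$protein_id, matches$position)
  if (is.null(ms_confirmed_sites) || nrow(ms_confirmed_sites) == 0) {
    matches$confirmed_by_ms <- rep(FALSE, nrow(matches))
  } else {
    matches$confirmed_by_ms <-
      key %in% paste(ms_confirmed_sites$protein_id, ms_confirmed_sites$position)
  }
  anchor <- if (!is.na(secondary_motif$phospho_index)) {
    secondary_motif$phospho_index
  } else 4L
  matches$matches_14_3_3 <- vapply(seq_len(nrow(matches)), function(i) {
    motif_matches_at(seqs[[matches$protein_id[i]]], matches$position[i],
                     secondary_motif, anchor)
  }, logical(1))
  matches
}

as_protein_vector <- function(proteome) {
  if (inherits(proteome, "AAStringSet") || inherits(proteome, "XStringSet")) {
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  }
  stopifnot(is.character(proteome))
  if (length(proteome)) stopifnot(!is.null(names(proteome)))
  proteome
}
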