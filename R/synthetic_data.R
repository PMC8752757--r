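#' Default generator settings
#'
#' The study conditions every synthetic input emulates, gathered in one
#' place. Expression: two microarray-like cohorts on the log2 scale with a
#' shared set of truly differential genes plus dataset-private decoys.
#' Survival: a TCGA-like cohort with a step hazard at an expression quantile
#' (the structure the cut-point scan is designed to detect). CNA: a
#' neighboring-locus block with a shared latent copy-number state, a
#' deletion-dominant category profile, and expression tracking the category.
#' Motif: a uniform-background proteome with exact-match planted substrate
#' sites. Peaks: ATAC-like peak sequences and negative-binomial counts with
#' accessibility loss planted on motif-bearing peaks.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @param ... Named overrides of any default listed below.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 1L, ...) {
  spec <- list(
    seed = as.integer(seed),
    n_genes = 2000L,
    n_samples_per_group = 10L,
    n_shared_de = 50L,
    n_specific_de = 25L,
    effect_size = 2.0,       # log2 units
    noise_sd = 0.5,          # log2 units
    baseline_log2 = 7,       # mean baseline log2 intensity
    survival = list(n = 400L, baseline_hazard = 0.02,  # events per month
                    hazard_ratio = 3, threshold_quantile = 0.7,
                    censor_rate = 0.3),
    cna = list(n = 400L, neighbor_rho = 0.9,
               # deep deletion, deletion, diploid, gain, amplification;
               # deletion-dominant, emulating a 14q32-like locus
               category_probs = c(0.05, 0.384, 0.416, 0.12, 0.03),
               cn_log2_sd = 0.25, expr_slope = 0.8, expr_sd = 0.5),
    motif = list(n_proteins = 50L, protein_length = 1000L, n_planted = 20L,
                 ms_confirmed_frac = 0.5),
    peaks = list(n_peaks = 2000L, peak_length = 200L,
                 planted_motif_frac = 0.05, fold_change = 0.25,
                 n_samples_per_group = 3L, nb_size = 10,
                 base_mean = 50, base_log_sd = 0.5)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(spec[[nm]]) && is.list(dots[[nm]])) {
      spec[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      spec[[nm]] <- dots[[nm]]
    }
  }
  stopifnot(spec$n_shared_de + 2 * spec$n_specific_de <= spec$n_genes)
  structure(spec, class = "generator_spec")
}

gene_names <- function(n) sprintf("gene%04d", seq_len(n))

#' Generate a pair of expression datasets with shared planted DE genes
#'
#' Two log2 expression cohorts sharing `n_shared_de` truly differential genes
#' (same sign in both), each carrying `n_specific_de` private decoy DE genes,
#' with independent Gaussian noise on the log2 scale. Group sizes default to
#' `spec$n_samples_per_group` per group and can be set per dataset to emulate
#' unbalanced microarray series.
#'
#' @param spec A [generator_spec()].
#' @param n_control,n_case Optional length-2 integer vectors of per-dataset
#'   group sizes.
#' @return List: `datasets` (two [expression_dataset()]), `truth` (data.frame
#'   `gene`, `sign`, `kind` in shared/specific1/specific2).
#' @export
make_expression_pair <- function(spec = generator_spec(),
                                 n_control = NULL, n_case = NULL) {
  set.seed(spec$seed)
  g <- spec$n_genes
  genes <- gene_names(g)
  if (is.null(n_control)) n_control <- rep(spec$n_samples_per_group, 2)
  if (is.null(n_case)) n_case <- rep(spec$n_samples_per_group, 2)
  baseline <- stats::rnorm(g, spec$baseline_log2, 1)
  idx <- sample.int(g, spec$n_shared_de + 2 * spec$n_specific_de)
  shared <- idx[seq_len(spec$n_shared_de)]
  spec1 <- idx[spec$n_shared_de + seq_len(spec$n_specific_de)]
  spec2 <- idx[spec$n_shared_de + spec$n_specific_de + seq_len(spec$n_specific_de)]
  signs <- stats::setNames(sample(c(-1, 1), length(idx), replace = TRUE), idx)
  build <- function(did, nc, nk, de_idx) {
    n <- nc + nk
    m <- matrix(stats::rnorm(g * n, 0, spec$noise_sd), g, n) + baseline
    group <- c(rep("control", nc), rep("case", nk))
    for (i in de_idx) {
      m[i, group == "case"] <- m[i, group == "case"] +
        signs[as.character(i)] * spec$effect_size
    }
    dimnames(m) <- list(genes, paste0(did, "_s", seq_len(n)))
    expression_dataset(did, m, group)
  }
  ds1 <- build("dataset1", n_control[1], n_case[1], c(shared, spec1))
  ds2 <- build("dataset2", n_control[2], n_case[2], c(shared, spec2))
  truth <- data.frame(
    gene = genes[c(shared, spec1, spec2)],
    sign = unname(signs[as.character(c(shared, spec1, spec2))]),
    kind = rep(c("shared", "specific1", "specific2"),
               c(length(shared), length(spec1), length(spec2))),
    stringsAsFactors = FALSE)
  list(datasets = list(ds1, ds2), truth = truth)
}

#' Generate a survival cohort with a step hazard at an expression quantile
#'
#' Per-sample expression is standard normal; event times are exponential with
#' baseline hazard below the threshold quantile and `hazard_ratio`-fold hazard
#' above it. Each record is independently censored with probability
#' `censor_rate`, at a uniform time before its event.
#'
#' @param spec A [generator_spec()].
#' @return List: `cohort` (data.frame `sample_id`, `time`, `event`, `expr`),
#'   `truth` (threshold quantile, hazard ratio, per-sample high-hazard flag).
#' @export
make_survival_cohort <- function(spec = generator_spec()) {
  set.seed(spec$seed)
  sv <- spec$survival
  n <- sv$n
  expr <- stats::rnorm(n)
  thr <- stats::quantile(expr, sv$threshold_quantile)
  high_hazard <- expr > thr
  hz <- sv$baseline_hazard * ifelse(high_hazard, sv$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate = hz)
  censored <- stats::runif(n) < sv$censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  cohort <- data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                       time = time, event = as.integer(!censored),
                       expr = expr, stringsAsFactors = FALSE)
  list(cohort = cohort,
       truth = list(threshold_quantile = sv$threshold_quantile,
                    hazard_ratio = sv$hazard_ratio,
                    high_hazard = high_hazard))
}

#' Generate a correlated neighboring-locus CNA cohort
#'
#' Loci share a latent per-sample Gaussian copy-number state along a chain
#' with adjacent-locus correlation `neighbor_rho` (so correlation decays with
#' chain distance). Relative linear copy number is lognormal around the
#' latent state (`2^(cn_log2_sd * z)`); the discrete category per locus is a
#' cohort-relative (GISTIC-like) call: quantile cuts of the latent state at
#' the cumulative `category_probs`. Expression follows the category linearly
#' with Gaussian noise.
#'
#' @param spec A [generator_spec()].
#' @param loci Character vector of locus (gene) names along the chain.
#' @return List: `cohort` (long data.frame `sample_id`, `gene`, `category`,
#'   `linear_cn`, `expr`), `truth` (neighbor_rho, category_probs, latent
#'   matrix).
#' @export
make_cna_cohort <- function(spec = generator_spec(),
                            loci = c("locusA", "locusB", "locusC")) {
  set.seed(spec$seed)
  cn <- spec$cna
  n <- cn$n
  k <- length(loci)
  z <- matrix(NA_real_, n, k)
  z[, 1] <- stats::rnorm(n)
  if (k > 1) for (j in 2:k) {
    z[, j] <- cn$neighbor_rho * z[, j - 1] +
      sqrt(1 - cn$neighbor_rho^2) * stats::rnorm(n)
  }
  cuts <- stats::qnorm(cumsum(cn$category_probs)[-length(cn$category_probs)])
  cohort <- do.call(rbind, lapply(seq_len(k), function(j) {
    cat_j <- CNA_CATEGORIES[findInterval(z[, j], cuts) + 1L]
    data.frame(sample_id = sprintf("s%04d", seq_len(n)),
               gene = loci[j],
               category = cat_j,
               linear_cn = 2^(cn$cn_log2_sd * z[, j]),
               expr = cn$expr_slope * cat_j + stats::rnorm(n, 0, cn$expr_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(cohort) <- NULL
  list(cohort = cohort,
       truth = list(neighbor_rho = cn$neighbor_rho,
                    category_probs = cn$category_probs, latent = z))
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

realize_motif <- function(motif) {
  vapply(seq_along(motif$positions), function(i) {
    p <- motif$positions[[i]]
    if (i == motif$phospho_index) {
      if (p$type == "wildcard") "S" else intersect(p$residues, c("S", "T"))[1]
    } else {
      switch(p$type,
             fixed = p$residues,
             class = sample(p$residues, 1),
             wildcard = sample(AA_ALPHABET, 1))
    }
  }, character(1))
}

#' Generate a synthetic proteome with planted motif matches
#'
#' Random protein sequences with uniform amino-acid background, into which
#' `n_planted` exact realizations of the motif are written at recorded,
#' non-overlapping positions; a configurable fraction of planted sites is
#' marked as mass-spec confirmed.
#'
#' @param spec A [generator_spec()].
#' @param motif A `consensus_motif` with a phospho-position.
#' @return List: `proteome` (named character vector), `planted` (data.frame
#'   `protein_id`, `position`), `ms_confirmed` (subset of `planted`).
#' @export
make_proteome <- function(spec = generator_spec(), motif) {
  stopifnot(inherits(motif, "consensus_motif"), !is.na(motif$phospho_index))
  set.seed(spec$seed)
  mo <- spec$motif
  width <- length(motif$positions)
  stopifnot(mo$protein_length > width)
  seqs <- vapply(seq_len(mo$n_proteins), function(i) {
    paste(sample(AA_ALPHABET, mo$protein_length, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("prot%03d", seq_len(mo$n_proteins))
  planted <- data.frame(protein_id = character(0), position = integer(0))
  used <- list()
  i <- 0L
  while (i < mo$n_planted) {
    pid <- sample(names(seqs), 1)
    start <- sample.int(mo$protein_length - width + 1L, 1)
    win <- c(start, start + width - 1L)
    clash <- any(vapply(used[[pid]] %||% list(), function(w) {
      win[1] <= w[2] && w[1] <= win[2]
    }, logical(1)))
    if (clash) next
    used[[pid]] <- c(used[[pid]], list(win))
    inst <- paste(realize_motif(motif), collapse = "")
    substr(seqs[pid], start, start + width - 1L) <- inst
    planted <- rbind(planted, data.frame(
      protein_id = pid, position = start + motif$phospho_index - 1L,
      stringsAsFactors = FALSE))
    i <- i + 1L
  }
  planted <- planted[order(planted$protein_id, planted$position), ]
  rownames(planted) <- NULL
  n_ms <- round(mo$ms_confirmed_frac * nrow(planted))
  ms <- planted[sample.int(nrow(planted), n_ms), , drop = FALSE]
  ms <- ms[order(ms$protein_id, ms$position), ]
  rownames(ms) <- NULL
  list(proteome = seqs, planted = planted, ms_confirmed = ms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pfm_consensus <- function(pfm) {
  paste(DNA_BASES[apply(pfm$counts, 2, which.max)], collapse = "")
}

#' Random decoy position frequency matrices
#'
#' Sharp PFMs around random consensus sequences, for use as decoy motifs in
#' enrichment simulations. Uses the current RNG state.
#'
#' @param n Number of motifs.
#' @param length Motif length in bases.
#' @param depth Total count per column.
#' @param prefix Motif id prefix.
#' @return Named list of `pfm` objects.
#' @export
make_random_pfms <- function(n, length = 8L, depth = 100, prefix = "DECOY") {
  out <- lapply(seq_len(n), function(i) {
    cons <- sample(4, length, replace = TRUE)
    counts <- matrix(depth * 0.04, 4, length, dimnames = list(DNA_BASES, NULL))
    counts[cbind(cons, seq_len(length))] <- depth * 0.88
    id <- sprintf("%s%02d", prefix, i)
    structure(list(motif_id = id, name = id, counts = counts), class = "pfm")
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "motif_id"))
}

#' Generate an ATAC-like peak set with planted motif-linked accessibility loss
#'
#' Random peak sequences with the motif consensus embedded in a
#' `planted_motif_frac` subset; negative-binomial raw counts per sample with
#' a lognormal per-peak baseline, and the condition-group mean of
#' motif-bearing peaks multiplied by `fold_change` (values below 1 plant an
#' accessibility decrease).
#'
#' @param spec A [generator_spec()].
#' @param pfm The planted motif's `pfm`.
#' @return List: `peaks` (data.frame `peak_id`, `chrom`, `start`, `end`,
#'   `sequence`), `counts` (peaks x samples), `condition` (per-sample labels),
#'   `truth` (ids of motif-bearing peaks).
#' @export
make_peakset <- function(spec = generator_spec(), pfm) {
  set.seed(spec$seed)
  pk <- spec$peaks
  n <- pk$n_peaks
  cons <- pfm_consensus(pfm)
  L <- nchar(cons)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, pk$peak_length, replace = TRUE), collapse = "")
  }, character(1))
  planted_idx <- sort(sample.int(n, round(pk$planted_motif_frac * n)))
  for (i in planted_idx) {
    start <- sample.int(pk$peak_length - L + 1L, 1)
    substr(seqs[i], start, start + L - 1L) <- cons
  }
  ids <- sprintf("peak%05d", seq_len(n))
  peaks <- data.frame(peak_id = ids, chrom = "chr1",
                      start = seq_len(n) * 1000L,
                      end = seq_len(n) * 1000L + pk$peak_length,
                      sequence = seqs, stringsAsFactors = FALSE)
  ns <- pk$n_samples_per_group
  condition <- c(rep("control", ns), rep("condition", ns))
  base <- pk$base_mean * exp(stats::rnorm(n, 0, pk$base_log_sd))
  mu <- matrix(base, n, 2 * ns)
  mu[planted_idx, condition == "condition"] <-
    mu[planted_idx, condition == "condition"] * pk$fold_change
  counts <- matrix(stats::rnbinom(n * 2 * ns, mu = mu, size = pk$nb_size),
                   n, 2 * ns,
                   dimnames = list(ids, paste0(condition, "_", seq_len(2 * ns))))
  list(peaks = peaks, counts = counts, condition = condition,
       truth = list(planted_peaks = ids[planted_idx], consensus = cons))
}
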