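toy_jaspar_text <- c(
  ">MA0001 toyAP1",
  "A  [ 10  0  1 15  0  1  9 ]",
  "C  [  2  1  0  0 14  1  2 ]",
  "G  [  1 15  1  0  1  0  3 ]",
  "T  [  3  0 14  1  1 14  2 ]",
  ">MA0002 toyCTCF",
  "A  [ 5 0 9 ]",
  "C  [ 2 9 0 ]",
  "G  [ 1 3 2 ]",
  "T  [ 8 4 5 ]")

test_that("JASPAR parsing, row normalization, and round trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(toy_jaspar_text, path)
  pfms <- read_jaspar(path)
  expect_length(pfms, 2)
  expect_equal(dim(pfms$MA0001$counts), c(4L, 7L))
  expect_equal(rownames(pfms$MA0001$counts), c("A", "C", "G", "T"))
  expect_equal(pfms$MA0002$counts["T", ], c(8, 4, 5))

  # rows labeled in C,A,T,G order normalize to A,C,G,T
  permuted <- c(">MX1 permuted",
                "C [ 2 1 ]", "A [ 5 0 ]", "T [ 8 4 ]", "G [ 1 3 ]")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(permuted, path2)
  p2 <- read_jaspar(path2)
  expect_equal(p2$MX1$counts["A", ], c(5, 0))
  expect_equal(p2$MX1$counts["C", ], c(2, 1))

  path3 <- withr::local_tempfile(fileext = ".txt")
  write_jaspar(pfms, path3)
  again <- read_jaspar(path3)
  expect_equal(again$MA0001$counts, pfms$MA0001$counts)
  expect_equal(again$MA0002$name, "toyCTCF")

  bad <- c(">MBAD x", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]")
  path4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(bad, path4)
  expect_error(read_jaspar(path4), "MBAD")
})

test_that("PWM scanning matches the hand log-odds oracle on both strands", {
  counts <- matrix(c(8, 1, 1, 0,   0, 9, 0, 1,   2, 0, 7, 1,   1, 1, 0, 8),
                   nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm <- structure(list(motif_id = "toy", name = "toy", counts = counts),
                   class = "pfm")
  seq <- "ACGTTACGATCG"
  hits <- pwm_scan(seq, pfm, threshold_frac = 0.5)
  fwd <- oracle_pwm_scores(seq, counts)
  rev <- oracle_pwm_scores(oracle_revcomp(seq), counts)
  # each column sums to 10; with pseudocount 0.5 the denominator is 10 + 2
  max_score <- sum(apply(log2((counts + 0.5) / 12 / 0.25), 2, max))
  n <- nchar(seq); L <- ncol(counts)
  want <- rbind(
    data.frame(position = which(fwd >= 0.5 * max_score), strand = "+",
               score = fwd[fwd >= 0.5 * max_score]),
    data.frame(position = n - L + 2 - which(rev >= 0.5 * max_score), strand = "-",
               score = rev[rev >= 0.5 * max_score]))
  want <- want[order(want$position, want$strand), ]
  expect_equal(hits$position, want$position)
  expect_equal(hits$score, want$score, tolerance = 1e-9)

  # consensus sequence scores the maximum at position 1
  cons <- "ACGT"
  h <- pwm_scan(cons, pfm, threshold_frac = 0.999)
  expect_true(any(h$position == 1 & h$strand == "+"))
  expect_equal(max(h$score), max_score, tolerance = 1e-9)
  # all-N sequence has no hits
  expect_equal(nrow(pwm_scan("NNNNNNNN", pfm, threshold_frac = 0.2)), 0)

  set.seed(401)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    got <- pwm_scan(s, pfm, threshold_frac = -100)  # keep every window
    fwd <- oracle_pwm_scores(s, counts)
    expect_equal(got$score[got$strand == "+"], unname(fwd), tolerance = 1e-9)
  }
})

test_that("peak-motif matrix counts embedded consensus and ignores peak order", {
  set.seed(402)
  pfms <- make_random_pfms(2, 8)
  cons <- paste(c("A", "C", "G", "T")[apply(pfms[[1]]$counts, 2, which.max)],
                collapse = "")
  n <- 100
  seqs <- vapply(1:n, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1))
  carriers <- 1:10
  for (i in carriers) substr(seqs[i], 20, 27) <- cons
  peaks <- data.frame(peak_id = sprintf("pk%03d", 1:n), chrom = "chr1",
                      start = 0:(n - 1) * 100, end = 0:(n - 1) * 100 + 60,
                      sequence = seqs, stringsAsFactors = FALSE)
  pm <- peak_motif_matrix(peaks, pfms[1])
  expect_true(all(pm[carriers, 1] == 1))
  expect_gte(sum(pm[, 1]), 10)
  perm <- sample(n)
  pm_perm <- peak_motif_matrix(peaks[perm, ], pfms[1])
  expect_equal(unname(pm_perm[order(perm), 1]), unname(pm[, 1]))
  peaks$sequence[3] <- ""
  expect_error(peak_motif_matrix(peaks, pfms[1]), "pk003")
})

test_that("differential peak scores: zero under identity, antisymmetric under label swap", {
  set.seed(403)
  counts <- matrix(rpois(200 * 6, 40), 200, 6,
                   dimnames = list(sprintf("pk%03d", 1:200), paste0("s", 1:6)))
  cond <- rep(c("control", "condition"), each = 3)
  # identical conditions: mirror the control block
  sym <- cbind(counts[, 1:3], counts[, 1:3])
  colnames(sym) <- paste0("s", 1:6)
  expect_equal(unname(differential_peaks(sym, cond)), rep(0, 200))
  sc <- differential_peaks(counts, cond)
  sc_swap <- differential_peaks(counts, rev(cond))
  expect_equal(sc_swap, -sc, tolerance = 1e-9)
  expect_error(differential_peaks(counts - 100, cond), "negative")

  # planted 4-fold increase is top-ranked
  counts2 <- counts
  counts2[1:10, 4:6] <- counts2[1:10, 4:6] * 4
  sc2 <- differential_peaks(counts2, cond)
  expect_true(all(rank(-sc2)[1:10] <= 15))
})

test_that("module-map enrichment matches the hypergeometric oracle on a 30-peak instance", {
  pm <- matrix(0L, 30, 2, dimnames = list(sprintf("pk%02d", 1:30), c("m1", "m2")))
  pm[1:12, 1] <- 1L   # motif m1 sits in the top-scoring peaks
  pm[c(5, 20, 25), 2] <- 1L
  scores <- 30:1
  res <- module_map_enrichment(pm, scores, top_frac = 0.4)  # top/bottom 12
  m1 <- res[res$motif_id == "m1", ]
  p_top <- oracle_hypergeom_tail_choose(12, 12, 30, 12)
  expect_equal(m1$enrichment_p, p_top, tolerance = 1e-9)
  expect_equal(m1$direction, "up")
  expect_equal(res$motif_id[1], "m1")
  expect_gt(m1$signed_score, 0)
  # q never below p, ranking stable under motif column permutation
  expect_true(all(res$q >= res$enrichment_p - 1e-12))
  res_perm <- module_map_enrichment(pm[, 2:1], scores, top_frac = 0.4)
  expect_equal(res_perm$motif_id, res$motif_id)
  expect_equal(res_perm$signed_score, res$signed_score)
  expect_error(module_map_enrichment(pm, scores, top_frac = 0.01), "more peaks")
})

test_that("a motif planted in bottom-scoring peaks ranks first with negative sign", {
  set.seed(405)
  pfms <- make_random_pfms(4, 8, prefix = "D")
  hits <- vapply(1:25, function(i) {
    ps <- make_peakset(generator_spec(5000 + i, peaks = list(n_peaks = 400L)),
                       pfms[[1]])
    pm <- peak_motif_matrix(ps$peaks, pfms)
    sc <- differential_peaks(ps$counts, ps$condition)
    en <- module_map_enrichment(pm, sc, top_frac = 0.05)
    en$motif_id[1] == "D01" && en$signed_score[1] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
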