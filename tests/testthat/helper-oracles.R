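# Independent brute-force / closed-form oracles. These re-derive each
# statistic from its definition (enumeration, sums of squares, product
# limits) and never call the implementation path they check.

oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(statistic = t, p_value = 2 * pt(-abs(t), df), df = df)
}

oracle_anova_f <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = pf(f, df1, df2, lower.tail = FALSE))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(t), n - 2))
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[ord] <- pmin(q_sorted, 1)
  q
}

oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = tt, surv = surv)
}

oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tt) {
    n1 <- sum(time >= t & g == 1); n2 <- sum(time >= t & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    n <- n1 + n2; d <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(statistic = chisq, p_value = pchisq(chisq, 1, lower.tail = FALSE))
}

# enumerate every 2x2 table with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- prob[xs == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# exhaustive subset enumeration (small universes only)
oracle_hypergeom_tail <- function(overlap, set_size, universe, draws) {
  subsets <- combn(universe, draws)
  marked <- seq_len(set_size)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= overlap)
}

# counting-formula tail for instances too large to enumerate subject-by-subject
oracle_hypergeom_tail_choose <- function(overlap, set_size, universe, draws) {
  ks <- overlap:min(set_size, draws)
  sum(choose(set_size, ks) * choose(universe - set_size, draws - ks)) /
    choose(universe, draws)
}

oracle_quantile_normalize <- function(m) {
  n <- nrow(m)
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # non-integer (tied) ranks take the mean of the straddled rank values
    vapply(r, function(ri) {
      lo <- floor(ri); hi <- ceiling(ri)
      mean(ref[c(lo, hi)])
    }, numeric(1))
  })
}

# windowed log-odds PWM scoring, written as the per-window double loop
oracle_pwm_scores <- function(seq, counts, pseudocount = 0.5) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(counts)
  vapply(seq_len(length(chars) - L + 1), function(st) {
    s <- 0
    for (j in seq_len(L)) {
      b <- chars[st + j - 1]
      if (b == "N") next
      s <- s + log2((counts[bases == b, j] + pseudocount) /
                      (sum(counts[, j]) + 4 * pseudocount) / 0.25)
    }
    s
  }, numeric(1))
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

# naive motif matcher: position-by-position loop over a parsed bracket motif
brute_motif_scan <- function(proteome, pattern, anchor, target = "S") {
  hits <- NULL
  for (id in names(proteome)) {
    chars <- strsplit(proteome[[id]], "")[[1]]
    for (pos in which(chars %in% target)) {
      ok <- TRUE
      for (i in seq_along(pattern)) {
        allowed <- pattern[[i]]
        if (is.null(allowed)) next            # wildcard
        sp <- pos + i - anchor
        if (sp < 1 || sp > length(chars) || !chars[sp] %in% allowed) {
          ok <- FALSE; break
        }
      }
      if (ok) hits <- rbind(hits, data.frame(protein_id = id, position = pos))
    }
  }
  if (is.null(hits)) data.frame(protein_id = character(0), position = integer(0))
  else hits
}

# turn a consensus_motif into the plain allowed-residue list brute_motif_scan uses
motif_to_pattern <- function(m) {
  lapply(m$positions, function(p) if (p$type == "wildcard") NULL else p$residues)
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

engineered_substrate_windows <- function() {
  c("LARFGSAPDHI", "LCRGHSVPEKL", "LDRHISMPFMV", "LERIKSAPGNI")
}
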