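# Independent oracles used to freeze expected values. These deliberately
# re-derive each quantity from its definition, by loops/enumeration, and
# never call the package functions they check.

# Two-way balanced ANOVA by definitional sums of squares (explicit loops).
oracle_anova <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  gm <- sum(y) / (n * k)
  ss_state <- 0
  for (c in seq_len(k)) {
    m_c <- sum(y[, c]) / n
    ss_state <- ss_state + n * (m_c - gm)^2
  }
  ss_donor <- 0
  for (d in seq_len(n)) {
    m_d <- sum(y[d, ]) / k
    ss_donor <- ss_donor + k * (m_d - gm)^2
  }
  ss_tot <- 0
  for (d in seq_len(n)) for (c in seq_len(k)) {
    ss_tot <- ss_tot + (y[d, c] - gm)^2
  }
  ss_res <- ss_tot - ss_state - ss_donor
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms <- ss_state / df1
  msr <- ss_res / df2
  f <- ms / msr
  list(ms = ms, f = f, p = pf(f, df1, df2, lower.tail = FALSE),
       partial_t = vapply(seq_len(k), function(c) {
         (mean(y[, c]) - gm) / sqrt(msr * df1 / (n * k))
       }, 0))
}

# Benjamini-Hochberg step-up applied directly from the formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, (m / j) * p[o[j]]), 0)
    q[o[i]] <- min(vals)
  }
  q
}

# Two-sided Fisher p by exhaustive enumeration over tables with the
# observed margins, probabilities from choose() ratios.
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  n1 <- a + c
  N <- a + b + c + d
  lo <- max(0, n1 - (N - m1))
  hi <- min(m1, n1)
  prob <- vapply(lo:hi, function(x) {
    exp(lchoose(n1, x) + lchoose(N - n1, m1 - x) - lchoose(N, m1))
  }, 0)
  obs <- prob[a - lo + 1]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Two-sided exact signed-rank p by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    v <- sum(r[signs])
    if (abs(v - mu) >= abs(v_obs - mu) - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# Maximal same-sign run containing the seed, by brute force over all
# contiguous runs of covered CpGs.
oracle_extend <- function(pair, seed_index, min_diff = 0.05,
                          max_gap = 1000) {
  ch <- pair$chrom[seed_index]
  rows <- which(pair$chrom == ch & pair$covered)
  at <- match(seed_index, rows)
  ds <- pair$delta[seed_index]
  if (is.na(at) || is.na(ds) || abs(ds) < min_diff) return(NULL)
  sgn <- sign(ds)
  valid_run <- function(lo, hi) {
    idx <- rows[lo:hi]
    dd <- pair$delta[idx]
    if (any(is.na(dd)) || any(dd * sgn < min_diff)) return(FALSE)
    if (hi > lo && any(diff(pair$pos[idx]) > max_gap)) return(FALSE)
    TRUE
  }
  best <- c(at, at)
  for (lo in seq_len(at)) {
    for (hi in at:length(rows)) {
      if (valid_run(lo, hi) && (hi - lo) > (best[2] - best[1])) {
        best <- c(lo, hi)
      }
    }
  }
  idx <- rows[best[1]:best[2]]
  list(n_cpg = length(idx), start = min(pair$pos[idx]),
       end = max(pair$pos[idx]), mean_delta = mean(pair$delta[idx]))
}

# Quadratic all-pairs point-in-interval oracle.
oracle_point_labels <- function(track, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    for (j in seq_len(nrow(track))) {
      if (track$chrom[j] == chrom[i] &&
          pos[i] - 1 >= track$start[j] && pos[i] - 1 < track$end[j]) {
        return(track$label[j])
      }
    }
    NA_character_
  }, "")
}

# Brute-force nearest gene over all TSS/TES distances.
oracle_nearest_gene <- function(pos, chrom, genes) {
  gi <- genes[genes$chrom == chrom, , drop = FALSE]
  best <- NULL
  for (j in seq_len(nrow(gi))) {
    for (site in c("tss", "tes")) {
      d <- abs(pos - gi[[site]][j])
      cand <- list(gene = gi$gene[j], d = d, is_tss = site == "tss")
      if (is.null(best) || d < best$d ||
          (d == best$d && ((cand$is_tss && !best$is_tss) ||
                           (cand$is_tss == best$is_tss &&
                            cand$gene < best$gene)))) {
        best <- cand
      }
    }
  }
  best
}

# Per-offset PWM window scorer (forward strand), from the definition.
oracle_pwm_scores <- function(seq, pwm) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- pwm$length
  W <- length(chars)
  if (W < L) return(numeric(0))
  sm <- sweep(pwm$probs + pwm$pseudocount, 2,
              colSums(pwm$probs + pwm$pseudocount), "/")
  lo <- log2(sweep(sm, 1, pwm$background[c("A", "C", "G", "T")], "/"))
  vapply(seq_len(W - L + 1), function(o) {
    s <- 0
    for (l in seq_len(L)) {
      b <- chars[o + l - 1]
      if (b != "N") s <- s + lo[b, l]
    }
    s
  }, 0)
}

revcomp_str <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
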