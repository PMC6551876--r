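#' Construct a position weight matrix object
#'
#' @param name Motif name.
#' @param probs 4 x L numeric matrix of per-position base probabilities,
#'   rows named A, C, G, T; each column must sum to 1 within 1e-6.
#' @param pseudocount Smoothing pseudocount added before log-odds
#'   (default 0.01).
#' @param background Background base frequencies (default uniform).
#' @return Object of class `pwm`: list with `name`, `probs`, `logodds`
#'   (5 x L, bits; fifth row `N` scores 0), `max_score`, `length`.
#' @export
new_pwm <- function(name, probs, pseudocount = 0.01,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(is.matrix(probs), nrow(probs) == 4L, pseudocount > 0)
  if (is.null(rownames(probs))) rownames(probs) <- c("A", "C", "G", "T")
  probs <- probs[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(probs) - 1) > 1e-6)) {
    stop("PWM '", name, "': column probabilities must sum to 1")
  }
  sm <- sweep(probs + pseudocount, 2L, colSums(probs + pseudocount), "/")
  lo <- log2(sweep(sm, 1L, background[c("A", "C", "G", "T")], "/"))
  lo <- rbind(lo, N = 0)
  structure(list(name = name, probs = probs, pseudocount = pseudocount,
                 background = background, logodds = lo,
                 max_score = sum(apply(lo[1:4, , drop = FALSE], 2L, max)),
                 length = ncol(probs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "- length", x$length,
      sprintf("- max score %.2f bits\n", x$max_score))
  invisible(x)
}

.encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) {
    stop("invalid sequence character '", chars[which(is.na(code))[1L]], "'")
  }
  code
}

.revcomp_code <- function(code) {
  # A<->T (1<->4), C<->G (2<->3), N (5) fixed
  rev(c(4L, 3L, 2L, 1L, 5L)[code])
}

.score_offsets <- function(code, lo) {
  L <- ncol(lo)
  W <- length(code)
  if (W < L) return(numeric(0))
  no <- W - L + 1L
  scores <- numeric(no)
  for (l in seq_len(L)) {
    scores <- scores + lo[cbind(code[l:(l + no - 1L)], l)]
  }
  scores
}

#' Scan a nucleotide sequence with a PWM
#'
#' Scores every window on both strands with the pseudocount-smoothed
#' log2-odds of the PWM against its background; `N` bases contribute 0.
#' A hit requires a score of at least `threshold_frac` times the maximum
#' attainable score.
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @param pwm A [new_pwm()] object.
#' @param threshold_frac Fraction of the maximum score required for a hit
#'   (default 0.8), in `(0, 1]`.
#' @return data.frame of hits: `motif`, `start` (0-based offset on the
#'   forward sequence), `strand`, `score` (bits).
#' @export
scan_pwm <- function(seq, pwm, threshold_frac = 0.8) {
  stopifnot(inherits(pwm, "pwm"),
            threshold_frac > 0, threshold_frac <= 1)
  empty <- data.frame(motif = character(), start = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nchar(seq) == 0L) return(empty)
  code <- .encode_seq(seq)
  L <- pwm$length
  W <- length(code)
  if (W < L) return(empty)
  thr <- threshold_frac * pwm$max_score
  fwd <- .score_offsets(code, pwm$logodds)
  rev_ <- .score_offsets(.revcomp_code(code), pwm$logodds)
  hit_f <- which(fwd >= thr)
  hit_r <- which(rev_ >= thr)
  out <- rbind(
    if (length(hit_f)) data.frame(motif = pwm$name, start = hit_f - 1L,
                                  strand = "+", score = fwd[hit_f],
                                  stringsAsFactors = FALSE),
    if (length(hit_r)) data.frame(motif = pwm$name,
                                  start = W - (hit_r - 1L) - L,
                                  strand = "-", score = rev_[hit_r],
                                  stringsAsFactors = FALSE))
  if (is.null(out)) empty else out[order(out$start, out$strand), , drop = FALSE]
}

#' Extract windows around CpG positions from a genome
#'
#' @param genome Named list of chromosome sequences (character strings).
#' @param chrom,pos Parallel vectors (1-based positions).
#' @param halfwidth Window half-width in bp (default 25; total 51 bp).
#' @return Character vector of window sequences, truncated at chromosome
#'   bounds (`attr(, "n_truncated")` reports how many).
#' @export
genome_windows <- function(genome, chrom, pos, halfwidth = 25L) {
  out <- character(length(pos))
  n_trunc <- 0L
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    s <- genome[[ch]]
    if (is.null(s)) stop("no sequence for chromosome ", ch)
    len <- nchar(s)
    from <- pmax(1L, pos[qi] - halfwidth)
    to <- pmin(len, pos[qi] + halfwidth)
    n_trunc <- n_trunc + sum(from != pos[qi] - halfwidth | to != pos[qi] + halfwidth)
    out[qi] <- substring(s, from, to)
  }
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Per-motif enrichment of PWM hits around target CpGs
#'
#' Scans a window around each target CpG and around a seeded random sample
#' of background CpGs; per motif builds the 2x2 table {target, background}
#' x {window has a hit, none} and ranks motifs by Fisher p (then by
#' descending odds ratio).
#'
#' @param target_ids,background_ids Character probe ids.
#' @param cpgs CpG map (`probe_id`, `chrom`, `pos`).
#' @param genome Named list of chromosome sequences.
#' @param pwms list of [new_pwm()] objects.
#' @param window_halfwidth Half-width in bp (default 25).
#' @param background_n Background sample size (default 50000, capped at the
#'   available background; sampled without replacement using the current
#'   RNG state).
#' @param threshold_frac Hit threshold passed to [scan_pwm()].
#' @return data.frame per motif: `motif`, counts, `or`, `log2_or`, `p`,
#'   `p_capped`, `q`, `rank`, `flag` (`"uninformative"` when the motif hits
#'   nothing anywhere).
#' @export
motif_enrichment <- function(target_ids, background_ids, cpgs, genome, pwms,
                             window_halfwidth = 25L, background_n = 50000L,
                             threshold_frac = 0.8) {
  bg <- background_ids
  if (length(bg) > background_n) bg <- sample(bg, background_n)
  sub_t <- cpgs[match(target_ids, cpgs$probe_id), , drop = FALSE]
  sub_b <- cpgs[match(bg, cpgs$probe_id), , drop = FALSE]
  win_t <- genome_windows(genome, sub_t$chrom, sub_t$pos, window_halfwidth)
  win_b <- genome_windows(genome, sub_b$chrom, sub_b$pos, window_halfwidth)
  code_t <- lapply(win_t, .encode_seq)
  code_b <- lapply(win_b, .encode_seq)
  has_hit <- function(code, pw, thr) {
    any(.score_offsets(code, pw$logodds) >= thr) ||
      any(.score_offsets(.revcomp_code(code), pw$logodds) >= thr)
  }
  rows <- lapply(pwms, function(pw) {
    thr <- threshold_frac * pw$max_score
    ht <- vapply(code_t, has_hit, logical(1L), pw = pw, thr = thr,
                 USE.NAMES = FALSE)
    hb <- vapply(code_b, has_hit, logical(1L), pw = pw, thr = thr,
                 USE.NAMES = FALSE)
    fr <- fisher_2x2(sum(ht), sum(!ht), sum(hb), sum(!hb))
    if (sum(ht) + sum(hb) == 0L) fr$flag <- "uninformative"
    data.frame(motif = pw$name, as.data.frame(fr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  ord <- order(out$p, -out$or)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
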