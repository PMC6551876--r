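#' Fisher's exact test on a 2x2 table
#'
#' Odds ratio is the sample OR `(a*d)/(b*c)` (`Inf` when `b*c == 0` and
#' `a*d > 0`; `NaN` when both products vanish, flagged). The two-sided
#' p-value follows the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables (same margins) no more likely
#' than the observed one, with the customary `1 + 1e-7` relative slack.
#' `p_capped` floors the p-value at `2.2e-16`, the smallest value that is
#' represented accurately.
#'
#' @param a,b,c,d Non-negative integer counts: rows target/background,
#'   columns feature/no-feature.
#' @param p_floor Cap floor for `p_capped` (default `2.2e-16`).
#' @return list with `a,b,c,d`, `or`, `log2_or`, `p`, `p_capped`, `flag`
#'   (`"ok"`, `"or-infinite"`, `"or-zero"` or `"or-undefined"`).
#' @export
fisher_2x2 <- function(a, b, c, d, p_floor = 2.2e-16) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("fisher_2x2 requires non-negative integer counts")
  }
  N <- a + b + c + d
  if (N == 0) stop("fisher_2x2 requires a positive total count")
  m <- a + c  # feature-positive total
  n <- b + d
  kk <- a + b # target total
  lo <- max(0, kk - n)
  hi <- min(kk, m)
  supp <- lo:hi
  dens <- stats::dhyper(supp, m, n, kk)
  obs <- stats::dhyper(a, m, n, kk)
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  num <- a * d
  den <- b * c
  if (den > 0) {
    or <- num / den
    flag <- "ok"
    if (or == 0) flag <- "or-zero"
  } else if (num > 0) {
    or <- Inf
    flag <- "or-infinite"
  } else {
    or <- NaN
    flag <- "or-undefined"
  }
  list(a = a, b = b, c = c, d = d, or = or, log2_or = log2(or),
       p = p, p_capped = max(p, p_floor), flag = flag)
}

#' Haldane-Anscombe smoothed odds ratio
#'
#' Adds 0.5 to every cell; intended for plotting log odds ratios when a cell
#' is empty, never for the reported OR.
#'
#' @inheritParams fisher_2x2
#' @return Smoothed odds ratio.
#' @export
or_haldane <- function(a, b, c, d) {
  ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
}

#' Stratified feature enrichment of a target CpG set
#'
#' Builds one 2x2 table per stratum: `a` targets with the feature, `b`
#' targets without, `c`/`d` likewise in the background. With `strata`
#' given (e.g. chromatin-state labels), the feature for stratum `s` is
#' "CpG carries label s"; with a logical `feature`, a single binary table
#' is built. Background defaults to all measured non-target CpGs (the
#' genome-wide comparison at measured positions).
#'
#' @param target_ids Character vector of target CpG ids (e.g. gain-DMCs).
#' @param background_ids Background CpG ids (disjoint from targets by
#'   default upstream).
#' @param feature Named logical vector per CpG (binary feature), or `NULL`
#'   when `strata` is used.
#' @param strata Named character vector per CpG of stratum labels, or
#'   `NULL`.
#' @param p_floor Cap floor.
#' @return data.frame, one row per stratum (or one row `feature`), with
#'   counts, `or`, `log2_or`, `p`, `p_capped`, `q` (BH across strata),
#'   `flag`.
#' @export
feature_enrichment <- function(target_ids, background_ids, feature = NULL,
                               strata = NULL, p_floor = 2.2e-16) {
  if (is.null(feature) == is.null(strata)) {
    stop("provide exactly one of 'feature' or 'strata'")
  }
  if (!is.null(strata)) {
    labs <- sort(unique(stats::na.omit(strata[c(target_ids, background_ids)])))
    labs <- setdiff(labs, "no-call")
    rows <- lapply(labs, function(s) {
      ft <- strata[target_ids] == s & !is.na(strata[target_ids])
      fb <- strata[background_ids] == s & !is.na(strata[background_ids])
      fr <- fisher_2x2(sum(ft), sum(!ft), sum(fb), sum(!fb), p_floor)
      data.frame(stratum = s, as.data.frame(fr), stringsAsFactors = FALSE)
    })
  } else {
    ft <- feature[target_ids]
    fb <- feature[background_ids]
    fr <- fisher_2x2(sum(ft, na.rm = TRUE), sum(!ft, na.rm = TRUE),
                     sum(fb, na.rm = TRUE), sum(!fb, na.rm = TRUE), p_floor)
    rows <- list(data.frame(stratum = "feature", as.data.frame(fr),
                            stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Gain-over-loss enrichment across chromatin-state transitions
#'
#' For each monocyte-to-macrophage state transition `(s, t)`, tests whether
#' gain-DMCs occupy that transition more often than loss-DMCs: 2x2 of
#' {gain, loss} x {in transition, not}. `OR > 1` means gain-enriched; the
#' grid is reported in log2 as it is usually drawn. CpGs with a no-call in
#' either cell type are excluded and counted.
#'
#' @param gain_ids,loss_ids DMC probe ids by direction.
#' @param state_mono,state_mac Named per-CpG consensus state labels
#'   (`"no-call"` allowed).
#' @param states State alphabet defining the grid (default: states observed).
#' @return data.frame with one row per observed transition: `state_mono`,
#'   `state_mac`, counts, `or`, `log2_or`, `p`, `p_capped`, `q`, `flag`;
#'   excluded no-call counts in `attr(, "n_nocall")`.
#' @export
transition_matrix <- function(gain_ids, loss_ids, state_mono, state_mac,
                              states = NULL) {
  ids <- c(gain_ids, loss_ids)
  sm <- state_mono[ids]
  sc <- state_mac[ids]
  ok <- !is.na(sm) & !is.na(sc) & sm != "no-call" & sc != "no-call"
  n_nocall <- sum(!ok)
  is_gain <- c(rep(TRUE, length(gain_ids)), rep(FALSE, length(loss_ids)))[ok]
  sm <- sm[ok]
  sc <- sc[ok]
  if (is.null(states)) states <- sort(unique(c(sm, sc)))
  trans <- expand.grid(state_mono = states, state_mac = states,
                       stringsAsFactors = FALSE)
  key <- paste(sm, sc, sep = "->")
  rows <- lapply(seq_len(nrow(trans)), function(i) {
    tk <- paste(trans$state_mono[i], trans$state_mac[i], sep = "->")
    int <- key == tk
    if (!any(int)) return(NULL)  # empty transition cell: not reported
    fr <- fisher_2x2(sum(is_gain & int), sum(is_gain & !int),
                     sum(!is_gain & int), sum(!is_gain & !int))
    data.frame(state_mono = trans$state_mono[i],
               state_mac = trans$state_mac[i],
               as.data.frame(fr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no transition has any DMC with state calls")
  out$q <- bh_fdr(out$p)
  attr(out, "n_nocall") <- n_nocall
  rownames(out) <- NULL
  out
}

#' TF binding gain at motif-overlapping DMCs
#'
#' Among CpGs whose motif window contains the given motif, tests whether
#' gain-DMCs acquire a ChIP peak during differentiation (peak in macrophage,
#' none in monocyte at the CpG position) more often than background CpGs at
#' the same motif. Also reports the mean array delta beta of the tested
#' gain-DMCs.
#'
#' @param gain_ids Gain-DMC probe ids overlapping the motif.
#' @param background_ids Background CpG ids overlapping the motif.
#' @param cpgs CpG map covering all ids.
#' @param chip_mono,chip_mac ChIP peak interval tracks for the TF.
#' @param delta_beta Named per-CpG array delta beta (used for the mean over
#'   `gain_ids`).
#' @param motif Motif name (for error messages / output label).
#' @return One-row data.frame: `motif`, counts, `or`, `log2_or`, `p`,
#'   `p_capped`, `flag`, `mean_delta_beta`.
#' @export
tf_binding_gain <- function(gain_ids, background_ids, cpgs, chip_mono,
                            chip_mac, delta_beta, motif = "motif") {
  if (length(gain_ids) == 0L && length(background_ids) == 0L) {
    stop("no motif-overlapping CpGs for motif '", motif, "'")
  }
  ids <- c(gain_ids, background_ids)
  sub <- cpgs[match(ids, cpgs$probe_id), , drop = FALSE]
  in_mono <- point_in_track(chip_mono, sub$chrom, sub$pos)
  in_mac <- point_in_track(chip_mac, sub$chrom, sub$pos)
  bgain <- in_mac & !in_mono
  is_t <- seq_along(ids) <= length(gain_ids)
  fr <- fisher_2x2(sum(bgain & is_t), sum(!bgain & is_t),
                   sum(bgain & !is_t), sum(!bgain & !is_t))
  if (sum(bgain) == 0L) fr$flag <- "no-binding-gain"
  data.frame(motif = motif, as.data.frame(fr),
             mean_delta_beta = mean(delta_beta[gain_ids]),
             stringsAsFactors = FALSE)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided test of symmetry about zero. Zero differences are dropped; if
#' none remain, `p = 1`. For `n <= exact_max` without ties in the absolute
#' differences the exact signed-rank distribution is used (doubled smaller
#' tail, equivalent to enumerating all sign assignments); otherwise a normal
#' approximation with continuity and tie correction.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return list with `v` (signed-rank statistic), `n` (non-zero pairs),
#'   `p`, `method` (`"exact"`/`"normal"`/`"all-zero"`), `median_shift`.
#' @export
signed_rank_test <- function(d, exact_max = 25L) {
  d <- d[is.finite(d)]
  med <- stats::median(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(v = NA_real_, n = 0L, p = 1, method = "all-zero",
                median_shift = med))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= exact_max && !ties) {
    p <- min(1, 2 * min(stats::psignrank(v, n),
                        stats::psignrank(v - 1, n, lower.tail = FALSE)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(v = v, n = n, p = p, method = method, median_shift = med)
}

#' Expression shift of genes nearest to DMCs
#'
#' Tests, per DMC direction, whether the nearest genes change expression
#' between monocytes and macrophages: paired logTPM differences
#' (macrophage - monocyte) across the unique nearest genes, Wilcoxon
#' signed-rank.
#'
#' @param gene_sets Named list of character vectors of gene names, e.g.
#'   `list(gain = ..., loss = ...)`.
#' @param expression Expression table with columns `gene`, `monocyte`,
#'   `macrophage` (logTPM).
#' @param min_genes Minimum genes with expression in both cell types
#'   (default 5).
#' @return data.frame with one row per set: `set`, `n_genes`, `v`, `p`,
#'   `median_shift`, `direction` (`up`/`down`/`none`), `method`.
#' @export
expression_shift <- function(gene_sets, expression, min_genes = 5L) {
  rows <- lapply(names(gene_sets), function(nm) {
    genes <- unique(gene_sets[[nm]])
    e <- expression[match(genes, expression$gene), , drop = FALSE]
    d <- e$macrophage - e$monocyte
    d <- d[is.finite(d)]
    if (length(d) < min_genes) {
      stop("expression_shift: set '", nm, "' has fewer than ", min_genes,
           " genes with expression in both cell types")
    }
    sr <- signed_rank_test(d)
    data.frame(set = nm, n_genes = sr$n, v = sr$v, p = sr$p,
               median_shift = sr$median_shift,
               direction = if (sr$median_shift > 0) "up"
                           else if (sr$median_shift < 0) "down" else "none",
               method = sr$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
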