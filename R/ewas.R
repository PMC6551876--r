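#' Default cell states of the study design
#'
#' Monocyte, naive macrophage, and four activated macrophage subtypes
#' (LPS/IFNg, IL-4, oxLDL, acLDL). The order is also the fixed tie-break
#' order for cell-type attribution.
#'
#' @return Character vector of six state names.
#' @export
default_states <- function() {
  c("monocyte", "macrophage", "mac_lps_ifng", "mac_il4",
    "mac_oxldl", "mac_acldl")
}

#' Balanced within-donor two-way ANOVA for one CpG
#'
#' Fits the paired cell-state comparison on a complete donor-by-state table
#' of beta values. For balanced complete data this is the exact form of the
#' donor random-intercept mixed model: the F test of the cell-state effect
#' and its Satterthwaite denominator degrees of freedom coincide with the
#' REML route whenever the donor variance estimate is interior.
#'
#' Decomposition: `SS_state = n * sum_c (m_c - m)^2`, `ms = SS_state/(k-1)`,
#' `F = ms / MS_res` with df `(k-1, (k-1)(n-1))`, and per-state partial
#' t-statistics `t_c = (m_c - m) / sqrt(MS_res * (k-1) / (n*k))`.
#'
#' @param y Numeric matrix, donors x states, no missing values.
#' @return list with `ms` (cell-state mean squares, the effect-size
#'   criterion), `f`, `p`, `partial_t` (named per state), `state_means`,
#'   `grand_mean`, `ms_res`, `df1`, `df2`, `n_donors`, `degenerate`
#'   (TRUE when the residual mean squares vanish while the state effect
#'   does not; then `f = Inf`, `p = 0`).
#' @export
fit_paired_anova <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y)
  k <- ncol(y)
  if (anyNA(y)) stop("fit_paired_anova requires complete data; drop incomplete donors first")
  if (n < 3L) stop("fit_paired_anova requires >= 3 complete donors")
  if (k < 2L) stop("fit_paired_anova requires >= 2 cell states")
  gm <- mean(y)
  sm <- colMeans(y)
  dm <- rowMeans(y)
  ss_state <- n * sum((sm - gm)^2)
  ss_donor <- k * sum((dm - gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_res <- max(ss_total - ss_state - ss_donor, 0)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms <- ss_state / df1
  ms_res <- ss_res / df2
  # exact-zero residual detection robust to cancellation noise
  tiny <- .Machine$double.eps * 100 * max(ss_total, .Machine$double.xmin)
  degenerate <- FALSE
  if (ss_res <= tiny) {
    if (ss_state <= tiny) {
      f <- 0
      p <- 1
      t <- rep(0, k)
    } else {
      f <- Inf
      p <- 0
      t <- ifelse(sm - gm == 0, 0, sign(sm - gm) * Inf)
      degenerate <- TRUE
    }
  } else {
    f <- ms / ms_res
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    t <- (sm - gm) / sqrt(ms_res * df1 / (n * k))
  }
  names(t) <- colnames(y)
  names(sm) <- colnames(y)
  list(ms = ms, f = f, p = p, partial_t = t, state_means = sm,
       grand_mean = gm, ms_res = ms_res, df1 = df1, df2 = df2,
       n_donors = n, degenerate = degenerate)
}

#' Paired ANOVA scan over a beta matrix
#'
#' Runs [fit_paired_anova()] per CpG on the complete-case donor set. A CpG
#' is tested only on donors with beta values for all cell states; CpGs with
#' fewer than `min_donors` complete donors are skipped and reported in the
#' `skipped` attribute. Computation is vectorized over CpGs sharing the same
#' complete-donor pattern.
#'
#' @param beta Probes x samples numeric matrix in `[0, 1]` (NA allowed).
#' @param samples Sample sheet data.frame (`sample_id`, `donor`, `cell_type`).
#' @param states Cell states to test (default [default_states()]); every
#'   donor/state combination must map to at most one sample.
#' @param min_donors Minimum complete donors per CpG (default 3).
#' @return data.frame with one row per tested CpG: `probe_id`, `n_donors`,
#'   `ms`, `f`, `p`, `q` (BH-adjusted), one `t_<state>` and `mean_<state>`
#'   column per state, `degenerate`. Skipped CpGs are recorded in
#'   `attr(, "skipped")` (probe_id + reason).
#' @export
ewas_scan <- function(beta, samples, states = default_states(),
                      min_donors = 3L) {
  stopifnot(is.matrix(beta))
  samples <- samples[samples$cell_type %in% states, , drop = FALSE]
  if (anyDuplicated(paste(samples$donor, samples$cell_type))) {
    stop("each donor may contribute at most one sample per cell state")
  }
  donors <- sort(unique(samples$donor))
  k <- length(states)
  # donor x state grid of column indices into beta
  idx <- matrix(NA_integer_, length(donors), k,
                dimnames = list(donors, states))
  m <- match(samples$sample_id, colnames(beta))
  idx[cbind(match(samples$donor, donors),
            match(samples$cell_type, states))] <- m
  if (anyNA(idx)) {
    miss <- which(is.na(idx), arr.ind = TRUE)
    stop("missing sample for donor/state: ",
         paste(donors[miss[, 1L]], states[miss[, 2L]], sep = "/",
               collapse = ", "))
  }
  n_all <- length(donors)
  # per CpG, which donors are complete (no NA across all k states)
  ok <- matrix(TRUE, nrow(beta), n_all)
  for (d in seq_len(n_all)) {
    ok[, d] <- rowSums(is.na(beta[, idx[d, ], drop = FALSE])) == 0L
  }
  ndon <- rowSums(ok)
  skip <- ndon < min_donors
  skipped <- data.frame(probe_id = rownames(beta)[skip],
                        reason = sprintf("only %d complete donors", ndon[skip]),
                        stringsAsFactors = FALSE)
  keep <- which(!skip)
  res <- vector("list", 0L)
  if (length(keep) > 0L) {
    pat <- apply(ok[keep, , drop = FALSE], 1L, function(z) {
      paste(which(z), collapse = ",")
    })
    res <- lapply(split(keep, pat), function(rows) {
      dset <- ok[rows[1L], ]
      n <- sum(dset)
      cols <- as.vector(idx[dset, , drop = FALSE])   # column-major: by state
      Y <- beta[rows, cols, drop = FALSE]
      nk <- n * k
      gm <- rowMeans(Y)
      # state means: average consecutive blocks of n donors
      sm <- matrix(0, length(rows), k)
      for (c in seq_len(k)) {
        sm[, c] <- rowMeans(Y[, ((c - 1L) * n + 1L):(c * n), drop = FALSE])
      }
      dmn <- matrix(0, length(rows), n)
      for (d in seq_len(n)) {
        dmn[, d] <- rowMeans(Y[, seq(d, nk, by = n), drop = FALSE])
      }
      ss_state <- n * rowSums((sm - gm)^2)
      ss_donor <- k * rowSums((dmn - gm)^2)
      ss_total <- rowSums((Y - gm)^2)
      ss_res <- pmax(ss_total - ss_state - ss_donor, 0)
      df1 <- k - 1L
      df2 <- (k - 1L) * (n - 1L)
      ms <- ss_state / df1
      ms_res <- ss_res / df2
      tiny <- .Machine$double.eps * 100 * pmax(ss_total, .Machine$double.xmin)
      degen <- ss_res <= tiny & ss_state > tiny
      null0 <- ss_res <= tiny & ss_state <= tiny
      f <- ms / ms_res
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
      se <- sqrt(ms_res * df1 / nk)
      tt <- (sm - gm) / se
      f[degen] <- Inf
      p[degen] <- 0
      tt[degen, ] <- sign(sm - gm)[degen, , drop = FALSE] * Inf
      tt[degen, ][sm[degen, , drop = FALSE] == gm[degen]] <- 0
      f[null0] <- 0
      p[null0] <- 1
      tt[null0, ] <- 0
      out <- data.frame(probe_id = rownames(beta)[rows], n_donors = n,
                        ms = ms, f = f, p = p, stringsAsFactors = FALSE)
      colnames(tt) <- paste0("t_", states)
      colnames(sm) <- paste0("mean_", states)
      out <- cbind(out, tt, sm)
      out$degenerate <- degen
      out
    })
  }
  out <- if (length(res)) do.call(rbind, res) else {
    stop("no CpG has >= ", min_donors, " complete donors")
  }
  out <- out[match(rownames(beta)[keep], out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  attr(out, "skipped") <- skipped
  attr(out, "states") <- states
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a p-value vector; thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @return Vector of BH-adjusted q-values, `q[i] >= p[i]`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify DMCs: thresholding, cell-type attribution, direction
#'
#' A CpG is a DMC iff `q < q_max` and `ms > ms_min`. The contributing phase
#' is attributed via the largest absolute partial t — computed on the
#' state-mean deviations, to which the partial t's are proportional within
#' a CpG (this stays defined for degenerate zero-residual CpGs): monocyte gives
#' `differentiation`, the naive macrophage gives `macrophage-specific`, an
#' activated subtype gives `activation:<subtype>`; when two or more states
#' reach `multi_frac` of the maximum the CpG is labelled `multi`. Ties in the
#' argmax are resolved by the fixed state order and counted in
#' `attr(, "n_ties")`.
#'
#' Delta beta (whose sign defines gain vs loss): differentiation and multi
#' use mean(macrophage-derived states) - mean(monocyte); macrophage-specific
#' uses macrophage - monocyte; activation uses subtype - macrophage.
#'
#' @param scan Result of [ewas_scan()].
#' @param q_max FDR threshold (default 0.05).
#' @param ms_min Mean-squares effect-size threshold (default 0.0025).
#' @param multi_frac Fraction of the top |partial t| at which a second state
#'   triggers the `multi` phase (default 0.9).
#' @param states Cell states in fixed order; first must be the monocyte,
#'   second the naive macrophage.
#' @return `scan` with added columns `is_dmc`, `top_state`, `phase`,
#'   `delta_beta`, `direction` (`gain`/`loss`), `switch_flag` (mean beta
#'   crosses 0.5 between monocyte and macrophage).
#' @export
call_dmcs <- function(scan, q_max = 0.05, ms_min = 0.0025, multi_frac = 0.9,
                      states = attr(scan, "states")) {
  if (is.null(states)) states <- default_states()
  k <- length(states)
  mmat <- as.matrix(scan[, paste0("mean_", states), drop = FALSE])
  # within a row |partial t| is proportional to the state-mean deviation
  # (common SE), so attribution works on deviations; this stays defined for
  # degenerate rows where every partial t is infinite
  tmat <- abs(mmat - rowMeans(mmat))
  top <- apply(tmat, 1L, function(z) which(z == max(z))[1L])  # fixed-order tie-break
  n_ties <- sum(apply(tmat, 1L, function(z) sum(z == max(z)) > 1L & max(z) > 0))
  tmax <- tmat[cbind(seq_len(nrow(tmat)), top)]
  n_top <- rowSums(tmat >= multi_frac * tmax & tmax > 0)
  phase <- character(nrow(scan))
  phase[top == 1L] <- "differentiation"
  phase[top == 2L] <- "macrophage-specific"
  act <- top > 2L
  phase[act] <- paste0("activation:", states[top[act]])
  phase[n_top >= 2L] <- "multi"
  mac_derived <- rowMeans(mmat[, 2:k, drop = FALSE])
  delta <- mac_derived - mmat[, 1L]
  delta[phase == "macrophage-specific"] <- (mmat[, 2L] - mmat[, 1L])[phase == "macrophage-specific"]
  delta[act & phase != "multi"] <-
    (mmat[cbind(seq_len(nrow(mmat)), top)] - mmat[, 2L])[act & phase != "multi"]
  scan$is_dmc <- !is.na(scan$q) & scan$q < q_max & scan$ms > ms_min
  scan$top_state <- states[top]
  scan$phase <- phase
  scan$delta_beta <- delta
  scan$direction <- ifelse(delta > 0, "gain", "loss")
  scan$switch_flag <- (mmat[, 1L] - 0.5) * (mmat[, 2L] - 0.5) < 0
  attr(scan, "n_ties") <- n_ties
  attr(scan, "states") <- states
  scan
}

#' Pearson concordance of two effect-size vectors
#'
#' Used to compare array delta beta against an external estimate (a public
#' 450k set, or WGBS deltas at the same CpGs).
#'
#' @param delta_a,delta_b Paired numeric vectors.
#' @return list with `r` (Pearson correlation over pairwise-complete
#'   entries), `n` (pairs used) and `flag` (`"ok"`, or `"zero-variance"`
#'   with `r = NA`).
#' @export
effect_concordance <- function(delta_a, delta_b) {
  stopifnot(length(delta_a) == length(delta_b))
  ok <- is.finite(delta_a) & is.finite(delta_b)
  n <- sum(ok)
  if (n < 3L) stop("effect_concordance requires >= 3 finite pairs")
  a <- delta_a[ok]
  b <- delta_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, n = n, flag = "zero-variance"))
  }
  list(r = stats::cor(a, b), n = n, flag = "ok")
}
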