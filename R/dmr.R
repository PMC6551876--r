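#' Pair monocyte and macrophage WGBS tracks
#'
#' Joins the two per-cell-type CpG tracks on exact position. "Sufficient
#' coverage" means present in both tracks with donor count at least
#' `min_donors` in each.
#'
#' @param mono,mac WGBS tracks as from [read_wgbs_track()].
#' @param min_donors Minimum donors per cell type (default 3).
#' @return data.frame sorted by `chrom`, `pos`: `beta_mono`, `beta_mac`,
#'   `delta` (macrophage - monocyte), `covered` (logical). CpGs present in
#'   only one track are kept with `covered = FALSE` and `NA` for the
#'   missing side.
#' @export
build_wgbs_pair <- function(mono, mac, min_donors = 3L) {
  key_mono <- paste(mono$chrom, mono$pos)
  key_mac <- paste(mac$chrom, mac$pos)
  all_key <- union(key_mono, key_mac)
  im <- match(all_key, key_mono)
  ic <- match(all_key, key_mac)
  chrom <- ifelse(is.na(im), mac$chrom[ic], mono$chrom[im])
  pos <- ifelse(is.na(im), mac$pos[ic], mono$pos[im])
  out <- data.frame(
    chrom = chrom, pos = pos,
    beta_mono = mono$beta[im], beta_mac = mac$beta[ic],
    n_mono = ifelse(is.na(im), 0L, mono$n_donors[im]),
    n_mac = ifelse(is.na(ic), 0L, mac$n_donors[ic]),
    stringsAsFactors = FALSE)
  out$delta <- out$beta_mac - out$beta_mono
  out$covered <- !is.na(im) & !is.na(ic) &
    out$n_mono >= min_donors & out$n_mac >= min_donors
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map array DMCs onto the WGBS CpG pair
#'
#' Requires exact positional identity between the array CpG and a
#' sufficiently covered WGBS CpG (`max_offset = 0` by default).
#'
#' @param cpgs data.frame of array CpGs (`probe_id`, `chrom`, `pos`).
#' @param pair Output of [build_wgbs_pair()].
#' @param max_offset Maximum bp offset tolerated between array and WGBS
#'   position (default 0).
#' @return data.frame `probe_id`, `wgbs_index` (row of `pair`, `NA` if
#'   uncovered), `wgbs_delta`, `reason` (`"ok"`, `"no-wgbs-cpg"`,
#'   `"insufficient-donors"`).
#' @export
map_dmc_to_wgbs <- function(cpgs, pair, max_offset = 0L) {
  idx <- rep(NA_integer_, nrow(cpgs))
  reason <- rep("no-wgbs-cpg", nrow(cpgs))
  covered_rows <- which(pair$covered)
  for (ch in unique(cpgs$chrom)) {
    qi <- which(cpgs$chrom == ch)
    pi_all <- which(pair$chrom == ch)
    if (length(pi_all) == 0L) next
    if (max_offset == 0L) {
      m <- match(cpgs$pos[qi], pair$pos[pi_all])
      hit <- !is.na(m)
      idx[qi[hit]] <- pi_all[m[hit]]
    } else {
      pp <- pair$pos[pi_all]
      for (i in qi) {
        d <- abs(pp - cpgs$pos[i])
        j <- which.min(d)
        if (length(j) && d[j] <= max_offset) idx[i] <- pi_all[j]
      }
    }
  }
  found <- !is.na(idx)
  reason[found & pair$covered[idx]] <- "ok"
  reason[found & !pair$covered[idx]] <- "insufficient-donors"
  idx[reason != "ok"] <- NA_integer_
  data.frame(probe_id = cpgs$probe_id, wgbs_index = idx,
             wgbs_delta = ifelse(is.na(idx), NA_real_, pair$delta[idx]),
             reason = reason, stringsAsFactors = FALSE)
}

#' Seed-and-extend DMR demarcation around one WGBS CpG
#'
#' Starting from the seed, extends over consecutive covered WGBS CpGs in
#' both directions while each next CpG (i) has a methylation difference of
#' at least `min_diff` with the seed's sign and (ii) lies within `max_gap`
#' bp of the previous member. Extension stops at the first failing CpG per
#' direction (strict consecutive rule); the result is the unique maximal
#' run containing the seed. A single-CpG DMR has `length_bp = 1`.
#'
#' @param pair Output of [build_wgbs_pair()].
#' @param seed_index Row index of the seed CpG in `pair`.
#' @param min_diff Minimum absolute same-direction difference (default
#'   0.05, i.e. 5 percentage points).
#' @param max_gap Maximum bp between consecutive member CpGs (default 1000;
#'   set to `1e6` to reproduce the literal megabase rule).
#' @return list: `concordant` (FALSE when the seed itself fails
#'   `min_diff`, all other fields NA), `chrom`, `start`, `end` (bp of
#'   first/last member), `n_cpg`, `length_bp`, `mean_delta`, `members`
#'   (positions).
#' @export
extend_dmr <- function(pair, seed_index, min_diff = 0.05, max_gap = 1000L) {
  stopifnot(seed_index >= 1L, seed_index <= nrow(pair))
  ds <- pair$delta[seed_index]
  if (is.na(ds) || abs(ds) < min_diff || !pair$covered[seed_index]) {
    return(list(concordant = FALSE, chrom = pair$chrom[seed_index],
                start = NA_integer_, end = NA_integer_, n_cpg = NA_integer_,
                length_bp = NA_integer_, mean_delta = NA_real_,
                members = integer()))
  }
  sgn <- sign(ds)
  ch <- pair$chrom[seed_index]
  # covered CpGs on the seed's chromosome, in position order
  rows <- which(pair$chrom == ch & pair$covered)
  at <- match(seed_index, rows)
  lo <- at
  while (lo > 1L) {
    nxt <- rows[lo - 1L]
    prv <- rows[lo]
    if (pair$pos[prv] - pair$pos[nxt] > max_gap) break
    if (is.na(pair$delta[nxt]) || pair$delta[nxt] * sgn < min_diff) break
    lo <- lo - 1L
  }
  hi <- at
  while (hi < length(rows)) {
    nxt <- rows[hi + 1L]
    prv <- rows[hi]
    if (pair$pos[nxt] - pair$pos[prv] > max_gap) break
    if (is.na(pair$delta[nxt]) || pair$delta[nxt] * sgn < min_diff) break
    hi <- hi + 1L
  }
  members <- rows[lo:hi]
  pos <- pair$pos[members]
  list(concordant = TRUE, chrom = ch,
       start = min(pos), end = max(pos),
       n_cpg = length(members),
       length_bp = max(pos) - min(pos) + 1L,
       mean_delta = mean(pair$delta[members]),
       members = pos)
}

#' Demarcate DMRs for a set of array DMCs
#'
#' Maps each DMC to the WGBS pair, checks direction concordance with the
#' array call, and runs [extend_dmr()] around concordant seeds.
#'
#' @param dmcs data.frame with `probe_id`, `chrom`, `pos`, `delta_beta`
#'   (array scale; sign defines the expected direction).
#' @param pair Output of [build_wgbs_pair()].
#' @param min_diff Concordance / extension threshold (default 0.05).
#' @param max_gap Extension gap limit in bp (default 1000).
#' @return data.frame with one row per DMC: mapping status, `wgbs_delta`,
#'   `concordant` (covered, same direction as array, `|delta| >= min_diff`),
#'   and for concordant seeds the DMR fields `dmr_start`, `dmr_end`,
#'   `dmr_n_cpg`, `dmr_length_bp`, `dmr_mean_delta`.
#' @export
call_dmrs <- function(dmcs, pair, min_diff = 0.05, max_gap = 1000L) {
  mp <- map_dmc_to_wgbs(dmcs, pair)
  n <- nrow(dmcs)
  out <- data.frame(probe_id = dmcs$probe_id,
                    covered = mp$reason == "ok",
                    reason = mp$reason,
                    wgbs_delta = mp$wgbs_delta,
                    concordant = FALSE,
                    dmr_start = NA_integer_, dmr_end = NA_integer_,
                    dmr_n_cpg = NA_integer_, dmr_length_bp = NA_integer_,
                    dmr_mean_delta = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(mp$wgbs_index[i])) next
    same_dir <- sign(mp$wgbs_delta[i]) == sign(dmcs$delta_beta[i])
    if (!isTRUE(same_dir) || abs(mp$wgbs_delta[i]) < min_diff) next
    r <- extend_dmr(pair, mp$wgbs_index[i], min_diff, max_gap)
    if (!r$concordant) next
    out$concordant[i] <- TRUE
    out$dmr_start[i] <- r$start
    out$dmr_end[i] <- r$end
    out$dmr_n_cpg[i] <- r$n_cpg
    out$dmr_length_bp[i] <- r$length_bp
    out$dmr_mean_delta[i] <- r$mean_delta
  }
  out
}

#' WGBS concordance enrichment of DMCs over non-DMCs
#'
#' Concordant means: mapped to a covered WGBS CpG whose difference has the
#' same direction as the array call and magnitude at least `min_diff`.
#' Reports the fold enrichment of the concordance rate in DMCs over
#' non-DMCs and a Fisher p on the underlying 2x2 (covered CpGs only).
#'
#' @param dmc_map data.frame for DMCs with `wgbs_delta`, `reason` and the
#'   array `delta_beta` (as from merging [map_dmc_to_wgbs()] output).
#' @param nondmc_map Same for non-DMC CpGs.
#' @param min_diff Threshold (default 0.05).
#' @return list: `n_dmc_covered`, `n_dmc_concordant`, `n_nondmc_covered`,
#'   `n_nondmc_concordant`, `fold` (rate ratio, `Inf` flagged), `p`,
#'   `p_capped`, `flag`.
#' @export
concordance_enrichment <- function(dmc_map, nondmc_map, min_diff = 0.05) {
  conc <- function(m) {
    cov <- m$reason == "ok"
    cc <- cov & abs(m$wgbs_delta) >= min_diff &
      sign(m$wgbs_delta) == sign(m$delta_beta)
    c(covered = sum(cov), concordant = sum(cc, na.rm = TRUE))
  }
  if (nrow(dmc_map) == 0L || nrow(nondmc_map) == 0L) {
    stop("concordance_enrichment requires non-empty DMC and non-DMC sets")
  }
  x <- conc(dmc_map)
  y <- conc(nondmc_map)
  rate_d <- x["concordant"] / x["covered"]
  rate_n <- y["concordant"] / y["covered"]
  fold <- unname(rate_d / rate_n)
  flag <- if (!is.finite(fold)) "fold-infinite" else "ok"
  fr <- fisher_2x2(x["concordant"], x["covered"] - x["concordant"],
                   y["concordant"], y["covered"] - y["concordant"])
  list(n_dmc_covered = unname(x["covered"]),
       n_dmc_concordant = unname(x["concordant"]),
       n_nondmc_covered = unname(y["covered"]),
       n_nondmc_concordant = unname(y["concordant"]),
       fold = fold, p = fr$p, p_capped = fr$p_capped, flag = flag)
}
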