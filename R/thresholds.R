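#' Default effect-size bins for the sensitivity analysis
#'
#' `>5%` keeps every concordant DMC (the primary analysis threshold),
#' `5-30%` keeps moderate effects (closed on both ends), `>30%` keeps only
#' large effects (strict).
#' @return Named list of `c(lo, hi)` bounds on `|delta|`, interpreted as
#'   `lo <= |delta|` and (when finite) `|delta| <= hi` for `5-30%`,
#'   `|delta| > lo` for the strict `>30%` bin.
#' @keywords internal
default_effect_bins <- function() {
  list(">5%" = c(0.05, Inf), "5-30%" = c(0.05, 0.30), ">30%" = c(0.30, Inf))
}

.in_effect_bin <- function(abs_delta, bin_name, bin) {
  if (bin_name == "5-30%") {
    abs_delta >= bin[1L] & abs_delta <= bin[2L]
  } else if (bin_name == ">30%") {
    abs_delta > bin[1L]
  } else {
    abs_delta >= bin[1L]
  }
}

#' Retention of DMCs under effect-size and DMR-size cutoffs
#'
#' Splits the WGBS-concordant DMC set by effect-size bins (WGBS delta at
#' the seed CpG) and DMR-size bins, separately for gain and loss, and
#' reports retained counts and lost fractions per bin and bin combination.
#' DMCs not covered in WGBS (or not direction-concordant) are excluded and
#' counted in the attributes `n_not_covered` / `n_not_concordant`.
#'
#' @param dmc_dmr data.frame with one row per DMC: `probe_id`, `direction`
#'   (`gain`/`loss`), `covered`, `concordant`, `wgbs_delta`, `dmr_n_cpg`
#'   (as from merging [call_dmrs()] output with the DMC table).
#' @param effect_bins Named list of effect bins (default
#'   [default_effect_bins()]).
#' @param dmr_bins Named list of DMR-size predicates as `c(lo, hi)` on
#'   `n_cpg`, closed; default `list("<=4" = c(1, 4), ">4" = c(5, Inf))`.
#' @return list: `report` (data.frame: `effect_bin`, `dmr_bin` (`"any"`
#'   included), `n_gain`, `n_loss`, `n_total`, `frac_lost_gain`,
#'   `frac_lost_loss`, `frac_lost_total`) and `retained` (named list of
#'   probe-id vectors per report row, key `"<effect>|<dmr>"`).
#' @export
apply_cutoffs <- function(dmc_dmr,
                          effect_bins = default_effect_bins(),
                          dmr_bins = list("<=4" = c(1, 4), ">4" = c(5, Inf))) {
  base <- dmc_dmr[dmc_dmr$covered & dmc_dmr$concordant, , drop = FALSE]
  n_gain0 <- sum(base$direction == "gain")
  n_loss0 <- sum(base$direction == "loss")
  n0 <- nrow(base)
  if (n0 == 0L) stop("no covered, concordant DMCs to threshold")
  abs_d <- abs(base$wgbs_delta)
  dmr_sets <- c(list(any = rep(TRUE, n0)),
                lapply(dmr_bins, function(b) {
                  base$dmr_n_cpg >= b[1L] & base$dmr_n_cpg <= b[2L]
                }))
  rows <- list()
  retained <- list()
  for (eb in names(effect_bins)) {
    in_e <- .in_effect_bin(abs_d, eb, effect_bins[[eb]])
    for (db in names(dmr_sets)) {
      keep <- in_e & dmr_sets[[db]]
      ng <- sum(keep & base$direction == "gain")
      nl <- sum(keep & base$direction == "loss")
      key <- paste(eb, db, sep = "|")
      retained[[key]] <- base$probe_id[keep]
      rows[[key]] <- data.frame(
        effect_bin = eb, dmr_bin = db,
        n_gain = ng, n_loss = nl, n_total = ng + nl,
        frac_lost_gain = if (n_gain0 > 0) 1 - ng / n_gain0 else NA_real_,
        frac_lost_loss = if (n_loss0 > 0) 1 - nl / n_loss0 else NA_real_,
        frac_lost_total = 1 - (ng + nl) / n0,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, retained = retained,
                 n_base = n0, n_base_gain = n_gain0, n_base_loss = n_loss0),
            n_not_covered = sum(!dmc_dmr$covered),
            n_not_concordant = sum(dmc_dmr$covered & !dmc_dmr$concordant))
}

#' Re-run enrichment analyses on retained DMC subsets
#'
#' Applies a caller-supplied enrichment closure to each retained set,
#' skipping sets below `min_size` (marked `"insufficient"`), so threshold
#' combinations can be compared side by side.
#'
#' @param retained Named list of probe-id vectors (from [apply_cutoffs()]).
#' @param enrich_fun Function taking a probe-id vector and returning an
#'   enrichment table.
#' @param min_size Minimum set size to re-run (default 20).
#' @return Named list: each element either the enrichment table or the
#'   string `"insufficient"`.
#' @export
rerun_enrichments <- function(retained, enrich_fun, min_size = 20L) {
  lapply(retained, function(ids) {
    if (length(ids) < min_size) "insufficient" else enrich_fun(ids)
  })
}
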