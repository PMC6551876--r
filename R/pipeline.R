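.load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed  # pipeline seed governs the generator
    return(simulate_all(sim))
  }
  p <- config$paths
  bundle <- list()
  bm <- read_beta_matrix(p$beta, p$samplesheet)
  bundle$beta <- bm$beta
  bundle$samples <- bm$samples
  bundle$cpg_map <- read_cpg_map(p$cpg_map)
  if ("dmr" %in% config$stages || "thresholds" %in% config$stages) {
    bundle$wgbs <- list(
      mono = read_wgbs_track(p$wgbs_mono, p$wgbs_mono_donors),
      mac = read_wgbs_track(p$wgbs_mac, p$wgbs_mac_donors))
  }
  ann <- list()
  if ("annotate" %in% config$stages) {
    ann$state_tracks <- list(monocyte = lapply(p$states_mono, read_bed),
                             macrophage = lapply(p$states_mac, read_bed))
    ann$dhs_tracks <- list(monocyte = lapply(p$dhs_mono, read_bed),
                           macrophage = lapply(p$dhs_mac, read_bed))
    ann$hic <- list(monocyte = read_bed(p$hic_mono),
                    macrophage = read_bed(p$hic_mac))
    ann$motif_sites <- read_bed(p$motif_sites)
    ann$genes <- read_gene_models(p$genes)
  }
  if (!is.null(p$expression)) ann$expression <- read_expression(p$expression)
  if ("motif" %in% config$stages) {
    ann$pwms <- read_pwms(p$pwms)
    ann$genome <- read_genome(p$genome)
  }
  if (!is.null(p$chip)) {
    ann$chip <- lapply(p$chip, function(tf) {
      list(monocyte = read_bed(tf[["monocyte"]]),
           macrophage = read_bed(tf[["macrophage"]]))
    })
  }
  bundle$annotation <- ann
  bundle
}

#' Run the full analysis pipeline
#'
#' Orchestrates every enabled stage on synthetic or file inputs:
#' paired EWAS and DMC calling, consensus annotation, enrichment analyses
#' (states, transitions, DNaseI change, Hi-C enhancers, TF binding gain,
#' expression shift), WGBS DMR demarcation and concordance, motif
#' enrichment, and threshold sensitivity. Deterministic given
#' `config$seed`. When `outdir` is given, result tables (TSV) and a JSON
#' run manifest are written.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if needed).
#' @return (Invisibly) a list with elements `dmc` (classified DMC table
#'   merged with annotation and DMR columns), `annotation`, `enrichment`
#'   (list of tables), `dmr` (table + concordance summary), `motif`
#'   (gain/loss rankings), `thresholds` (retention report + re-run
#'   tables), `truth` (synthetic mode only), `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  validate_config(config)
  set.seed(config$seed)
  bundle <- .load_inputs(config)
  res <- list()
  counts <- list()

  ## --- ewas -------------------------------------------------------------
  scan <- ewas_scan(bundle$beta, bundle$samples,
                    min_donors = config$min_donors)
  dmc <- call_dmcs(scan, q_max = config$q_max, ms_min = config$ms_min,
                   multi_frac = config$multi_frac)
  counts$n_tested <- nrow(dmc)
  counts$n_dmc <- sum(dmc$is_dmc)
  diff_like <- dmc$is_dmc & dmc$phase %in% c("differentiation", "multi",
                                             "macrophage-specific")
  gain_ids <- dmc$probe_id[diff_like & dmc$direction == "gain"]
  loss_ids <- dmc$probe_id[diff_like & dmc$direction == "loss"]
  nondmc_ids <- dmc$probe_id[!dmc$is_dmc]
  res$dmc <- dmc

  ann <- bundle$annotation
  if ("annotate" %in% config$stages) {
    anno <- annotate_cpgs(bundle$cpg_map, ann$state_tracks, ann$dhs_tracks,
                          ann$hic, ann$motif_sites, ann$genes,
                          state_min_votes = config$state_min_votes,
                          dhs_min_votes = config$dhs_min_votes,
                          window_halfwidth = config$motif_window_halfwidth)
    rownames(anno) <- anno$probe_id
    res$annotation <- anno
    counts$n_state_call_mono <- sum(anno$state_mono != "no-call")
  }

  if ("enrich" %in% config$stages) {
    stopifnot(!is.null(res$annotation))
    anno <- res$annotation
    st_mono <- stats::setNames(anno$state_mono, anno$probe_id)
    st_mac <- stats::setNames(anno$state_mac, anno$probe_id)
    dhs_change <- stats::setNames(anno$dhs_mono != anno$dhs_mac,
                                  anno$probe_id)
    enr <- list()
    enr$states_mono_gain <- feature_enrichment(gain_ids, nondmc_ids,
                                               strata = st_mono)
    enr$states_mono_loss <- feature_enrichment(loss_ids, nondmc_ids,
                                               strata = st_mono)
    enr$states_mac_gain <- feature_enrichment(gain_ids, nondmc_ids,
                                              strata = st_mac)
    enr$states_mac_loss <- feature_enrichment(loss_ids, nondmc_ids,
                                              strata = st_mac)
    enr$transitions <- transition_matrix(gain_ids, loss_ids, st_mono, st_mac)
    enr$dhs_change_gain <- feature_enrichment(gain_ids, nondmc_ids,
                                              feature = dhs_change)
    enr$dhs_change_loss <- feature_enrichment(loss_ids, nondmc_ids,
                                              feature = dhs_change)
    hic_mono <- stats::setNames(anno$enhancer_hic_mono, anno$probe_id)
    hic_mac <- stats::setNames(anno$enhancer_hic_mac, anno$probe_id)
    all_dmc <- c(gain_ids, loss_ids)
    enr$hic_mono <- feature_enrichment(all_dmc, nondmc_ids,
                                       feature = hic_mono)
    enr$hic_mac <- feature_enrichment(all_dmc, nondmc_ids,
                                      feature = hic_mac)
    if (!is.null(ann$chip)) {
      db <- stats::setNames(dmc$delta_beta, dmc$probe_id)
      motif_of <- strsplit(stats::setNames(anno$motif_hits, anno$probe_id),
                           ",", fixed = TRUE)
      enr$tf_binding_gain <- do.call(rbind, lapply(names(ann$chip),
        function(tf) {
          motif <- config$tf_motifs[[tf]]
          if (is.null(motif) || is.na(motif)) motif <- tf
          has_m <- vapply(motif_of, function(z) motif %in% z, TRUE)
          tf_binding_gain(gain_ids[has_m[gain_ids]],
                          nondmc_ids[has_m[nondmc_ids]],
                          bundle$cpg_map,
                          ann$chip[[tf]]$monocyte, ann$chip[[tf]]$macrophage,
                          db, motif = paste(tf, motif, sep = "@"))
        }))
    }
    if (!is.null(ann$expression)) {
      enr$expression_shift <- expression_shift(
        list(gain = anno[gain_ids, "nearest_gene"],
             loss = anno[loss_ids, "nearest_gene"]),
        ann$expression)
    }
    res$enrichment <- enr
  }

  if ("dmr" %in% config$stages) {
    pair <- build_wgbs_pair(bundle$wgbs$mono, bundle$wgbs$mac,
                            min_donors = config$wgbs_min_donors)
    dmc_rows <- dmc[diff_like, , drop = FALSE]
    dmc_pos <- bundle$cpg_map[match(dmc_rows$probe_id,
                                    bundle$cpg_map$probe_id), ]
    dmrs <- call_dmrs(
      data.frame(probe_id = dmc_rows$probe_id, chrom = dmc_pos$chrom,
                 pos = dmc_pos$pos, delta_beta = dmc_rows$delta_beta,
                 stringsAsFactors = FALSE),
      pair, min_diff = config$dmr_min_diff, max_gap = config$dmr_max_gap)
    nond_pos <- bundle$cpg_map[match(nondmc_ids, bundle$cpg_map$probe_id), ]
    nond_map <- map_dmc_to_wgbs(nond_pos, pair)
    nond_map$delta_beta <- dmc$delta_beta[match(nondmc_ids, dmc$probe_id)]
    dmc_map <- dmrs[, c("probe_id", "wgbs_delta", "reason")]
    dmc_map$delta_beta <- dmc_rows$delta_beta
    conc <- concordance_enrichment(dmc_map, nond_map,
                                   min_diff = config$dmr_min_diff)
    dmrs$direction <- dmc_rows$direction
    res$dmr <- list(table = dmrs, pair_n = nrow(pair), concordance = conc)
    counts$n_dmc_covered <- conc$n_dmc_covered
    counts$n_dmc_concordant <- conc$n_dmc_concordant
  }

  if ("motif" %in% config$stages) {
    res$motif <- list(
      gain = motif_enrichment(gain_ids, nondmc_ids, bundle$cpg_map,
                              ann$genome, ann$pwms,
                              window_halfwidth = config$motif_window_halfwidth,
                              background_n = config$motif_background_n,
                              threshold_frac = config$motif_threshold_frac),
      loss = motif_enrichment(loss_ids, nondmc_ids, bundle$cpg_map,
                              ann$genome, ann$pwms,
                              window_halfwidth = config$motif_window_halfwidth,
                              background_n = config$motif_background_n,
                              threshold_frac = config$motif_threshold_frac))
  }

  if ("thresholds" %in% config$stages) {
    stopifnot(!is.null(res$dmr), !is.null(res$annotation))
    dd <- res$dmr$table
    dd$direction <- dmc$direction[match(dd$probe_id, dmc$probe_id)]
    cuts <- apply_cutoffs(data.frame(
      probe_id = dd$probe_id, direction = dd$direction,
      covered = dd$covered, concordant = dd$concordant,
      wgbs_delta = dd$wgbs_delta, dmr_n_cpg = dd$dmr_n_cpg,
      stringsAsFactors = FALSE))
    anno <- res$annotation
    st_mono <- stats::setNames(anno$state_mono, anno$probe_id)
    dhs_change <- stats::setNames(anno$dhs_mono != anno$dhs_mac,
                                  anno$probe_id)
    top_motifs <- if (!is.null(res$motif)) {
      unique(c(head(res$motif$gain$motif, 5L),
               head(res$motif$loss$motif, 5L)))
    } else character()
    motif_of <- strsplit(stats::setNames(anno$motif_hits, anno$probe_id),
                         ",", fixed = TRUE)
    enrich_fun <- function(ids) {
      out <- list(states = feature_enrichment(ids, nondmc_ids,
                                              strata = st_mono),
                  dhs = feature_enrichment(ids, nondmc_ids,
                                           feature = dhs_change))
      for (mt in top_motifs) {
        fm <- vapply(motif_of, function(z) mt %in% z, TRUE)
        out[[paste0("motif_", mt)]] <-
          feature_enrichment(ids, nondmc_ids, feature = fm)
      }
      out
    }
    gain_set <- intersect(cuts$retained[[">5%|any"]], gain_ids)
    loss_set <- intersect(cuts$retained[[">5%|any"]], loss_ids)
    per_dir <- list()
    for (key in names(cuts$retained)) {
      per_dir[[paste0(key, "|gain")]] <- intersect(cuts$retained[[key]],
                                                   gain_set)
      per_dir[[paste0(key, "|loss")]] <- intersect(cuts$retained[[key]],
                                                   loss_set)
    }
    res$thresholds <- list(
      report = cuts$report,
      retained = cuts$retained,
      n_base = cuts$n_base, n_base_gain = cuts$n_base_gain,
      n_base_loss = cuts$n_base_loss,
      reruns = rerun_enrichments(per_dir, enrich_fun,
                                 min_size = config$rerun_min_size))
  }

  if (!is.null(bundle$truth)) res$truth <- bundle$truth
  res$manifest <- list(
    package = "macmeth",
    version = as.character(utils::packageVersion("macmeth")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    thresholds = list(q_max = config$q_max, ms_min = config$ms_min,
                      dmr_min_diff = config$dmr_min_diff,
                      dmr_max_gap = config$dmr_max_gap,
                      motif_window_halfwidth = config$motif_window_halfwidth),
    counts = counts)

  if (!is.null(outdir)) .write_pipeline_outputs(res, outdir, bundle)
  invisible(res)
}

.write_pipeline_outputs <- function(res, outdir, bundle) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dmc_tab <- res$dmc
  if (!is.null(res$annotation)) {
    dmc_tab <- merge(dmc_tab, res$annotation, by = "probe_id", sort = FALSE)
  }
  if (!is.null(res$dmr)) {
    dmc_tab <- merge(dmc_tab,
                     res$dmr$table[, c("probe_id", "covered", "concordant",
                                       "wgbs_delta", "dmr_n_cpg",
                                       "dmr_length_bp", "dmr_mean_delta")],
                     by = "probe_id", all.x = TRUE, sort = FALSE)
  }
  dmc_tab <- dmc_tab[order(match(dmc_tab$probe_id, res$dmc$probe_id)), ]
  write_tsv(dmc_tab[dmc_tab$is_dmc, , drop = FALSE],
            file.path(outdir, "dmc_table.tsv"))
  if (!is.null(res$enrichment)) {
    for (nm in names(res$enrichment)) {
      write_tsv(res$enrichment[[nm]],
                file.path(outdir, paste0("enrichment_", nm, ".tsv")))
    }
  }
  if (!is.null(res$dmr)) {
    write_tsv(res$dmr$table, file.path(outdir, "dmr_table.tsv"))
  }
  if (!is.null(res$motif)) {
    write_tsv(res$motif$gain, file.path(outdir, "motif_gain.tsv"))
    write_tsv(res$motif$loss, file.path(outdir, "motif_loss.tsv"))
  }
  if (!is.null(res$thresholds)) {
    write_tsv(res$thresholds$report, file.path(outdir, "retention.tsv"))
  }
  if (!is.null(res$truth)) {
    write_tsv(res$truth, file.path(outdir, "truth.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
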