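#' Pipeline configuration
#'
#' One declarative object holding every threshold and input reference the
#' pipeline uses. Inputs come either from the synthetic generator (`sim`,
#' the default) or from files (`paths`, a named list; see Details).
#'
#' @details File mode expects `paths` entries: `beta`, `samplesheet`,
#' `cpg_map`, `wgbs_mono`, `wgbs_mac` (optionally `wgbs_mono_donors`,
#' `wgbs_mac_donors`), `states_mono`/`states_mac` (vectors of per-donor
#' BEDs), `dhs_mono`/`dhs_mac` (vectors of BEDs), `hic_mono`, `hic_mac`,
#' `motif_sites`, `genes`, `expression`, `pwms`, `genome` (FASTA). Stages
#' that lack their inputs fail validation before any computation.
#'
#' @param seed Random seed driving every stochastic step.
#' @param stages Stages to run, a subset of
#'   `c("ewas", "annotate", "enrich", "dmr", "motif", "thresholds")`.
#' @param q_max FDR threshold for DMC calling (default 0.05).
#' @param ms_min Mean-squares effect-size cutoff (default 0.0025).
#' @param multi_frac Multi-phase attribution fraction (default 0.9).
#' @param min_donors Minimum complete donors per tested CpG (default 3).
#' @param dmr_min_diff WGBS concordance/extension threshold (default 0.05).
#' @param dmr_max_gap Maximum intra-DMR gap in bp (default 1000).
#' @param wgbs_min_donors WGBS coverage sufficiency (default 3).
#' @param state_min_votes Chromatin-state majority votes (default 3).
#' @param dhs_min_votes Named DNaseI majority votes (default
#'   `c(monocyte = 3, macrophage = 2)`).
#' @param motif_window_halfwidth Motif window half-width in bp (default 25).
#' @param motif_background_n Background CpG sample size (default 50000).
#' @param motif_threshold_frac PWM hit threshold fraction (default 0.8).
#' @param rerun_min_size Minimum retained-set size for threshold re-runs
#'   (default 20).
#' @param tf_motifs Named map from ChIP TF track name to the motif scanned
#'   at its binding sites (used by the TF-binding-gain test).
#' @param sim A [sim_config()] (its seed is overridden by `seed`), or
#'   `NULL` in file mode.
#' @param paths Named list of input paths (file mode), or `NULL`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("ewas", "annotate", "enrich", "dmr",
                                       "motif", "thresholds"),
                            q_max = 0.05,
                            ms_min = 0.0025,
                            multi_frac = 0.9,
                            min_donors = 3L,
                            dmr_min_diff = 0.05,
                            dmr_max_gap = 1000L,
                            wgbs_min_donors = 3L,
                            state_min_votes = 3L,
                            dhs_min_votes = c(monocyte = 3L, macrophage = 2L),
                            motif_window_halfwidth = 25L,
                            motif_background_n = 50000L,
                            motif_threshold_frac = 0.8,
                            rerun_min_size = 20L,
                            tf_motifs = c(CEBP = "CEBP_like",
                                          PU1 = "ETS_like"),
                            sim = sim_config(),
                            paths = NULL) {
  cfg <- as.list(environment())
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges and, in file mode, that every enabled stage has
#' its inputs, before any computation.
#'
#' @param config A `pipeline_config`.
#' @return The config, invisibly classed, or an error.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  with(config, {
    stopifnot(q_max > 0, q_max <= 1, ms_min >= 0,
              multi_frac > 0, multi_frac <= 1,
              dmr_min_diff >= 0, dmr_min_diff <= 1, dmr_max_gap >= 1,
              motif_window_halfwidth >= 1, motif_background_n >= 1,
              motif_threshold_frac > 0, motif_threshold_frac <= 1,
              rerun_min_size >= 0)
    stopifnot(all(stages %in% c("ewas", "annotate", "enrich", "dmr",
                                "motif", "thresholds")))
  })
  if (is.null(config$sim) && is.null(config$paths)) {
    stop("config needs either 'sim' (synthetic mode) or 'paths' (file mode)")
  }
  if (!is.null(config$sim)) stopifnot(inherits(config$sim, "sim_config"))
  if (is.null(config$sim)) {
    need <- list(
      ewas = c("beta", "samplesheet", "cpg_map"),
      annotate = c("states_mono", "states_mac", "dhs_mono", "dhs_mac",
                   "hic_mono", "hic_mac", "motif_sites", "genes"),
      enrich = "expression",
      dmr = c("wgbs_mono", "wgbs_mac"),
      motif = c("pwms", "genome"),
      thresholds = character())
    for (st in config$stages) {
      missing <- setdiff(need[[st]], names(config$paths))
      if (length(missing) > 0L) {
        stop("stage '", st, "' enabled but config lacks path(s): ",
             paste(missing, collapse = ", "))
      }
    }
  }
  invisible(config)
}

.plain <- function(x) {
  if (inherits(x, "data.frame")) {
    c(list(".df" = TRUE), lapply(x, identity))
  } else if (is.list(x)) {
    lapply(x, .plain)
  } else x
}

.unplain <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x[[".df"]])) {
      as.data.frame(x[setdiff(names(x), ".df")], stringsAsFactors = FALSE)
    } else lapply(x, .unplain)
  } else x
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- .plain(unclass(config))
  if (!is.null(config$sim)) x$sim <- .plain(unclass(config$sim))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Round-trips exactly with [write_config()] for valid configurations.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  x <- .unplain(yaml::read_yaml(path))
  if (!is.null(x$sim)) {
    sim <- x$sim
    sim$states <- as.character(unlist(sim$states))
    sim$state_names <- as.character(unlist(sim$state_names))
    sim$activation_counts <- lapply(sim$activation_counts, unlist)
    for (nm in c("n_dhs_donors", "dhs_min_votes", "dhs_change_prob",
                 "gain_motifs", "loss_motifs", "chip_tfs",
                 "state_background_probs")) {
      sim[[nm]] <- unlist(sim[[nm]])
    }
    x$sim <- do.call(sim_config, sim)
  }
  x$dhs_min_votes <- unlist(x$dhs_min_votes)
  x$tf_motifs <- unlist(x$tf_motifs)
  x$stages <- as.character(unlist(x$stages))
  do.call(pipeline_config, x)
}
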