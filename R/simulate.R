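#' Default chromatin-state alphabet
#'
#' Nine labels following the usual reference nomenclature for a
#' four-histone-mark model, with "active" marking H3K27ac-containing
#' states.
#' @return Character vector of nine state names.
#' @export
default_state_names <- function() {
  c("tss", "active_tss", "flank_tss", "enhancer", "active_enhancer",
    "transcription", "quiescent", "polycomb", "bivalent")
}

#' Default PWM set for the synthetic genome
#'
#' Six sharp motifs: the three planted around DMCs by default
#' (`CEBP_like`, `ETS_like` for gain; `AP1_like` for loss) plus three
#' decoys. Consensus bases carry probability 0.91.
#'
#' @param pseudocount Passed to [new_pwm()].
#' @return Named list of [new_pwm()] objects with a `consensus` attribute
#'   per element.
#' @export
default_pwms <- function(pseudocount = 0.01) {
  cons <- c(CEBP_like = "TTGCGCAA", ETS_like = "ACAGGAAGT",
            AP1_like = "TGACTCA", NFKB_like = "GGGAATTTCC",
            GATA_like = "AGATAAGA", IRF_like = "TTTCACTTTC")
  bases <- c("A", "C", "G", "T")
  pwms <- lapply(names(cons), function(nm) {
    chars <- strsplit(cons[[nm]], "")[[1L]]
    mat <- matrix(0.03, 4L, length(chars), dimnames = list(bases, NULL))
    mat[cbind(match(chars, bases), seq_along(chars))] <- 0.91
    p <- new_pwm(nm, mat, pseudocount = pseudocount)
    attr(p, "consensus") <- cons[[nm]]
    p
  })
  stats::setNames(pwms, names(cons))
}

#' Configuration for the synthetic study generator
#'
#' Defaults define the default desk-scale study: 4 donors x 6 cell states,
#' bimodal baseline methylation, differentiation DMCs planted as gain
#' (smaller effects, shorter regions) and loss (larger effects, longer
#' regions), rare loss-dominated activation effects, WGBS tracks with
#' partial coverage and partial array concordance, consensus-with-noise
#' donor annotation tracks, and motif/ChIP placements tied to planted DMC
#' directions. See the methods vignette for the rationale behind each
#' default.
#'
#' @param n_cpgs Number of array CpGs.
#' @param n_donors Donors (paired across all states).
#' @param states Cell states (first = monocyte, second = naive macrophage).
#' @param donor_sd Between-donor SD of the baseline beta.
#' @param noise_sd Residual SD of array betas.
#' @param n_gain_diff,n_loss_diff Planted differentiation DMC counts.
#' @param gain_effect_range,loss_effect_range Uniform ranges for |delta
#'   beta| of planted differentiation effects.
#' @param activation_counts Named list per activated state of
#'   `c(gain = , loss = )` planted counts.
#' @param activation_effect_range Uniform |delta| range for activation and
#'   macrophage-specific effects.
#' @param n_mac_specific Planted macrophage-specific DMCs (half gain).
#' @param frac_single_cpg Fraction of WGBS-expressed planted effects
#'   confined to a single WGBS CpG.
#' @param region_ncpg_gain,region_ncpg_loss Candidate WGBS CpG counts for
#'   multi-CpG regions by direction.
#' @param clamp_margin Betas are kept within `[margin, 1 - margin]` before
#'   noise.
#' @param array_spacing `c(min, max)` uniform gap between array CpGs (bp).
#' @param wgbs_spacing_mean Mean WGBS inter-CpG spacing (geometric, bp).
#' @param wgbs_coverage Probability an array CpG is sufficiently covered in
#'   both WGBS tracks.
#' @param wgbs_dmc_concordance Probability a planted differentiation /
#'   macrophage-specific effect is expressed in WGBS.
#' @param wgbs_background_diff_rate Probability a background WGBS CpG
#'   carries a random-direction difference.
#' @param wgbs_background_diff_range Uniform |delta| range of such
#'   background differences.
#' @param wgbs_noise_sd Per-track WGBS noise SD.
#' @param wgbs_donors,wgbs_min_donors Donor count written to tracks and
#'   the sufficiency threshold.
#' @param chrom Chromosome name of the synthetic genome.
#' @param state_names Chromatin-state alphabet.
#' @param state_background_probs Named sampling weights of background
#'   monocyte states.
#' @param state_churn Probability a background CpG changes state between
#'   cell types.
#' @param gain_transitions,loss_transitions data.frames (`mono`, `mac`,
#'   `prob`) of planted state transitions per DMC direction.
#' @param state_concordance Probability a donor segment equals the
#'   consensus state.
#' @param n_state_donors,state_min_votes Donor tracks and majority votes
#'   for states.
#' @param segment_halfwidth State segment half-width (bp).
#' @param n_dhs_donors,dhs_min_votes Named (`monocyte`, `macrophage`)
#'   DNaseI donor counts and majority thresholds.
#' @param dhs_change_prob Named (`gain`, `loss`) probability a planted DMC
#'   sits at a DNaseI change.
#' @param dhs_background_both,dhs_background_change Background DNaseI
#'   rates (peak in both / change).
#' @param dhs_donor_sensitivity,dhs_donor_fpr Per-donor peak recall and
#'   spurious-peak rate.
#' @param dhs_halfwidth DNaseI peak half-width (bp).
#' @param hic_dmc_prob,hic_background_prob,hic_halfwidth Hi-C enhancer
#'   placement rates and half-width.
#' @param gain_motifs,loss_motifs Named placement probabilities of motifs
#'   within the window of planted DMCs by direction.
#' @param background_motif_prob Per-CpG, per-motif background placement
#'   rate.
#' @param motif_window_halfwidth Window half-width for placement and
#'   scanning (bp).
#' @param chip_tfs Named map motif -> TF name for ChIP tracks.
#' @param chip_binding_gain_prob,chip_both_prob Binding-gain / constitutive
#'   rates at planted gain-DMC motif sites.
#' @param chip_background_both,chip_background_gain Background ChIP rates.
#' @param chip_halfwidth ChIP peak half-width (bp).
#' @param gene_spacing,gene_length_range Gene tiling parameters (bp).
#' @param expr_baseline `c(mean, sd)` of monocyte logTPM.
#' @param expr_shift Expression shift of genes nearest to loss (+) / gain
#'   (-) differentiation DMCs.
#' @param expr_noise_sd Residual SD of the macrophage - monocyte shift.
#' @param seed Random seed for [simulate_study()] / [simulate_all()].
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_cpgs = 10000L,
                       n_donors = 4L,
                       states = default_states(),
                       donor_sd = 0.05,
                       noise_sd = 0.03,
                       n_gain_diff = 1200L,
                       n_loss_diff = 800L,
                       gain_effect_range = c(0.10, 0.25),
                       loss_effect_range = c(0.30, 0.50),
                       activation_counts = list(
                         mac_lps_ifng = c(gain = 2L, loss = 12L),
                         mac_il4 = c(gain = 1L, loss = 1L),
                         mac_oxldl = c(gain = 0L, loss = 2L),
                         mac_acldl = c(gain = 0L, loss = 1L)),
                       activation_effect_range = c(0.15, 0.35),
                       n_mac_specific = 4L,
                       frac_single_cpg = 0.26,
                       region_ncpg_gain = 2:4,
                       region_ncpg_loss = 5:9,
                       clamp_margin = 0.02,
                       array_spacing = c(400L, 800L),
                       wgbs_spacing_mean = 40,
                       wgbs_coverage = 0.78,
                       wgbs_dmc_concordance = 0.5,
                       wgbs_background_diff_rate = 0.10,
                       wgbs_background_diff_range = c(0.05, 0.20),
                       wgbs_noise_sd = 0.01,
                       wgbs_donors = 4L,
                       wgbs_min_donors = 3L,
                       chrom = "chr1",
                       state_names = default_state_names(),
                       state_background_probs = c(
                         tss = 0.04, active_tss = 0.03, flank_tss = 0.05,
                         enhancer = 0.10, active_enhancer = 0.05,
                         transcription = 0.15, quiescent = 0.50,
                         polycomb = 0.05, bivalent = 0.03),
                       state_churn = 0.15,
                       gain_transitions = data.frame(
                         mono = c("quiescent", "enhancer", "polycomb"),
                         mac = c("quiescent", "quiescent", "polycomb"),
                         prob = c(0.4, 0.3, 0.3),
                         stringsAsFactors = FALSE),
                       loss_transitions = data.frame(
                         mono = c("enhancer", "quiescent"),
                         mac = c("active_enhancer", "enhancer"),
                         prob = c(0.6, 0.4),
                         stringsAsFactors = FALSE),
                       state_concordance = 0.9,
                       n_state_donors = 5L,
                       state_min_votes = 3L,
                       segment_halfwidth = 200L,
                       n_dhs_donors = c(monocyte = 5L, macrophage = 4L),
                       dhs_min_votes = c(monocyte = 3L, macrophage = 2L),
                       dhs_change_prob = c(gain = 0.30, loss = 0.60),
                       dhs_background_both = 0.10,
                       dhs_background_change = 0.03,
                       dhs_donor_sensitivity = 0.9,
                       dhs_donor_fpr = 0.05,
                       dhs_halfwidth = 75L,
                       hic_dmc_prob = 0.30,
                       hic_background_prob = 0.15,
                       hic_halfwidth = 500L,
                       gain_motifs = c(CEBP_like = 0.50, ETS_like = 0.35),
                       loss_motifs = c(AP1_like = 0.50),
                       background_motif_prob = 0.02,
                       motif_window_halfwidth = 25L,
                       chip_tfs = c(CEBP_like = "CEBP", ETS_like = "PU1"),
                       chip_binding_gain_prob = 0.60,
                       chip_both_prob = 0.20,
                       chip_background_both = 0.05,
                       chip_background_gain = 0.09,
                       chip_halfwidth = 100L,
                       gene_spacing = 3000L,
                       gene_length_range = c(500L, 2000L),
                       expr_baseline = c(5, 1.5),
                       expr_shift = 1.0,
                       expr_noise_sd = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  n_planted <- cfg$n_gain_diff + cfg$n_loss_diff +
    sum(vapply(cfg$activation_counts, sum, 0)) + cfg$n_mac_specific
  stopifnot(
    cfg$n_cpgs >= 1L, cfg$n_donors >= 3L, length(cfg$states) >= 2L,
    cfg$donor_sd > 0 || cfg$donor_sd == 0, cfg$noise_sd >= 0,
    n_planted <= cfg$n_cpgs,
    all(cfg$gain_effect_range > 0), all(cfg$loss_effect_range > 0),
    cfg$frac_single_cpg >= 0, cfg$frac_single_cpg <= 1,
    cfg$wgbs_coverage >= 0, cfg$wgbs_coverage <= 1,
    cfg$wgbs_dmc_concordance >= 0, cfg$wgbs_dmc_concordance <= 1,
    cfg$state_concordance >= 0, cfg$state_concordance <= 1,
    cfg$clamp_margin >= 0, cfg$clamp_margin < 0.5,
    cfg$segment_halfwidth >= 1L, cfg$motif_window_halfwidth >= 1L,
    all(names(cfg$activation_counts) %in% cfg$states))
  stopifnot(all(c(cfg$gain_transitions$mono, cfg$gain_transitions$mac,
                  cfg$loss_transitions$mono, cfg$loss_transitions$mac)
                %in% cfg$state_names))
  if (max(cfg$gain_effect_range, cfg$loss_effect_range,
          cfg$activation_effect_range) + 2 * cfg$clamp_margin >= 1) {
    stop("effect sizes leave no room inside the clamp margin")
  }
  structure(cfg, class = "sim_config")
}

.clamp01 <- function(x, margin = 0) pmin(pmax(x, margin), 1 - margin)

.draw_mu_bimodal <- function(n, margin) {
  .clamp01(stats::rbeta(n, 0.6, 0.6), margin)
}

#' Simulate the paired methylation study
#'
#' Generates the beta matrix, sample sheet, CpG position map and
#' ground-truth table. Betas follow
#' `clamp(mu_i + a_id + e_ic + eps, 0, 1)` with donor effects
#' `a ~ N(0, donor_sd^2)` and noise `eps ~ N(0, noise_sd^2)`; `e_ic` is 0
#' except at planted CpGs (differentiation: all five macrophage-derived
#' states; activation: one activated state; macrophage-specific: the naive
#' macrophage only). Baselines are bimodal spanning ~0-1; planted baselines
#' are re-drawn so the effect fits inside the clamp margin. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return list: `beta` (matrix CpG x sample), `samples` (sample sheet),
#'   `cpg_map`, `truth` (one row per planted CpG: `probe_id`, `phase`,
#'   `direction`, `true_delta`, `region_id`, `region_n_cpg`), `mu` (named
#'   baseline vector, used by [simulate_wgbs()]), `clamped_frac`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cpgs
  k <- length(cfg$states)
  probe_id <- sprintf("cg%07d", seq_len(n))
  gaps <- round(stats::runif(n, cfg$array_spacing[1L], cfg$array_spacing[2L]))
  pos <- 1000L + cumsum(as.integer(gaps))
  cpg_map <- data.frame(probe_id = probe_id, chrom = cfg$chrom, pos = pos,
                        strand = "+", stringsAsFactors = FALSE)

  # --- planted assignment (disjoint) ------------------------------------
  act_states <- names(cfg$activation_counts)
  n_act <- vapply(cfg$activation_counts, sum, 0)
  n_planted <- cfg$n_gain_diff + cfg$n_loss_diff + sum(n_act) +
    cfg$n_mac_specific
  planted_idx <- sample.int(n, n_planted)
  take <- function(m) {
    out <- planted_idx[seq_len(m)]
    planted_idx <<- planted_idx[-seq_len(m)]
    out
  }
  truth_rows <- list()
  add_truth <- function(idx, phase, direction, delta) {
    if (length(idx) == 0L) return(invisible(NULL))
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      probe_id = probe_id[idx], phase = phase, direction = direction,
      true_delta = delta, stringsAsFactors = FALSE)
  }
  gi <- take(cfg$n_gain_diff)
  add_truth(gi, "differentiation", "gain",
            stats::runif(cfg$n_gain_diff, cfg$gain_effect_range[1L],
                         cfg$gain_effect_range[2L]))
  li <- take(cfg$n_loss_diff)
  add_truth(li, "differentiation", "loss",
            -stats::runif(cfg$n_loss_diff, cfg$loss_effect_range[1L],
                          cfg$loss_effect_range[2L]))
  for (st in act_states) {
    cts <- cfg$activation_counts[[st]]
    if (cts[["gain"]] > 0L) {
      ai <- take(cts[["gain"]])
      add_truth(ai, paste0("activation:", st), "gain",
                stats::runif(cts[["gain"]], cfg$activation_effect_range[1L],
                             cfg$activation_effect_range[2L]))
    }
    if (cts[["loss"]] > 0L) {
      ai <- take(cts[["loss"]])
      add_truth(ai, paste0("activation:", st), "loss",
                -stats::runif(cts[["loss"]], cfg$activation_effect_range[1L],
                              cfg$activation_effect_range[2L]))
    }
  }
  if (cfg$n_mac_specific > 0L) {
    ms <- take(cfg$n_mac_specific)
    half <- ceiling(cfg$n_mac_specific / 2)
    dirs <- rep(c("gain", "loss"), c(half, cfg$n_mac_specific - half))
    dl <- stats::runif(cfg$n_mac_specific, cfg$activation_effect_range[1L],
                       cfg$activation_effect_range[2L])
    add_truth(ms, "macrophage-specific", dirs,
              ifelse(dirs == "gain", dl, -dl))
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(probe_id = character(), phase = character(),
               direction = character(), true_delta = numeric(),
               stringsAsFactors = FALSE)

  # --- region geometry (used by simulate_wgbs) --------------------------
  regional <- truth$phase %in% c("differentiation", "macrophage-specific")
  nreg <- sum(regional)
  single <- stats::runif(nreg) < cfg$frac_single_cpg
  sizes <- integer(nreg)
  gdir <- truth$direction[regional]
  sizes[single] <- 1L
  pick <- function(set, m) if (m == 0L) integer() else
    set[sample.int(length(set), m, replace = TRUE)]
  sizes[!single & gdir == "gain"] <-
    pick(cfg$region_ncpg_gain, sum(!single & gdir == "gain"))
  sizes[!single & gdir == "loss"] <-
    pick(cfg$region_ncpg_loss, sum(!single & gdir == "loss"))
  truth$region_id <- rep(NA_character_, nrow(truth))
  truth$region_n_cpg <- rep(NA_integer_, nrow(truth))
  truth$region_id[regional] <- truth$probe_id[regional]
  truth$region_n_cpg[regional] <- sizes

  # --- baselines and effects --------------------------------------------
  mu <- .draw_mu_bimodal(n, cfg$clamp_margin)
  names(mu) <- probe_id
  ti <- match(truth$probe_id, probe_id)
  # re-draw planted baselines so mu and mu + delta stay inside the margin
  lo <- ifelse(truth$true_delta > 0, cfg$clamp_margin,
               cfg$clamp_margin - truth$true_delta)
  hi <- ifelse(truth$true_delta > 0, 1 - cfg$clamp_margin - truth$true_delta,
               1 - cfg$clamp_margin)
  mu[ti] <- stats::runif(nrow(truth), lo, hi)

  effects <- matrix(0, n, k, dimnames = list(probe_id, cfg$states))
  mac_states <- cfg$states[-1L]
  diff_rows <- ti[truth$phase == "differentiation"]
  effects[diff_rows, mac_states] <-
    matrix(rep(truth$true_delta[truth$phase == "differentiation"],
               length(mac_states)), ncol = length(mac_states))
  msp <- truth$phase == "macrophage-specific"
  effects[ti[msp], cfg$states[2L]] <- truth$true_delta[msp]
  for (st in act_states) {
    sel <- truth$phase == paste0("activation:", st)
    effects[ti[sel], st] <- truth$true_delta[sel]
  }

  donors <- paste0("donor", seq_len(cfg$n_donors))
  samples <- data.frame(
    sample_id = as.vector(outer(donors, cfg$states, paste, sep = "_")),
    donor = rep(donors, times = k),
    cell_type = rep(cfg$states, each = cfg$n_donors),
    sex = rep(ifelse(seq_len(cfg$n_donors) <= ceiling(cfg$n_donors * 0.75),
                     "M", "F"), times = k),
    stringsAsFactors = FALSE)
  a <- matrix(stats::rnorm(n * cfg$n_donors, 0, cfg$donor_sd),
              n, cfg$n_donors)
  beta <- matrix(0, n, nrow(samples),
                 dimnames = list(probe_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    d <- match(samples$donor[j], donors)
    c_ <- samples$cell_type[j]
    raw <- mu + a[, d] + effects[, c_] +
      stats::rnorm(n, 0, cfg$noise_sd)
    beta[, j] <- .clamp01(raw)
  }
  clamped_frac <- mean(beta == 0 | beta == 1)
  list(beta = beta, samples = samples, cpg_map = cpg_map, truth = truth,
       mu = mu, clamped_frac = clamped_frac)
}

#' Simulate per-cell-type WGBS CpG tracks
#'
#' WGBS CpGs are laid out with geometric inter-CpG spacing and include the
#' array positions. Array CpGs are sufficiently covered (present in both
#' tracks with full donor count) with probability `wgbs_coverage`. A
#' planted differentiation / macrophage-specific effect is expressed in
#' WGBS with probability `wgbs_dmc_concordance`; when expressed it spans
#' its region's consecutive WGBS CpGs with the planted sign (a region of 1
#' is the single-CpG case). Background WGBS CpGs carry a random-direction
#' difference with probability `wgbs_background_diff_rate`.
#'
#' @param cfg A [sim_config()].
#' @param study Output of [simulate_study()] (uses `truth`, `cpg_map`,
#'   `mu`). Uses the current RNG state (call after [simulate_study()] or
#'   via [simulate_all()]).
#' @return list: `mono`, `mac` (WGBS tracks as [read_wgbs_track()]
#'   data.frames), `truth_wgbs` (per planted regional CpG: `probe_id`,
#'   `expressed`, realized `region_n_cpg`, `region_start`, `region_end`).
#' @export
simulate_wgbs <- function(cfg, study) {
  truth <- study$truth
  cpg_map <- study$cpg_map
  last <- max(cpg_map$pos) + 2000L
  m_est <- ceiling(last / max(cfg$wgbs_spacing_mean - 2, 1)) + 1000L
  gaps <- 2L + stats::rgeom(m_est, 1 / max(cfg$wgbs_spacing_mean - 2, 1))
  wpos <- 500L + cumsum(gaps)
  wpos <- wpos[wpos <= last]
  wpos <- sort(unique(c(wpos, cpg_map$pos)))
  m <- length(wpos)
  is_array <- wpos %in% cpg_map$pos
  base <- numeric(m)
  base[is_array] <- study$mu[match(wpos[is_array], cpg_map$pos)]
  base[!is_array] <- .draw_mu_bimodal(sum(!is_array), cfg$clamp_margin)

  delta <- numeric(m)
  # background regional variation, random direction
  bg <- stats::runif(m) < cfg$wgbs_background_diff_rate
  nbg <- sum(bg)
  delta[bg] <- sample(c(-1, 1), nbg, replace = TRUE) *
    stats::runif(nbg, cfg$wgbs_background_diff_range[1L],
                 cfg$wgbs_background_diff_range[2L])

  regional <- which(truth$phase %in% c("differentiation",
                                       "macrophage-specific"))
  nr <- length(regional)
  tw <- data.frame(probe_id = truth$probe_id[regional],
                   expressed = rep(FALSE, nr),
                   region_n_cpg = rep(NA_integer_, nr),
                   region_start = rep(NA_integer_, nr),
                   region_end = rep(NA_integer_, nr),
                   stringsAsFactors = FALSE)
  expressed <- stats::runif(length(regional)) < cfg$wgbs_dmc_concordance
  member <- logical(m)
  flank <- integer(0)
  for (r in seq_along(regional)) {
    i <- regional[r]
    seed_pos <- cpg_map$pos[match(truth$probe_id[i], cpg_map$probe_id)]
    j <- match(seed_pos, wpos)
    if (!expressed[r]) {
      delta[j] <- 0  # array effect does not replicate in WGBS
      next
    }
    size <- truth$region_n_cpg[i]
    offset <- sample.int(size, 1L) - 1L
    from <- max(1L, j - offset)
    to <- min(m, from + size - 1L)
    from <- max(1L, to - size + 1L)
    dlt <- truth$true_delta[i]
    delta[from:to] <- dlt
    # region members share the seed's baseline regime so the planted
    # difference has room on every member CpG (it must not clamp away)
    mlo <- if (dlt > 0) cfg$clamp_margin else cfg$clamp_margin - dlt
    mhi <- if (dlt > 0) 1 - cfg$clamp_margin - dlt else 1 - cfg$clamp_margin
    memb <- setdiff(from:to, j)
    base[memb] <- pmin(pmax(base[j] + stats::rnorm(length(memb), 0, 0.05),
                            mlo), mhi)
    member[from:to] <- TRUE
    flank <- c(flank, from - 1L, to + 1L)
    tw$expressed[r] <- TRUE
    tw$region_n_cpg[r] <- to - from + 1L
    tw$region_start[r] <- wpos[from]
    tw$region_end[r] <- wpos[to]
  }

  # planted regions must not bleed into adjacent background differences:
  # the CpG on either side of a planted region carries no difference, so
  # realized region geometry equals the planted geometry
  flank <- setdiff(flank[flank >= 1L & flank <= m], which(member))
  delta[flank] <- 0

  covered <- rep(TRUE, m)
  covered[is_array] <- stats::runif(sum(is_array)) < cfg$wgbs_coverage
  nd_mono <- rep(cfg$wgbs_donors, m)
  nd_mac <- rep(cfg$wgbs_donors, m)
  drop_mono <- logical(m)
  drop_mac <- logical(m)
  unc <- which(!covered)
  if (length(unc) > 0L) {
    mode <- sample(3L, length(unc), replace = TRUE)
    drop_mono[unc[mode == 1L]] <- TRUE
    drop_mac[unc[mode == 2L]] <- TRUE
    low <- unc[mode == 3L]
    nd_mono[low] <- sample(cfg$wgbs_min_donors - 1L, length(low),
                           replace = TRUE)
  }
  beta_mono <- .clamp01(base + stats::rnorm(m, 0, cfg$wgbs_noise_sd))
  beta_mac <- .clamp01(base + delta + stats::rnorm(m, 0, cfg$wgbs_noise_sd))
  mono <- data.frame(chrom = cfg$chrom, pos = wpos, beta = beta_mono,
                     n_donors = nd_mono,
                     stringsAsFactors = FALSE)[!drop_mono, , drop = FALSE]
  mac <- data.frame(chrom = cfg$chrom, pos = wpos, beta = beta_mac,
                    n_donors = nd_mac,
                    stringsAsFactors = FALSE)[!drop_mac, , drop = FALSE]
  rownames(mono) <- rownames(mac) <- NULL
  list(mono = mono, mac = mac, truth_wgbs = tw)
}

.place_intervals <- function(chrom, centers, halfwidth, label) {
  if (length(centers) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(chrom = chrom, start = pmax(0L, centers - 1L - halfwidth),
             end = centers + halfwidth, label = label,
             stringsAsFactors = FALSE)
}

#' Simulate annotation tracks, genome, motifs, ChIP, genes and expression
#'
#' Builds per-donor chromatin-state and DNaseI tracks around a per-CpG
#' consensus (donors agree with the consensus with probability
#' `state_concordance` / `dhs_donor_sensitivity`), Hi-C enhancer intervals,
#' a random genome with motif consensus sequences written at planted and
#' background motif sites, ChIP tracks with binding gain at planted
#' gain-DMC motif sites, gene models tiling the genome, and a logTPM
#' expression table shifted for genes nearest to planted differentiation
#' DMCs (loss up, gain down in macrophages). Uses the current RNG state.
#'
#' @param cfg A [sim_config()].
#' @param study Output of [simulate_study()].
#' @return list: `state_tracks`, `dhs_tracks` (each
#'   `list(monocyte = , macrophage = )` of per-donor interval
#'   data.frames), `consensus_states` (data.frame per CpG: truth-level
#'   `state_mono`, `state_mac`), `dhs_consensus` (`dhs_mono`, `dhs_mac`),
#'   `hic`, `motif_sites`, `chip` (per TF `list(monocyte, macrophage)`),
#'   `genes`, `expression`, `genome`, `pwms`.
#' @export
simulate_annotation_tracks <- function(cfg, study) {
  cpg_map <- study$cpg_map
  truth <- study$truth
  n <- nrow(cpg_map)
  ti <- match(truth$probe_id, cpg_map$probe_id)
  dir_of <- rep(NA_character_, n)
  dir_of[ti[truth$phase == "differentiation"]] <-
    truth$direction[truth$phase == "differentiation"]

  # --- chromatin-state consensus per CpG --------------------------------
  st_mono <- sample(names(cfg$state_background_probs), n, replace = TRUE,
                    prob = cfg$state_background_probs)
  churn <- stats::runif(n) < cfg$state_churn
  st_mac <- st_mono
  st_mac[churn] <- vapply(st_mono[churn], function(s) {
    sample(setdiff(cfg$state_names, s), 1L)
  }, "")
  for (d in c("gain", "loss")) {
    tr <- if (d == "gain") cfg$gain_transitions else cfg$loss_transitions
    rows <- which(!is.na(dir_of) & dir_of == d)
    if (length(rows) == 0L) next
    pickt <- sample.int(nrow(tr), length(rows), replace = TRUE,
                        prob = tr$prob)
    st_mono[rows] <- tr$mono[pickt]
    st_mac[rows] <- tr$mac[pickt]
  }
  seg_start <- pmax(0L, cpg_map$pos - 1L - cfg$segment_halfwidth)
  seg_end <- cpg_map$pos + cfg$segment_halfwidth
  donor_states <- function(consensus) {
    lapply(seq_len(cfg$n_state_donors), function(d) {
      agree <- stats::runif(n) < cfg$state_concordance
      lab <- consensus
      if (any(!agree)) {
        lab[!agree] <- vapply(consensus[!agree], function(s) {
          sample(setdiff(cfg$state_names, s), 1L)
        }, "")
      }
      data.frame(chrom = cfg$chrom, start = seg_start, end = seg_end,
                 label = lab, stringsAsFactors = FALSE)
    })
  }
  state_tracks <- list(monocyte = donor_states(st_mono),
                       macrophage = donor_states(st_mac))

  # --- DNaseI consensus and donor tracks --------------------------------
  dhs_mono <- logical(n)
  dhs_mac <- logical(n)
  u <- stats::runif(n)
  both <- u < cfg$dhs_background_both
  chg <- !both & u < cfg$dhs_background_both + cfg$dhs_background_change
  dhs_mono[both] <- TRUE
  dhs_mac[both] <- TRUE
  side <- stats::runif(n) < 0.5
  dhs_mono[chg & side] <- TRUE
  dhs_mac[chg & !side] <- TRUE
  for (d in c("gain", "loss")) {
    rows <- which(!is.na(dir_of) & dir_of == d)
    pl <- rows[stats::runif(length(rows)) < cfg$dhs_change_prob[[d]]]
    dhs_mono[pl] <- FALSE  # DNaseI site acquired during differentiation
    dhs_mac[pl] <- TRUE
  }
  donor_peaks <- function(consensus, n_donors) {
    lapply(seq_len(n_donors), function(d) {
      has <- (consensus & stats::runif(n) < cfg$dhs_donor_sensitivity) |
        (!consensus & stats::runif(n) < cfg$dhs_donor_fpr)
      .place_intervals(cfg$chrom, cpg_map$pos[has], cfg$dhs_halfwidth, "1")
    })
  }
  dhs_tracks <- list(
    monocyte = donor_peaks(dhs_mono, cfg$n_dhs_donors[["monocyte"]]),
    macrophage = donor_peaks(dhs_mac, cfg$n_dhs_donors[["macrophage"]]))

  # --- Hi-C enhancers ----------------------------------------------------
  is_dmc_pos <- !is.na(dir_of)
  hic_one <- function() {
    p <- ifelse(is_dmc_pos, cfg$hic_dmc_prob, cfg$hic_background_prob)
    has <- stats::runif(n) < p
    .place_intervals(cfg$chrom, cpg_map$pos[has], cfg$hic_halfwidth,
                     "enhancer")
  }
  hic <- list(monocyte = hic_one(), macrophage = hic_one())

  # --- genome, motif sites ----------------------------------------------
  glen <- max(cpg_map$pos) + 2000L
  genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  pwms <- default_pwms()
  site_rows <- list()
  place_motif <- function(rows, motif) {
    cons <- attr(pwms[[motif]], "consensus")
    L <- nchar(cons)
    span <- cfg$motif_window_halfwidth * 2L + 1L - L
    stopifnot(span >= 0L)
    starts <- cpg_map$pos[rows] - cfg$motif_window_halfwidth +
      sample.int(span + 1L, length(rows), replace = TRUE) - 1L
    for (i in seq_along(rows)) {
      genome_chars[starts[i]:(starts[i] + L - 1L)] <<-
        strsplit(cons, "")[[1L]]
    }
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      chrom = cfg$chrom, start = starts - 1L, end = starts + L - 1L,
      label = motif, probe_id = cpg_map$probe_id[rows],
      stringsAsFactors = FALSE)
  }
  for (motif in names(cfg$gain_motifs)) {
    rows <- which(!is.na(dir_of) & dir_of == "gain" &
                    stats::runif(n) < cfg$gain_motifs[[motif]])
    if (length(rows)) place_motif(rows, motif)
  }
  for (motif in names(cfg$loss_motifs)) {
    rows <- which(!is.na(dir_of) & dir_of == "loss" &
                    stats::runif(n) < cfg$loss_motifs[[motif]])
    if (length(rows)) place_motif(rows, motif)
  }
  for (motif in names(pwms)) {
    rows <- which(is.na(dir_of) & stats::runif(n) < cfg$background_motif_prob)
    if (length(rows)) place_motif(rows, motif)
  }
  motif_sites <- do.call(rbind, site_rows)
  genome <- stats::setNames(list(paste(genome_chars, collapse = "")),
                            cfg$chrom)

  # --- ChIP tracks with binding gain at gain-DMC motif sites ------------
  chip <- list()
  for (motif in names(cfg$chip_tfs)) {
    tf <- cfg$chip_tfs[[motif]]
    at_motif <- unique(motif_sites$probe_id[motif_sites$label == motif])
    rows_gain <- which(cpg_map$probe_id %in% at_motif &
                         !is.na(dir_of) & dir_of == "gain")
    u <- stats::runif(length(rows_gain))
    bg_rows <- rows_gain[u < cfg$chip_binding_gain_prob]
    both_rows <- rows_gain[u >= cfg$chip_binding_gain_prob &
                             u < cfg$chip_binding_gain_prob + cfg$chip_both_prob]
    others <- setdiff(seq_len(n), rows_gain)
    ub <- stats::runif(length(others))
    o_both <- others[ub < cfg$chip_background_both]
    o_gain <- others[ub >= cfg$chip_background_both &
                       ub < cfg$chip_background_both + cfg$chip_background_gain]
    mono_centers <- cpg_map$pos[sort(c(both_rows, o_both))]
    mac_centers <- cpg_map$pos[sort(c(bg_rows, both_rows, o_both, o_gain))]
    chip[[tf]] <- list(
      monocyte = .place_intervals(cfg$chrom, mono_centers,
                                  cfg$chip_halfwidth, tf),
      macrophage = .place_intervals(cfg$chrom, mac_centers,
                                    cfg$chip_halfwidth, tf))
  }

  # --- genes and expression ---------------------------------------------
  n_genes <- max(2L, floor(glen / cfg$gene_spacing))
  gstart <- round(stats::runif(n_genes, 0.05, 0.55) * cfg$gene_spacing) +
    (seq_len(n_genes) - 1L) * cfg$gene_spacing
  glength <- round(stats::runif(n_genes, cfg$gene_length_range[1L],
                                cfg$gene_length_range[2L]))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(
    gene = sprintf("gene%05d", seq_len(n_genes)),
    chrom = cfg$chrom,
    tss = ifelse(strand == "+", gstart, gstart + glength),
    tes = ifelse(strand == "+", gstart + glength, gstart),
    strand = strand, stringsAsFactors = FALSE)
  diff_cpgs <- cpg_map[!is.na(dir_of), , drop = FALSE]
  ng <- nearest_gene(diff_cpgs, genes)
  shift <- stats::setNames(rep(0, n_genes), genes$gene)
  shift[unique(ng$nearest_gene[dir_of[!is.na(dir_of)] == "gain"])] <-
    -cfg$expr_shift
  shift[unique(ng$nearest_gene[dir_of[!is.na(dir_of)] == "loss"])] <-
    cfg$expr_shift
  mono_expr <- stats::rnorm(n_genes, cfg$expr_baseline[1L],
                            cfg$expr_baseline[2L])
  expression <- data.frame(
    gene = genes$gene,
    monocyte = mono_expr,
    macrophage = mono_expr + shift +
      stats::rnorm(n_genes, 0, cfg$expr_noise_sd),
    stringsAsFactors = FALSE)

  list(state_tracks = state_tracks, dhs_tracks = dhs_tracks,
       consensus_states = data.frame(probe_id = cpg_map$probe_id,
                                     state_mono = st_mono,
                                     state_mac = st_mac,
                                     stringsAsFactors = FALSE),
       dhs_consensus = data.frame(probe_id = cpg_map$probe_id,
                                  dhs_mono = dhs_mono, dhs_mac = dhs_mac,
                                  stringsAsFactors = FALSE),
       hic = hic, motif_sites = motif_sites, chip = chip, genes = genes,
       expression = expression, genome = genome, pwms = pwms)
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' Produces the file set consumed by the pipeline's file mode (and by the
#' package readers): beta matrix + sample sheet TSV, CpG map TSV, WGBS
#' bedGraphs with donor-count sidecars, per-donor state and DNaseI BEDs,
#' Hi-C BEDs, motif-site BED, ChIP BEDs, gene model TSV, expression TSV,
#' PWM file, genome FASTA and the truth table TSV.
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created).
#' @return Named list of written paths suitable for
#'   `pipeline_config(paths = )`.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, paste0(...))
  paths <- list(beta = fp("beta.tsv"), samplesheet = fp("samples.tsv"),
                cpg_map = fp("cpg_map.tsv"),
                wgbs_mono = fp("wgbs_mono.bedgraph"),
                wgbs_mono_donors = fp("wgbs_mono_donors.tsv"),
                wgbs_mac = fp("wgbs_mac.bedgraph"),
                wgbs_mac_donors = fp("wgbs_mac_donors.tsv"),
                hic_mono = fp("hic_mono.bed"), hic_mac = fp("hic_mac.bed"),
                motif_sites = fp("motif_sites.bed"),
                genes = fp("genes.tsv"), expression = fp("expression.tsv"),
                pwms = fp("motifs_synthetic.pwm"),
                genome = fp("genome_synthetic.fa"),
                truth = fp("truth.tsv"))
  write_beta_matrix(list(beta = sim$beta, samples = sim$samples),
                    paths$beta, paths$samplesheet)
  write_tsv(sim$cpg_map, paths$cpg_map)
  write_wgbs_track(sim$wgbs$mono, paths$wgbs_mono, paths$wgbs_mono_donors)
  write_wgbs_track(sim$wgbs$mac, paths$wgbs_mac, paths$wgbs_mac_donors)
  ann <- sim$annotation
  paths$states_mono <- vapply(seq_along(ann$state_tracks$monocyte),
    function(d) {
      p <- fp("states_mono_donor", d, ".bed")
      write_bed(ann$state_tracks$monocyte[[d]], p)
      p
    }, "")
  paths$states_mac <- vapply(seq_along(ann$state_tracks$macrophage),
    function(d) {
      p <- fp("states_mac_donor", d, ".bed")
      write_bed(ann$state_tracks$macrophage[[d]], p)
      p
    }, "")
  paths$dhs_mono <- vapply(seq_along(ann$dhs_tracks$monocyte), function(d) {
    p <- fp("dhs_mono_donor", d, ".bed")
    write_bed(ann$dhs_tracks$monocyte[[d]], p)
    p
  }, "")
  paths$dhs_mac <- vapply(seq_along(ann$dhs_tracks$macrophage), function(d) {
    p <- fp("dhs_mac_donor", d, ".bed")
    write_bed(ann$dhs_tracks$macrophage[[d]], p)
    p
  }, "")
  write_bed(ann$hic$monocyte, paths$hic_mono)
  write_bed(ann$hic$macrophage, paths$hic_mac)
  write_bed(ann$motif_sites[, c("chrom", "start", "end", "label")],
            paths$motif_sites)
  write_tsv(ann$genes, paths$genes)
  write_tsv(ann$expression, paths$expression)
  write_pwms(ann$pwms, paths$pwms)
  write_genome(ann$genome, paths$genome)
  write_tsv(sim$truth, paths$truth)
  paths$chip <- lapply(stats::setNames(names(ann$chip), names(ann$chip)),
    function(tf) {
      pm <- fp("chip_", tf, "_mono.bed")
      pc <- fp("chip_", tf, "_mac.bed")
      write_bed(ann$chip[[tf]]$monocyte, pm)
      write_bed(ann$chip[[tf]]$macrophage, pc)
      c(monocyte = pm, macrophage = pc)
    })
  paths
}

#' Simulate the complete study bundle
#'
#' Runs [simulate_study()], [simulate_wgbs()] and
#' [simulate_annotation_tracks()] in a fixed order under `cfg$seed`, so the
#' whole bundle is deterministic per seed.
#'
#' @param cfg A [sim_config()].
#' @return list combining all three generators' outputs (`beta`, `samples`,
#'   `cpg_map`, `truth`, `wgbs`, `annotation`).
#' @export
simulate_all <- function(cfg) {
  study <- simulate_study(cfg)
  wgbs <- simulate_wgbs(cfg, study)
  ann <- simulate_annotation_tracks(cfg, study)
  c(study, list(wgbs = wgbs, annotation = ann))
}
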