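mk_pair <- function(pos, delta, covered = TRUE) {
  data.frame(chrom = "chr1", pos = as.integer(pos),
             beta_mono = 0.5, beta_mac = 0.5 + delta,
             n_mono = 4L, n_mac = 4L, delta = delta,
             covered = rep_len(covered, length(pos)))
}

test_that("extend_dmr stops at the first non-qualifying CpG per direction", {
  pair <- mk_pair(c(100, 150, 220, 300), c(0.08, 0.06, 0.02, 0.07))
  r <- extend_dmr(pair, seed_index = 2, min_diff = 0.05, max_gap = 1000)
  expect_true(r$concordant)
  expect_equal(r$members, c(100, 150))
  expect_equal(r$n_cpg, 2)
  expect_equal(r$length_bp, 51)
  expect_equal(r$mean_delta, 0.07)
})

test_that("an isolated seed yields a single-CpG DMR of length 1", {
  pair <- mk_pair(c(100, 150, 200), c(0.01, 0.20, -0.02))
  r <- extend_dmr(pair, 2)
  expect_equal(r$n_cpg, 1)
  expect_equal(r$length_bp, 1)
  expect_equal(r$start, r$end)
})

test_that("the gap rule excludes distant qualifying CpGs", {
  pair <- mk_pair(c(100, 2000100), c(0.2, 0.2))
  expect_equal(extend_dmr(pair, 1, max_gap = 1000)$n_cpg, 1)
  # the literal megabase-scale rule is selectable
  pair2 <- mk_pair(c(100, 900100), c(0.2, 0.2))
  expect_equal(extend_dmr(pair2, 1, max_gap = 1e6)$n_cpg, 2)
})

test_that("a non-concordant seed is marked and carries no DMR", {
  pair <- mk_pair(c(100, 150), c(0.02, 0.3))
  r <- extend_dmr(pair, 1)
  expect_false(r$concordant)
  expect_true(is.na(r$n_cpg))
})

test_that("extension sign follows the seed and never mixes directions", {
  pair <- mk_pair(c(10, 40, 70, 100, 130), c(0.1, -0.1, 0.2, 0.15, -0.3))
  r <- extend_dmr(pair, 3)
  expect_equal(r$members, c(70, 100))
  expect_true(all(pair$delta[pair$pos %in% r$members] >= 0.05))
})

test_that("extend_dmr equals the brute-force maximal-run oracle", {
  for (s in 1:200) {
    pair <- random_wgbs_pair(n = 25, seed = s)
    seeds <- which(pair$covered & abs(pair$delta) >= 0.05)
    if (length(seeds) == 0) next
    for (sd_ix in seeds[seq_len(min(3, length(seeds)))]) {
      r <- extend_dmr(pair, sd_ix, min_diff = 0.05, max_gap = 1000)
      o <- oracle_extend(pair, sd_ix, min_diff = 0.05, max_gap = 1000)
      expect_equal(r$n_cpg, o$n_cpg)
      expect_equal(r$start, o$start)
      expect_equal(r$end, o$end)
      expect_equal(r$mean_delta, o$mean_delta)
    }
  }
})

test_that("raising min_diff never grows a DMR, and members pass the audit", {
  for (s in 1:40) {
    pair <- random_wgbs_pair(n = 30, seed = 1000 + s)
    seeds <- which(pair$covered & abs(pair$delta) >= 0.10)
    if (length(seeds) == 0) next
    i <- seeds[1]
    prev <- Inf
    for (md in c(0.05, 0.10)) {
      r <- extend_dmr(pair, i, min_diff = md)
      expect_lte(r$n_cpg, prev)
      prev <- r$n_cpg
      # every member individually satisfies the membership predicate
      md_ok <- pair$delta[pair$pos %in% r$members] * sign(pair$delta[i])
      expect_true(all(md_ok >= md))
    }
  }
})

test_that("build_wgbs_pair joins tracks and applies the donor filter", {
  mono <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                     beta = c(0.1, 0.5, 0.9), n_donors = c(4L, 2L, 4L))
  mac <- data.frame(chrom = "chr1", pos = c(10L, 30L, 40L),
                    beta = c(0.3, 0.9, 0.2), n_donors = c(4L, 4L, 4L))
  pair <- build_wgbs_pair(mono, mac, min_donors = 3L)
  expect_equal(nrow(pair), 4)
  expect_equal(pair$covered, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(pair$delta[1], 0.2)
  cpgs <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(10L, 20L, 99L), strand = "+")
  mp <- map_dmc_to_wgbs(cpgs, pair)
  expect_equal(mp$reason, c("ok", "insufficient-donors", "no-wgbs-cpg"))
  expect_equal(mp$wgbs_delta[1], 0.2)
})

test_that("concordance enrichment reproduces the fold arithmetic", {
  mk_map <- function(n, n_conc) {
    data.frame(wgbs_delta = c(rep(0.1, n_conc), rep(0.01, n - n_conc)),
               reason = "ok", delta_beta = 0.2)
  }
  r <- concordance_enrichment(mk_map(1000, 480), mk_map(1000, 45))
  expect_equal(r$fold, (480 / 1000) / (45 / 1000))
  expect_equal(r$fold, 10.67, tolerance = 1e-3)
  expect_equal(r$p, oracle_fisher_p(480, 520, 45, 955))
  r1 <- concordance_enrichment(mk_map(100, 20), mk_map(100, 20))
  expect_equal(r1$fold, 1)
  # discordant direction does not count as concordant
  m <- data.frame(wgbs_delta = rep(-0.2, 10), reason = "ok",
                  delta_beta = rep(0.2, 10))
  r2 <- concordance_enrichment(m, mk_map(100, 5))
  expect_equal(r2$n_dmc_concordant, 0)
})

test_that("noise-free planted regions are recovered exactly", {
  cfg <- sim_config(n_cpgs = 150, n_gain_diff = 15, n_loss_diff = 15,
                    activation_counts = list(
                      mac_lps_ifng = c(gain = 0L, loss = 0L)),
                    n_mac_specific = 0L,
                    wgbs_noise_sd = 1e-9, wgbs_background_diff_rate = 0,
                    wgbs_coverage = 1, wgbs_dmc_concordance = 1,
                    seed = 77)
  s <- simulate_study(cfg)
  w <- simulate_wgbs(cfg, s)
  pair <- build_wgbs_pair(w$mono, w$mac)
  cm <- s$cpg_map
  dmcs <- data.frame(probe_id = s$truth$probe_id, chrom = "chr1",
                     pos = cm$pos[match(s$truth$probe_id, cm$probe_id)],
                     delta_beta = s$truth$true_delta)
  dm <- call_dmrs(dmcs, pair)
  expect_true(all(dm$covered & dm$concordant))
  tw <- w$truth_wgbs
  expect_equal(dm$dmr_n_cpg,
               tw$region_n_cpg[match(dm$probe_id, tw$probe_id)])
  expect_equal(dm$dmr_start,
               tw$region_start[match(dm$probe_id, tw$probe_id)])
})
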