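test_that("the generator is deterministic per seed", {
  cfg <- small_sim_config(seed = 99)
  a <- simulate_all(cfg)
  b <- simulate_all(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$truth, b$truth)
  expect_identical(a$wgbs$mono, b$wgbs$mono)
  expect_identical(a$annotation$genome, b$annotation$genome)
  c_ <- simulate_study(small_sim_config(seed = 100))
  expect_false(identical(a$beta, c_$beta))
})

test_that("the noise-free limit returns baselines plus planted effects exactly", {
  cfg <- sim_config(n_cpgs = 80, n_donors = 4, donor_sd = 0,
                    noise_sd = 0, n_gain_diff = 10, n_loss_diff = 10,
                    activation_counts = list(
                      mac_lps_ifng = c(gain = 2L, loss = 2L)),
                    n_mac_specific = 2L, seed = 5)
  s <- simulate_study(cfg)
  truth <- s$truth
  for (i in seq_len(nrow(truth))) {
    row <- s$beta[truth$probe_id[i], ]
    mu <- s$mu[truth$probe_id[i]]
    mono <- row[s$samples$cell_type == "monocyte"]
    expect_equal(unname(mono), rep(mu, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    if (truth$phase[i] == "differentiation") {
      mac <- row[s$samples$cell_type != "monocyte"]
      expect_equal(unname(mac), rep(mu + truth$true_delta[i], 20),
                   ignore_attr = TRUE)
    }
    if (truth$phase[i] == "macrophage-specific") {
      expect_equal(unname(row[s$samples$cell_type == "macrophage"]),
                   rep(mu + truth$true_delta[i], 4), ignore_attr = TRUE)
      expect_equal(unname(row[s$samples$cell_type == "mac_il4"]),
                   rep(mu, 4), ignore_attr = TRUE)
    }
  }
  # unplanted CpGs are flat across all samples
  flat <- setdiff(rownames(s$beta), truth$probe_id)[1:10]
  for (pid in flat) {
    expect_equal(unname(s$beta[pid, ]), rep(s$mu[pid], 24),
                 ignore_attr = TRUE)
  }
})

test_that("truth round-trip: noise-free DMC calls equal the planted set exactly", {
  cfg <- sim_config(n_cpgs = 300, n_donors = 4, donor_sd = 0, noise_sd = 0,
                    n_gain_diff = 25, n_loss_diff = 25,
                    activation_counts = list(
                      mac_lps_ifng = c(gain = 2L, loss = 3L)),
                    n_mac_specific = 2L, seed = 15)
  s <- simulate_study(cfg)
  scan <- ewas_scan(s$beta, s$samples)
  dmc <- call_dmcs(scan)
  called <- dmc$probe_id[dmc$is_dmc]
  expect_setequal(called, s$truth$probe_id)
  got <- dmc[match(s$truth$probe_id, dmc$probe_id), ]
  expect_equal(got$direction, s$truth$direction)
  expect_equal(got$phase, s$truth$phase)
})

test_that("planted effect categories are disjoint and direction-consistent", {
  s <- simulate_study(small_sim_config(seed = 3))
  expect_false(anyDuplicated(s$truth$probe_id) > 0)
  expect_equal(s$truth$direction, ifelse(s$truth$true_delta > 0,
                                         "gain", "loss"))
  expect_true(all(abs(s$truth$true_delta) <= 0.5))
  expect_true(all(s$beta >= 0 & s$beta <= 1))
})

test_that("WGBS coverage and expression rates match their configured values", {
  cfg <- sim_config(n_cpgs = 4000, n_gain_diff = 300, n_loss_diff = 200,
                    seed = 8)
  s <- simulate_study(cfg)
  w <- simulate_wgbs(cfg, s)
  pair <- build_wgbs_pair(w$mono, w$mac, min_donors = 3L)
  cm <- s$cpg_map
  mp <- map_dmc_to_wgbs(cm, pair)
  cov_rate <- mean(mp$reason == "ok")
  se <- sqrt(0.78 * 0.22 / nrow(cm))
  expect_lt(abs(cov_rate - cfg$wgbs_coverage), 4 * se)
  tw <- w$truth_wgbs
  expr_rate <- mean(tw$expressed)
  se2 <- sqrt(0.5 * 0.5 / nrow(tw))
  expect_lt(abs(expr_rate - cfg$wgbs_dmc_concordance), 4 * se2)
  # WGBS positions are strictly increasing and include all array CpGs
  expect_true(all(diff(w$mono$pos) > 0))
})

test_that("state concordance of 1 makes every donor track reproduce the consensus", {
  cfg <- small_sim_config(seed = 12, state_concordance = 1)
  s <- simulate_study(cfg)
  ann <- simulate_annotation_tracks(cfg, s)
  cons <- consensus_states(s$cpg_map, ann$state_tracks$monocyte,
                           min_votes = 5L)
  expect_equal(as.vector(cons), ann$consensus_states$state_mono)
})

test_that("all generated files parse back through the readers unchanged", {
  sim <- simulate_all(small_sim_config(seed = 33))
  d <- withr::local_tempdir()
  paths <- expect_no_warning(write_sim_inputs(sim, d))
  bm <- expect_no_warning(read_beta_matrix(paths$beta, paths$samplesheet))
  expect_equal(bm$beta, sim$beta, tolerance = 1e-12)
  expect_equal(bm$samples, sim$samples)
  cm <- expect_no_warning(read_cpg_map(paths$cpg_map))
  expect_equal(cm, sim$cpg_map)
  wm <- expect_no_warning(read_wgbs_track(paths$wgbs_mono,
                                          paths$wgbs_mono_donors))
  expect_equal(wm, sim$wgbs$mono, tolerance = 1e-12)
  st <- expect_no_warning(read_bed(paths$states_mono[1]))
  expect_equal(st, sim$annotation$state_tracks$monocyte[[1]])
  expect_no_warning(read_gene_models(paths$genes))
  expect_no_warning(read_expression(paths$expression))
  pw <- expect_no_warning(read_pwms(paths$pwms))
  expect_equal(names(pw), names(sim$annotation$pwms))
  g <- expect_no_warning(read_genome(paths$genome))
  expect_identical(g, sim$annotation$genome)
})

test_that("planted gain/loss CpGs sit at their configured state transitions", {
  cfg <- small_sim_config(seed = 44)
  s <- simulate_study(cfg)
  ann <- simulate_annotation_tracks(cfg, s)
  truth <- s$truth
  diff_gain <- truth$probe_id[truth$phase == "differentiation" &
                                truth$direction == "gain"]
  cs <- ann$consensus_states
  got <- cs[match(diff_gain, cs$probe_id), ]
  pairs <- paste(got$state_mono, got$state_mac, sep = "->")
  allowed <- paste(cfg$gain_transitions$mono, cfg$gain_transitions$mac,
                   sep = "->")
  expect_true(all(pairs %in% allowed))
  # infeasible-effect guard: no planted baseline leaves the clamp margin
  mu <- s$mu[truth$probe_id]
  expect_true(all(mu + truth$true_delta >= cfg$clamp_margin - 1e-9))
  expect_true(all(mu + truth$true_delta <= 1 - cfg$clamp_margin + 1e-9))
})
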