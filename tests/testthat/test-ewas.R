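test_that("noise-free additive design gives exact mean squares and degenerate residual", {
  y <- cbind(monocyte = rep(0.50, 4), macrophage = rep(0.60, 4))
  r <- fit_paired_anova(y)
  # SS_state = 4 * (0.05^2 + 0.05^2), df1 = 1
  expect_equal(r$ms, 0.02)
  expect_true(r$degenerate)
  expect_equal(r$f, Inf)
  expect_equal(r$p, 0)
})

test_that("a constant table is the exact null: ms = 0, p = 1", {
  y <- matrix(0.42, 4, 6, dimnames = list(NULL, default_states()))
  r <- fit_paired_anova(y)
  expect_equal(r$ms, 0)
  expect_equal(r$f, 0)
  expect_equal(r$p, 1)
  expect_equal(unname(r$partial_t), rep(0, 6))
})

test_that("random tables match the definitional sums-of-squares oracle", {
  set.seed(11)
  for (i in 1:50) {
    y <- matrix(runif(24), 4, 6)
    r <- fit_paired_anova(y)
    o <- oracle_anova(y)
    expect_equal(r$ms, o$ms, tolerance = 1e-10)
    expect_equal(r$f, o$f, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
    expect_equal(unname(r$partial_t), o$partial_t, tolerance = 1e-10)
    # state-mean deviations from the grand mean sum to zero exactly
    expect_equal(sum(r$state_means - r$grand_mean), 0, tolerance = 1e-12)
  }
})

test_that("input contracts are enforced", {
  expect_error(fit_paired_anova(matrix(runif(12), 2, 6)), ">= 3")
  y <- matrix(runif(24), 4, 6)
  y[2, 3] <- NA
  expect_error(fit_paired_anova(y), "complete")
})

test_that("ewas_scan equals per-CpG fits and handles missing donors", {
  set.seed(21)
  cfg <- sim_config(n_cpgs = 40, n_gain_diff = 5, n_loss_diff = 5,
                    activation_counts = list(
                      mac_lps_ifng = c(gain = 0L, loss = 0L)),
                    n_mac_specific = 0L, seed = 21)
  s <- simulate_study(cfg)
  beta <- s$beta
  # knock out one donor for some CpGs, two donors for one CpG
  idx <- which(s$samples$donor == "donor2" &
                 s$samples$cell_type == "mac_il4")
  beta[3, idx] <- NA
  beta[5, s$samples$donor %in% c("donor1", "donor3") &
         s$samples$cell_type == "monocyte"] <- NA
  scan <- ewas_scan(beta, s$samples)
  expect_equal(nrow(scan), 39)  # CpG 5 has only 2 complete donors
  expect_equal(attr(scan, "skipped")$probe_id, rownames(beta)[5])
  # row 3 must equal a 3-donor fit with donor2 dropped
  d_ok <- setdiff(paste0("donor", 1:4), "donor2")
  y <- sapply(default_states(), function(st) {
    beta[3, s$samples$sample_id[s$samples$donor %in% d_ok &
                                  s$samples$cell_type == st]]
  })
  r <- fit_paired_anova(y)
  row3 <- scan[scan$probe_id == rownames(beta)[3], ]
  expect_equal(row3$ms, r$ms)
  expect_equal(row3$f, r$f)
  expect_equal(row3$n_donors, 3)
  # a complete CpG equals the 4-donor fit
  y8 <- sapply(default_states(), function(st) {
    beta[8, s$samples$sample_id[s$samples$cell_type == st]]
  })
  r8 <- fit_paired_anova(y8)
  expect_equal(scan$f[scan$probe_id == rownames(beta)[8]], r8$f)
})

test_that("bh_fdr matches the hand step-up and the independent oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_identical(bh_fdr(p), oracle_bh(p))
  }
})

test_that("q-values never fall below their p-values", {
  set.seed(6)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
})

test_that("call_dmcs applies thresholds and attributes the right phase", {
  states <- default_states()
  mk <- function(q, ms, t, means) {
    scan <- data.frame(probe_id = "cg1", n_donors = 4, ms = ms, f = 50,
                       p = q / 2, q = q, degenerate = FALSE)
    scan[paste0("t_", states)] <- as.list(t)
    scan[paste0("mean_", states)] <- as.list(means)
    attr(scan, "states") <- states
    scan
  }
  # monocyte carries the largest |t|, macrophage-derived mean is higher
  x <- call_dmcs(mk(0.01, 0.004, c(-5, 1, 1, 1, 1, 1),
                    c(0.30, 0.42, 0.42, 0.42, 0.42, 0.42)))
  expect_true(x$is_dmc)
  expect_equal(x$phase, "differentiation")
  expect_equal(x$direction, "gain")
  expect_equal(x$delta_beta, 0.12)
  # over the FDR threshold: not a DMC regardless of effect size
  expect_false(call_dmcs(mk(0.20, 0.1, c(-5, 1, 1, 1, 1, 1),
                            c(0.3, 0.4, 0.4, 0.4, 0.4, 0.4)))$is_dmc)
  # under the ms cutoff: not a DMC
  expect_false(call_dmcs(mk(0.01, 0.002, c(-5, 1, 1, 1, 1, 1),
                            c(0.3, 0.4, 0.4, 0.4, 0.4, 0.4)))$is_dmc)
  # activated state dominating: activation phase, delta vs macrophage
  x <- call_dmcs(mk(0.01, 0.004, c(1, 1, -6, 1, 1, 1),
                    c(0.5, 0.5, 0.35, 0.5, 0.5, 0.5)))
  expect_equal(x$phase, "activation:mac_lps_ifng")
  expect_equal(x$direction, "loss")
  expect_equal(x$delta_beta, -0.15)
  # two states deviating at >= 0.9 of the max trigger the multi phase
  x <- call_dmcs(mk(0.01, 0.004, c(-5, -4.8, 1, 1, 1, 1),
                    c(0.30, 0.31, 0.45, 0.45, 0.45, 0.45)))
  expect_equal(x$phase, "multi")
  # exact tie resolved by fixed state order (monocyte first)
  x <- call_dmcs(mk(0.01, 0.004, c(-5, 5, 1, 1, 1, 1),
                    c(0.3, 0.5, 0.4, 0.4, 0.4, 0.4)))
  expect_equal(x$top_state, "monocyte")
  # switch flag: crossing 0.5 between monocyte and macrophage
  x <- call_dmcs(mk(0.01, 0.004, c(-5, 1, 1, 1, 1, 1),
                    c(0.40, 0.60, 0.60, 0.60, 0.60, 0.60)))
  expect_true(x$switch_flag)
})

test_that("effect_concordance matches the definitional formula", {
  x <- c(0.1, -0.2, 0.3, 0.05)
  expect_equal(effect_concordance(x, x)$r, 1)
  expect_equal(effect_concordance(x, -x)$r, -1)
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(20)
    b <- rnorm(20)
    r <- effect_concordance(a, b)
    manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(r$r, manual, tolerance = 1e-12)
    expect_equal(r$n, 20)
  }
  expect_equal(effect_concordance(rep(1, 5), rnorm(5))$flag, "zero-variance")
  expect_error(effect_concordance(c(1, NA, NA, NA), c(1, 2, 3, NA)), ">= 3")
})

test_that("increasing a planted effect never decreases F (common random numbers)", {
  # F(delta) is a quadratic-over-constant in the planted effect, so it is
  # monotone once the effect exceeds the noise-scale vertex (~noise/sqrt(n));
  # the grid starts above that scale
  set.seed(31)
  for (i in 1:10) {
    noise <- matrix(rnorm(24, 0, 0.03), 4, 6)
    donor <- rnorm(4, 0, 0.05)
    f_at <- function(delta) {
      y <- 0.4 + donor + noise
      y[, 2:6] <- y[, 2:6] + delta
      fit_paired_anova(y)$f
    }
    fs <- vapply(seq(0.05, 0.35, by = 0.02), f_at, 0)
    expect_true(all(diff(fs) >= 0))
  }
})
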