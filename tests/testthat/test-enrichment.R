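test_that("fisher_2x2 handles independence, enrichment and the cap", {
  r <- fisher_2x2(10, 10, 10, 10)
  expect_equal(r$or, 1)
  expect_equal(r$p, 1)
  r <- fisher_2x2(8, 2, 2, 8)
  expect_equal(r$or, 16)
  expect_equal(r$p, oracle_fisher_p(8, 2, 2, 8))
  expect_equal(r$p, 0.023, tolerance = 2e-3)
  # an extreme table hits the representable floor
  r <- fisher_2x2(100, 0, 0, 100)
  expect_lt(r$p, 2.2e-16)
  expect_equal(r$p_capped, 2.2e-16)
  expect_equal(r$flag, "or-infinite")
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
  expect_equal(fisher_2x2(0, 5, 0, 5)$flag, "or-undefined")
})

test_that("odds ratios transform correctly under table symmetries", {
  set.seed(3)
  for (i in 1:20) {
    x <- sample(0:30, 4, replace = TRUE)
    if (sum(x) == 0) next
    r <- fisher_2x2(x[1], x[2], x[3], x[4])
    swapped <- fisher_2x2(x[3], x[4], x[1], x[2])  # swap rows
    both <- fisher_2x2(x[4], x[3], x[2], x[1])     # swap rows and columns
    expect_equal(both$or, r$or)
    if (is.finite(r$or) && r$or > 0) {
      expect_equal(swapped$or, 1 / r$or)
    }
    # p is invariant under any margin-preserving relabelling
    expect_equal(swapped$p, r$p, tolerance = 1e-12)
  }
})

test_that("feature_enrichment builds the right tables per stratum", {
  feat <- setNames(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                   paste0("cg", 1:6))
  r <- feature_enrichment(c("cg1", "cg2", "cg3"), c("cg4", "cg5", "cg6"),
                          feature = feat)
  expect_equal(r[, c("a", "b", "c", "d")],
               data.frame(a = 2L, b = 1L, c = 1L, d = 2L))
  # complete separation: infinite OR, flagged
  strat <- setNames(rep(c("enh", "quies"), each = 3), paste0("cg", 1:6))
  r <- feature_enrichment(c("cg1", "cg2", "cg3"), c("cg4", "cg5", "cg6"),
                          strata = strat)
  enh <- r[r$stratum == "enh", ]
  expect_equal(enh$or, Inf)
  expect_equal(enh$flag, "or-infinite")
  expect_true(all(r$q >= r$p))
})

test_that("transition_matrix reproduces direct 2x2 arithmetic", {
  gain <- paste0("g", 1:10)
  loss <- paste0("l", 1:10)
  sm <- setNames(c(rep("quiescent", 8), rep("enhancer", 2),
                   rep("quiescent", 2), rep("enhancer", 8)), c(gain, loss))
  sc <- sm  # stay in the same state
  r <- transition_matrix(gain, loss, sm, sc)
  qq <- r[r$state_mono == "quiescent" & r$state_mac == "quiescent", ]
  expect_equal(qq$or, 16)  # (8*8)/(2*2)
  expect_equal(qq$p, oracle_fisher_p(8, 2, 2, 8))
  ee <- r[r$state_mono == "enhancer" & r$state_mac == "enhancer", ]
  expect_equal(ee$or, 1 / 16)
  # identical gain/loss distributions: every defined OR is 1
  r0 <- transition_matrix(gain, loss,
                          setNames(rep(c("a", "b"), 10), c(gain, loss)),
                          setNames(rep(c("a", "b"), 10), c(gain, loss)))
  expect_true(all(r0$or == 1))
  # no-calls are excluded and counted
  sm2 <- sm
  sm2[1] <- "no-call"
  r2 <- transition_matrix(gain, loss, sm2, sc)
  expect_equal(attr(r2, "n_nocall"), 1L)
})

test_that("tf_binding_gain counts binding-gain events at the CpG position", {
  cpgs <- data.frame(probe_id = paste0("cg", 1:6), chrom = "chr1",
                     pos = c(100L, 200L, 300L, 400L, 500L, 600L),
                     strand = "+")
  mac <- data.frame(chrom = "chr1", start = c(95L, 195L, 395L),
                    end = c(105L, 205L, 405L), label = "tf")
  mono <- data.frame(chrom = "chr1", start = 395L, end = 405L, label = "tf")
  db <- setNames(c(0.2, 0.3, 0.1, 0.25, 0.05, 0.1), cpgs$probe_id)
  r <- tf_binding_gain(c("cg1", "cg2", "cg3"), c("cg4", "cg5", "cg6"),
                       cpgs, mono, mac, db, motif = "CEBP_like")
  # cg1, cg2 gain binding; cg4 has a constitutive peak, cg5/cg6 none
  expect_equal(unname(unlist(r[, c("a", "b", "c", "d")])), c(2, 1, 0, 3))
  expect_equal(r$mean_delta_beta, mean(c(0.2, 0.3, 0.1)))
  expect_error(tf_binding_gain(character(), character(), cpgs, mono, mac,
                               db, motif = "X"), "X")
  # identical tracks: no binding gain anywhere, flagged
  r0 <- tf_binding_gain(c("cg1", "cg2"), c("cg5", "cg6"), cpgs, mac, mac,
                        db)
  expect_equal(r0$flag, "no-binding-gain")
})

test_that("signed-rank test: exact cases, zeros, and the normal approximation", {
  expect_equal(signed_rank_test(rep(0, 8))$p, 1)
  r <- signed_rank_test(c(0.4, 0.8, 1.5, 2.2, 3.1, 5.0))
  expect_equal(r$p, 2 / 64)  # all six differences positive
  expect_equal(r$method, "exact")
  set.seed(41)
  for (i in 1:10) {
    d <- round(rnorm(sample(4:10, 1)), 6)
    d <- d[d != 0]
    r <- signed_rank_test(d)
    expect_equal(r$p, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # exact and approximate p agree reasonably at n = 30
  set.seed(43)
  for (i in 1:5) {
    d <- rnorm(30, 0.1)
    p_apx <- signed_rank_test(d, exact_max = 25)$p
    p_ex <- signed_rank_test(d, exact_max = 30)$p
    expect_lt(abs(p_apx - p_ex), 0.01)
  }
})

test_that("expression_shift recovers planted directional shifts", {
  set.seed(47)
  genes <- sprintf("g%02d", 1:40)
  expr <- data.frame(gene = genes, monocyte = rnorm(40, 5, 1))
  shift <- c(rep(1, 15), rep(-1, 15), rep(0, 10))
  expr$macrophage <- expr$monocyte + shift + rnorm(40, 0, 0.2)
  r <- expression_shift(list(loss = genes[1:15], gain = genes[16:30]),
                        expr)
  expect_equal(r$direction, c("up", "down"))
  expect_true(all(r$p < 0.01))
  expect_error(expression_shift(list(x = genes[1:3]), expr), "fewer than")
})
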