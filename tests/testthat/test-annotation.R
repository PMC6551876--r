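test_that("majority_call follows the at-least-k-of-n rule", {
  expect_equal(as.vector(majority_call(c("E4", "E4", "E4", "E7", "E2"), 3)),
               "E4")
  expect_true(is.na(majority_call(c("E4", "E4", "E7", "E7", "E2"), 3)))
  # 26 donors, 13 with a peak, threshold 13: called
  labs <- rep(c("peak", NA), c(13, 13))
  expect_equal(as.vector(majority_call(labs, 13)), "peak")
  expect_true(is.na(majority_call(rep(c("peak", NA), c(12, 14)), 13)))
  # low thresholds can be ambiguous: two labels reach 2 votes
  amb <- majority_call(c("A", "A", "B", "B"), 2)
  expect_true(is.na(amb))
  expect_true(attr(amb, "ambiguous"))
  expect_error(majority_call(character(), 1), ">= 1")
})

test_that("majority_call is permutation-invariant and monotone in min_votes", {
  set.seed(13)
  for (i in 1:25) {
    labs <- sample(c("a", "b", "c", NA), 7, replace = TRUE)
    v <- sample(4:6, 1)
    r1 <- as.vector(majority_call(labs, v))
    r2 <- as.vector(majority_call(sample(labs), v))
    expect_identical(r1, r2)
    # raising min_votes never converts no-call into a call
    r_hi <- as.vector(majority_call(labs, v + 1))
    if (is.na(r1)) expect_true(is.na(r_hi))
  }
})

test_that("nearest_gene uses TSS/TES point distances with documented tie-break", {
  genes <- data.frame(gene = c("A", "B"), chrom = "chr1",
                      tss = c(1000L, 5000L), tes = c(2000L, 7000L),
                      strand = c("+", "+"))
  cp <- function(pos) data.frame(probe_id = "cg1", chrom = "chr1",
                                 pos = pos, strand = "+")
  r <- nearest_gene(cp(2600L), genes)
  expect_equal(r$nearest_gene, "A")
  expect_equal(r$gene_distance, 600)
  r <- nearest_gene(cp(1000L), genes)
  expect_equal(r$gene_distance, 0)
  # 3500 is equidistant between A.tes (2000) and B.tss (5000); the TSS wins
  r <- nearest_gene(cp(3500L), genes)
  expect_equal(r$nearest_gene, "B")
  expect_equal(r$gene_distance, 1500)
  expect_equal(attr(r, "n_ties"), 1L)
  # empty chromosome: no-call with a warning
  expect_warning(
    r <- nearest_gene(data.frame(probe_id = "cg2", chrom = "chrX",
                                 pos = 5L, strand = "+"), genes),
    "no genes")
  expect_true(is.na(r$nearest_gene))
})

test_that("nearest_gene matches brute force and ignores gene-list order", {
  set.seed(17)
  for (i in 1:10) {
    ng <- sample(3:12, 1)
    a <- sample(1:20000, ng)
    genes <- data.frame(gene = sprintf("g%02d", sample(ng)), chrom = "chr1",
                        tss = a, tes = a + sample(100:3000, ng, TRUE),
                        strand = sample(c("+", "-"), ng, TRUE))
    cpgs <- data.frame(probe_id = sprintf("cg%d", 1:30), chrom = "chr1",
                       pos = sample(1:25000, 30), strand = "+")
    r <- nearest_gene(cpgs, genes)
    r2 <- nearest_gene(cpgs, genes[sample(ng), , drop = FALSE])
    expect_equal(r$nearest_gene, r2$nearest_gene)
    for (j in seq_len(nrow(cpgs))) {
      o <- oracle_nearest_gene(cpgs$pos[j], "chr1", genes)
      expect_equal(r$gene_distance[j], o$d)
      expect_equal(r$nearest_gene[j], o$gene)
    }
  }
})

test_that("point labels agree with the quadratic all-pairs oracle", {
  set.seed(19)
  for (i in 1:5) {
    n <- 40
    start <- sample(0:3000, n)
    trk <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = start, end = start + sample(1:400, n, TRUE),
                      label = sample(letters[1:5], n, TRUE))
    chrom <- sample(c("chr1", "chr2"), 200, TRUE)
    pos <- sample(1:3500, 200, TRUE)
    expect_equal(label_at(trk, chrom, pos),
                 oracle_point_labels(trk, chrom, pos))
  }
})

test_that("annotate_cpgs windows and point overlaps behave at boundaries", {
  cpgs <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 1000L,
                     strand = "+")
  mk_state <- function(lab) list(
    data.frame(chrom = "chr1", start = 900L, end = 1100L, label = lab))
  tracks <- list(monocyte = mk_state("active_enhancer"),
                 macrophage = mk_state("quiescent"))
  dhs <- list(monocyte = list(data.frame(chrom = "chr1", start = 0L,
                                         end = 1L, label = "1")),
              macrophage = list(data.frame(chrom = "chr1", start = 950L,
                                           end = 1050L, label = "1")))
  hic <- list(monocyte = data.frame(chrom = character(), start = integer(),
                                    end = integer(), label = character()),
              macrophage = data.frame(chrom = "chr1", start = 0L,
                                      end = 5000L, label = "enhancer"))
  genes <- data.frame(gene = "G", chrom = "chr1", tss = 1L, tes = 2L,
                      strand = "+")
  # motif 30 bp away: outside a 25 bp window, inside a 50 bp window
  sites <- data.frame(chrom = "chr1", start = 1029L, end = 1037L,
                      label = "CEBP_like")
  a25 <- annotate_cpgs(cpgs, tracks, dhs, hic, sites, genes,
                       state_min_votes = 1L,
                       dhs_min_votes = c(monocyte = 1L, macrophage = 1L),
                       window_halfwidth = 25L)
  expect_equal(a25$state_mono, "active_enhancer")
  expect_equal(a25$state_mac, "quiescent")
  expect_false(a25$dhs_mono)
  expect_true(a25$dhs_mac)
  expect_false(a25$enhancer_hic_mono)
  expect_true(a25$enhancer_hic_mac)
  expect_equal(a25$motif_hits, "")
  a50 <- annotate_cpgs(cpgs, tracks, dhs, hic, sites, genes,
                       state_min_votes = 1L,
                       dhs_min_votes = c(monocyte = 1L, macrophage = 1L),
                       window_halfwidth = 50L)
  expect_equal(a50$motif_hits, "CEBP_like")
})

test_that("consensus annotation equals the brute-force overlap oracle on random tracks", {
  set.seed(23)
  n_cpg <- 120
  cpgs <- data.frame(probe_id = sprintf("cg%03d", 1:n_cpg), chrom = "chr1",
                     pos = sort(sample(1:50000, n_cpg)), strand = "+")
  donors <- lapply(1:5, function(d) {
    start <- sort(sample(seq(0, 49000, by = 1000), 30))
    data.frame(chrom = "chr1", start = start,
               end = start + sample(200:900, 30, TRUE),
               label = sample(default_state_names(), 30, TRUE))
  })
  cons <- consensus_states(cpgs, donors, min_votes = 3L)
  manual <- vapply(seq_len(n_cpg), function(i) {
    labs <- vapply(donors, function(trk) {
      oracle_point_labels(trk, "chr1", cpgs$pos[i])
    }, "")
    tab <- table(labs[!is.na(labs)])
    win <- names(tab)[tab >= 3]
    if (length(win) == 1) win else NA_character_
  }, "")
  expect_equal(as.vector(cons), manual)
})

test_that("consensus_peaks applies the per-cell-type vote threshold", {
  cpgs <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                     pos = c(100L, 500L), strand = "+")
  peak_at <- function(pos) data.frame(chrom = "chr1", start = pos - 10L,
                                      end = pos + 10L, label = "1")
  trks <- list(peak_at(100L), peak_at(100L),
               peak_at(500L), peak_at(100L))
  expect_equal(consensus_peaks(cpgs, trks, 2L), c(TRUE, FALSE))
  expect_equal(consensus_peaks(cpgs, trks, 3L), c(TRUE, FALSE))
  expect_equal(consensus_peaks(cpgs, trks, 4L), c(FALSE, FALSE))
})
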