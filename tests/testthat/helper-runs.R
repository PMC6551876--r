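# Shared fixtures built in code. The ten default-study pipeline runs are
# computed lazily once and reused by the end-to-end tests.

.run_cache <- new.env(parent = emptyenv())

default_study_runs <- function(seeds = 1:10) {
  key <- paste0("runs_", paste(seeds, collapse = "_"))
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- lapply(seeds, function(s) {
      run_pipeline(pipeline_config(seed = s))
    })
  }
  .run_cache[[key]]
}

# A reduced study used by unit tests where full scale is unnecessary.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_cpgs = 600L, n_gain_diff = 90L, n_loss_diff = 60L,
             activation_counts = list(
               mac_lps_ifng = c(gain = 1L, loss = 4L),
               mac_il4 = c(gain = 0L, loss = 1L),
               mac_oxldl = c(gain = 0L, loss = 1L),
               mac_acldl = c(gain = 0L, loss = 0L)),
             n_mac_specific = 2L, seed = seed, ...)
}

random_wgbs_pair <- function(n = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- cumsum(sample(c(5:80, 1500), n, replace = TRUE))
  data.frame(chrom = "chr1", pos = pos,
             beta_mono = runif(n), beta_mac = runif(n),
             n_mono = 4L, n_mac = 4L,
             delta = round(runif(n, -0.4, 0.4), 2),
             covered = runif(n) > 0.1)
}
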