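#' Majority call across donors
#'
#' Returns the unique label receiving at least `min_votes` votes, else
#' `NA` (no-call). With `min_votes <= n/2` two labels can reach the
#' threshold; that ambiguity is also a no-call (flagged via
#' `attr(, "ambiguous")`). Permutation-invariant in donor order.
#'
#' @param labels Character vector, one label per donor (`NA` = donor has no
#'   call at this position and contributes no vote).
#' @param min_votes Minimum votes for a call.
#' @return Length-1 character (the winning label) or `NA_character_`.
#' @export
majority_call <- function(labels, min_votes) {
  if (length(labels) == 0L) stop("majority_call requires >= 1 donor label")
  tab <- table(labels[!is.na(labels)])
  winners <- names(tab)[tab >= min_votes]
  out <- if (length(winners) == 1L) winners else NA_character_
  attr(out, "ambiguous") <- length(winners) > 1L
  out
}

#' Consensus labels at CpG positions across donor tracks
#'
#' Per CpG position, looks up each donor's interval label and applies
#' [majority_call()].
#'
#' @param cpgs CpG map data.frame (`chrom`, `pos` 1-based).
#' @param donor_tracks list of per-donor interval data.frames
#'   (`chrom`, `start`, `end`, `label`).
#' @param min_votes Votes required for a consensus call.
#' @return Character vector of consensus labels (`NA` = no-call), with a
#'   `votes` attribute (matrix donors x CpGs of observed labels).
#' @export
consensus_states <- function(cpgs, donor_tracks, min_votes) {
  votes <- vapply(donor_tracks, function(trk) {
    label_at(trk, cpgs$chrom, cpgs$pos)
  }, character(nrow(cpgs)))
  votes <- matrix(votes, nrow = nrow(cpgs))
  out <- apply(votes, 1L, function(z) as.vector(majority_call(z, min_votes)))
  attr(out, "votes") <- t(votes)
  out
}

#' Consensus binary peak calls at CpG positions
#'
#' A peak is called where at least `min_votes` donor tracks contain the
#' position.
#'
#' @inheritParams consensus_states
#' @return Logical vector, one per CpG.
#' @export
consensus_peaks <- function(cpgs, donor_tracks, min_votes) {
  hits <- vapply(donor_tracks, function(trk) {
    point_in_track(trk, cpgs$chrom, cpgs$pos)
  }, logical(nrow(cpgs)))
  hits <- matrix(hits, nrow = nrow(cpgs))
  rowSums(hits) >= min_votes
}

#' Nearest gene by TSS/TES point distance
#'
#' Distance is the minimum over all genes' transcription start and end sites
#' of `|pos - site|` on the CpG's chromosome. Ties between genes are broken
#' by the smaller distance to a TSS, then lexicographic gene name; tie
#' counts are reported in `attr(, "n_ties")`.
#'
#' @param cpgs CpG map data.frame (`probe_id`, `chrom`, `pos`).
#' @param genes Gene models (`gene`, `chrom`, `tss`, `tes`).
#' @return data.frame `probe_id`, `nearest_gene` (`NA` if the chromosome has
#'   no genes), `gene_distance`.
#' @export
nearest_gene <- function(cpgs, genes) {
  out <- data.frame(probe_id = cpgs$probe_id,
                    nearest_gene = NA_character_,
                    gene_distance = NA_real_,
                    stringsAsFactors = FALSE)
  n_ties <- 0L
  for (ch in unique(cpgs$chrom)) {
    gi <- genes[genes$chrom == ch, , drop = FALSE]
    qi <- which(cpgs$chrom == ch)
    if (nrow(gi) == 0L) {
      warning("no genes on chromosome ", ch, "; nearest gene is a no-call")
      next
    }
    sites <- data.frame(gene = rep(gi$gene, 2L),
                        pos = c(gi$tss, gi$tes),
                        is_tss = rep(c(TRUE, FALSE), each = nrow(gi)),
                        stringsAsFactors = FALSE)
    ord <- order(sites$pos)
    sites <- sites[ord, , drop = FALSE]
    sp <- sites$pos
    L <- length(sp)
    # nearest sorted neighbours suffice for the minimum distance
    j <- findInterval(cpgs$pos[qi], sp)
    d_left <- ifelse(j >= 1L, cpgs$pos[qi] - sp[pmax(j, 1L)], Inf)
    d_right <- ifelse(j < L, sp[pmin(j + 1L, L)] - cpgs$pos[qi], Inf)
    dmin <- pmin(d_left, d_right)
    for (ii in seq_along(qi)) {
      i <- qi[ii]
      p <- cpgs$pos[i]
      k <- if (d_left[ii] <= d_right[ii]) j[ii] else j[ii] + 1L
      # fast path: unique nearest site without equal-coordinate duplicates
      unique_side <- d_left[ii] != d_right[ii]
      no_dup <- (k == 1L || sp[k - 1L] != sp[k]) &&
        (k == L || sp[k + 1L] != sp[k])
      if (unique_side && no_dup) {
        out$nearest_gene[i] <- sites$gene[k]
        out$gene_distance[i] <- dmin[ii]
        next
      }
      cand <- sites[sp == p - dmin[ii] | sp == p + dmin[ii], , drop = FALSE]
      if (nrow(cand) > 1L && length(unique(cand$gene)) > 1L) {
        n_ties <- n_ties + 1L
        # prefer a TSS hit, then lexicographic gene name
        cand <- cand[order(!cand$is_tss, cand$gene), , drop = FALSE]
      }
      out$nearest_gene[i] <- cand$gene[1L]
      out$gene_distance[i] <- dmin[ii]
    }
  }
  attr(out, "n_ties") <- n_ties
  out
}

#' Annotate CpGs with consensus regulatory features
#'
#' One row per CpG: consensus chromatin state per cell type, consensus
#' DNaseI hypersensitivity, Hi-C enhancer overlap, motif sites within a
#' window, and nearest gene. State/DHS/enhancer overlaps are evaluated at
#' the cytosine position; motif hits over
#' `[pos - window_halfwidth, pos + window_halfwidth]`.
#'
#' @param cpgs CpG map (`probe_id`, `chrom`, `pos`).
#' @param state_tracks list with elements `monocyte` and `macrophage`, each
#'   a list of per-donor state interval tracks.
#' @param dhs_tracks Same shape for DNaseI peak tracks.
#' @param hic list with `monocyte`/`macrophage` enhancer interval tracks.
#' @param motif_sites Interval track of motif sites (label = motif name).
#' @param genes Gene models.
#' @param state_min_votes Votes for the state consensus (default 3).
#' @param dhs_min_votes Named votes for DHS consensus,
#'   `c(monocyte = , macrophage = )`.
#' @param window_halfwidth Motif window half-width in bp (default 25).
#' @return data.frame keyed by `probe_id` with columns `state_mono`,
#'   `state_mac` (label or `"no-call"`), `dhs_mono`, `dhs_mac`,
#'   `enhancer_hic_mono`, `enhancer_hic_mac`, `motif_hits`
#'   (comma-collapsed), `nearest_gene`, `gene_distance`.
#' @export
annotate_cpgs <- function(cpgs, state_tracks, dhs_tracks, hic, motif_sites,
                          genes, state_min_votes = 3L,
                          dhs_min_votes = c(monocyte = 3L, macrophage = 2L),
                          window_halfwidth = 25L) {
  st_mono <- consensus_states(cpgs, state_tracks$monocyte, state_min_votes)
  st_mac <- consensus_states(cpgs, state_tracks$macrophage, state_min_votes)
  dhs_mono <- consensus_peaks(cpgs, dhs_tracks$monocyte,
                              dhs_min_votes[["monocyte"]])
  dhs_mac <- consensus_peaks(cpgs, dhs_tracks$macrophage,
                             dhs_min_votes[["macrophage"]])
  hic_mono <- point_in_track(hic$monocyte, cpgs$chrom, cpgs$pos)
  hic_mac <- point_in_track(hic$macrophage, cpgs$chrom, cpgs$pos)
  hits <- labels_in_window(motif_sites, cpgs$chrom, cpgs$pos,
                           halfwidth = window_halfwidth)
  ng <- nearest_gene(cpgs, genes)
  data.frame(
    probe_id = cpgs$probe_id,
    state_mono = ifelse(is.na(st_mono), "no-call", as.vector(st_mono)),
    state_mac = ifelse(is.na(st_mac), "no-call", as.vector(st_mac)),
    dhs_mono = dhs_mono, dhs_mac = dhs_mac,
    enhancer_hic_mono = hic_mono, enhancer_hic_mac = hic_mac,
    motif_hits = vapply(hits, paste, "", collapse = ","),
    nearest_gene = ng$nearest_gene,
    gene_distance = ng$gene_distance,
    stringsAsFactors = FALSE)
}
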