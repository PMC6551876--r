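#' Label interval tracks carry 0-based half-open coordinates; CpG positions
#' are 1-based. All point queries funnel through this one conversion.
#'
#' @param track data.frame with `chrom`, `start`, `end` and optionally
#'   `label` (0-based half-open).
#' @param chrom,pos Parallel vectors of query chromosome and 1-based position.
#' @return Character vector of labels at each position (`NA` where no
#'   interval covers the point; the first covering interval in track order
#'   wins if several do).
#' @export
label_at <- function(track, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_character_, length(pos))
  if (nrow(track) == 0L || length(pos) == 0L) return(out)
  lab <- if ("label" %in% names(track)) track$label else rep("1", nrow(track))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0L) next
    # 0-based half-open [start, end) -> 1-based closed [start + 1, end]
    q <- IRanges::IRanges(start = pos[qi], width = 1L)
    s <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    hits <- IRanges::findOverlaps(q, s, select = "first")
    found <- !is.na(hits)
    out[qi[found]] <- lab[ti[hits[found]]]
  }
  out
}

#' Test whether points fall inside any interval of a track
#'
#' @inheritParams label_at
#' @return Logical vector, one per query point.
#' @export
point_in_track <- function(track, chrom, pos) {
  !is.na(label_at(track, chrom, pos))
}

#' Find intervals overlapping windows around points
#'
#' Used for motif-site lookup: returns, per query point, the labels of all
#' intervals overlapping the window `[pos - halfwidth, pos + halfwidth]`
#' (1-based closed on the genome).
#'
#' @inheritParams label_at
#' @param halfwidth Window half-width in bp.
#' @return list of character vectors (unique labels per point).
#' @export
labels_in_window <- function(track, chrom, pos, halfwidth = 25L) {
  out <- rep(list(character()), length(pos))
  if (nrow(track) == 0L || length(pos) == 0L) return(out)
  lab <- if ("label" %in% names(track)) track$label else rep("1", nrow(track))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0L) next
    q <- IRanges::IRanges(start = pmax(1L, pos[qi] - halfwidth),
                          end = pos[qi] + halfwidth)
    s <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (j in unique(qh)) {
      out[[qi[j]]] <- unique(c(out[[qi[j]]], lab[ti[sh[qh == j]]]))
    }
  }
  out
}
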