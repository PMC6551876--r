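#' Read a BED3/BED4 interval file
#'
#' Parses tab-separated intervals using the BED convention (0-based half-open
#' coordinates). Column 4, when present, becomes the interval label; otherwise
#' the label defaults to `"1"` (binary peak flag). Input order is preserved.
#'
#' @param path Path to a BED file with at least three tab-separated columns.
#' @return A data.frame with columns `chrom`, `start` (0-based inclusive),
#'   `end` (0-based exclusive) and `label`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("BED parse error at line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(end <= start | start < 0L)
  if (length(bad) > 0L) {
    stop("BED parse error at line ", bad[1L],
         ": requires 0 <= start < end, got [", start[bad[1L]], ", ",
         end[bad[1L]], ")")
  }
  label <- ifelse(nf >= 4L, vapply(fields, function(f) {
    if (length(f) >= 4L) f[[4L]] else "1"
  }, ""), "1")
  data.frame(chrom = chrom, start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED4
#'
#' @param x A data.frame with columns `chrom`, `start`, `end` and optionally
#'   `label` (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  label <- if ("label" %in% names(x)) x$label else rep("1", nrow(x))
  out <- data.frame(x$chrom, x$start, x$end, label)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph methylation track
#'
#' Four tab-separated columns: chrom, start (0-based), end, value in `[0, 1]`
#' (mean methylation fraction). A companion donor-count sidecar (same rows,
#' single integer column) may accompany the track; see [read_wgbs_track()].
#'
#' @param path Path to a bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 4L) stop("bedGraph requires 4 columns: ", path)
  names(x)[1:4] <- c("chrom", "start", "end", "value")
  if (any(!is.finite(x$value)) || any(x$value < 0) || any(x$value > 1)) {
    stop("bedGraph values must lie in [0, 1]: ", path)
  }
  x[, 1:4]
}

#' Read a per-cell-type WGBS CpG track
#'
#' The track is a bedGraph of single-CpG mean beta values plus a sidecar TSV
#' of per-CpG donor counts (column `n_donors`). CpG position is taken as the
#' 1-based cytosine position, i.e. `start + 1`.
#'
#' @param path bedGraph path.
#' @param donor_path Optional sidecar TSV with one `n_donors` column aligned
#'   row-by-row with the bedGraph; when absent all donor counts are set to
#'   `default_donors`.
#' @param default_donors Donor count assumed without a sidecar.
#' @return data.frame with `chrom`, `pos` (1-based), `beta`, `n_donors`,
#'   sorted by chromosome then position.
#' @export
read_wgbs_track <- function(path, donor_path = NULL, default_donors = 4L) {
  bg <- read_bedgraph(path)
  out <- data.frame(chrom = bg$chrom, pos = bg$start + 1L, beta = bg$value,
                    stringsAsFactors = FALSE)
  if (!is.null(donor_path)) {
    dc <- read.delim(donor_path, stringsAsFactors = FALSE)
    if (nrow(dc) != nrow(out)) {
      stop("donor-count sidecar row count does not match track: ", donor_path)
    }
    out$n_donors <- as.integer(dc$n_donors)
  } else {
    out$n_donors <- as.integer(default_donors)
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  if (any(duplicated(paste(out$chrom, out$pos)))) {
    stop("WGBS track has duplicated CpG positions: ", path)
  }
  rownames(out) <- NULL
  out
}

#' Write a WGBS track as bedGraph (+ donor-count sidecar)
#'
#' @param x data.frame as returned by [read_wgbs_track()].
#' @param path bedGraph output path.
#' @param donor_path Optional sidecar output path.
#' @return `path`, invisibly.
#' @export
write_wgbs_track <- function(x, path, donor_path = NULL) {
  bg <- data.frame(x$chrom, x$pos - 1L, x$pos, x$beta)
  write.table(bg, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(donor_path)) {
    write.table(data.frame(n_donors = x$n_donors), donor_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a beta-value matrix and its sample sheet
#'
#' The matrix TSV has probe identifiers in the first column (`probe_id`) and
#' one column per sample; the sample sheet TSV has columns `sample_id`,
#' `donor`, `cell_type`, `sex`. Matrix columns must match the sample sheet
#' exactly (same set). Values must be in `[0, 1]` or missing (`NA`).
#'
#' @param path Beta matrix TSV path.
#' @param samplesheet Sample sheet TSV path.
#' @return list with `beta` (numeric matrix, probes x samples, columns in
#'   sample-sheet order) and `samples` (data.frame).
#' @export
read_beta_matrix <- function(path, samplesheet) {
  mat <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(mat)[1L] != "probe_id") {
    stop("beta matrix must have 'probe_id' as its first column")
  }
  if (anyDuplicated(mat$probe_id)) stop("duplicated probe_id in beta matrix")
  sheet <- read.delim(samplesheet, stringsAsFactors = FALSE)
  req <- c("sample_id", "donor", "cell_type", "sex")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  beta <- as.matrix(mat[, -1L, drop = FALSE])
  rownames(beta) <- mat$probe_id
  only_mat <- setdiff(colnames(beta), sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, colnames(beta))
  if (length(only_mat) || length(only_sheet)) {
    stop("beta matrix / sample sheet mismatch; matrix-only: [",
         paste(only_mat, collapse = ", "), "] sheet-only: [",
         paste(only_sheet, collapse = ", "), "]")
  }
  beta <- beta[, sheet$sample_id, drop = FALSE]
  storage.mode(beta) <- "double"
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad) > 0L) {
    stop("beta values outside [0, 1]: ", length(bad), " cells, first at row ",
         row(beta)[bad[1L]], " column ", col(beta)[bad[1L]])
  }
  list(beta = beta, samples = sheet)
}

#' Write a beta-value matrix and sample sheet
#'
#' @param x list with `beta` and `samples` as from [read_beta_matrix()].
#' @param path Beta matrix TSV path.
#' @param samplesheet Sample sheet TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, samplesheet) {
  out <- data.frame(probe_id = rownames(x$beta), x$beta,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, samplesheet, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a CpG position map
#'
#' TSV with columns `probe_id`, `chrom`, `pos` (1-based cytosine position)
#' and optionally `strand`.
#'
#' @param path TSV path.
#' @return data.frame with unique `probe_id`, `chrom`, `pos`, `strand`.
#' @export
read_cpg_map <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "chrom", "pos") %in% names(x))) {
    stop("CpG map requires columns probe_id, chrom, pos")
  }
  if (anyDuplicated(x$probe_id)) stop("duplicated probe_id in CpG map")
  if (any(x$pos < 1L)) stop("CpG positions must be >= 1 (1-based)")
  if (is.null(x$strand)) x$strand <- "*"
  x[, c("probe_id", "chrom", "pos", "strand")]
}

#' Read gene models
#'
#' TSV with columns `gene`, `chrom`, `tss`, `tes` (1-based), `strand`.
#'
#' @param path TSV path.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "tss", "tes", "strand")
  if (!all(req %in% names(x))) {
    stop("gene models require columns: ", paste(req, collapse = ", "))
  }
  if (any(x$tss == x$tes)) stop("gene model with tss == tes")
  if (!all(x$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  x[, req]
}

#' Read a gene expression table
#'
#' TSV with a `gene` column and one logTPM column per cell type
#' (e.g. `monocyte`, `macrophage`).
#'
#' @param path TSV path.
#' @return data.frame keyed by `gene`.
#' @export
read_expression <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(x)) stop("expression table requires a 'gene' column")
  if (anyDuplicated(x$gene)) stop("duplicated gene in expression table")
  x
}

#' Read JASPAR-style plain-text PWM files
#'
#' Each record is a `>name` header followed by four whitespace-separated rows
#' of per-position counts or probabilities in A, C, G, T order (optionally
#' prefixed with the base letter and brackets as in JASPAR pfm format).
#'
#' @param path PWM file path (may contain several records).
#' @param pseudocount Pseudocount passed to [new_pwm()].
#' @return list of PWM objects (see [new_pwm()]).
#' @export
read_pwms <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no PWM records ('>' headers) in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  pwms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(name, "\\s+")[[1L]][1L]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L) {
      stop("PWM record '", name, "' must have exactly 4 rows (A, C, G, T)")
    }
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*\\[", "", ln)
      ln <- gsub("\\]\\s*$", "", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("PWM record '", name, "' has ragged rows")
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    # normalize counts to per-position probabilities
    mat <- sweep(mat, 2L, colSums(mat), "/")
    pwms[[i]] <- new_pwm(name, mat, pseudocount = pseudocount)
  }
  names(pwms) <- vapply(pwms, function(p) p$name, "")
  pwms
}

#' Write PWMs in JASPAR-style plain text
#'
#' @param pwms list of PWM objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ",
                        paste(formatC(p$probs[b, ], format = "f", digits = 6),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Minimal single-purpose reader for the synthetic genome: plain FASTA,
#' one or more records, sequence uppercased.
#'
#' @param path FASTA path.
#' @return Named list of chromosome sequences (character strings).
#' @export
read_genome <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no FASTA records in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- lapply(seq_along(starts), function(i) {
    toupper(paste(lines[(starts[i] + 1L):ends[i]], collapse = ""))
  })
  names(out) <- sub("^>\\s*(\\S+).*$", "\\1", lines[starts])
  out
}

#' Write a genome as FASTA
#'
#' @param genome Named list of chromosome sequences.
#' @param path Output path.
#' @param width Line width (default 80).
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(genome)) {
    writeLines(paste0(">", ch), con)
    s <- genome[[ch]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Write a generic TSV result table
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
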