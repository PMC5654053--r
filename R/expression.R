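# Promoter annotation, TMM/TPM normalization and expression filters.

#' Per-position stranded CAGE TSS counts
#'
#' The atomic CAGE signal: for every genomic position with at least one tag,
#' a stranded position record and one count per sample.
#'
#' @param positions data.frame(chrom, pos, strand) with 0-based positions
#'   and strand "+" or "-".
#' @param counts integer matrix, `nrow(positions)` x samples, with sample
#'   ids as column names.
#' @return A `tss_counts` object.
#' @export
tss_counts <- function(positions, counts) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(positions)),
            nrow(positions) == nrow(counts))
  if (!all(positions$strand %in% c("+", "-")))
    stop("TSS strand must be + or -")
  if (any(counts < 0)) stop("negative counts")
  if (is.null(colnames(counts))) stop("counts must have sample id columns")
  key <- paste(positions$chrom, positions$strand, positions$pos)
  if (anyDuplicated(key)) stop("duplicate TSS positions")
  structure(list(positions = positions, counts = counts),
            class = "tss_counts")
}

#' @export
print.tss_counts <- function(x, ...) {
  cat(sprintf("tss_counts: %d positions x %d samples (%.0f tags)\n",
              nrow(x$positions), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Stranded CAGE tag-cluster peaks with per-sample counts
#'
#' @param peaks data.frame(id, chrom, start, end, strand, summit); summit
#'   must lie in `[start, end)` and strand must be "+" or "-".
#' @param counts matrix of per-sample tag counts, rownames = peak ids.
#' @return A `cage_peaks` object.
#' @export
cage_peaks <- function(peaks, counts) {
  stopifnot(all(c("id", "chrom", "start", "end", "strand", "summit") %in%
                  names(peaks)))
  if (anyDuplicated(peaks$id)) stop("duplicate peak ids")
  if (!all(peaks$strand %in% c("+", "-")))
    stop("CAGE peak strand must be + or -")
  if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end))
    stop("summit outside [start, end)")
  if (!identical(rownames(counts), peaks$id))
    counts <- counts[peaks$id, , drop = FALSE]
  structure(list(peaks = peaks, counts = counts), class = "cage_peaks")
}

#' @export
print.cage_peaks <- function(x, ...) {
  cat(sprintf("cage_peaks: %d peaks (%d +, %d -) x %d samples\n",
              nrow(x$peaks), sum(x$peaks$strand == "+"),
              sum(x$peaks$strand == "-"), ncol(x$counts)))
  invisible(x)
}

#' Sum TSS-level counts into CAGE peak counts
#'
#' Each TSS position is assigned to the (at most one) same-strand peak whose
#' interval contains it; member counts are summed per sample. Positions
#' outside every peak are ignored with a message.
#'
#' @param tc a [tss_counts()] object.
#' @param peaks peak data.frame (id, chrom, start, end, strand) with
#'   non-overlapping intervals per chromosome and strand.
#' @return matrix of peak counts (rownames = peak id), in peak order.
#' @export
sum_tss_to_peaks <- function(tc, peaks) {
  out <- matrix(0, nrow = nrow(peaks), ncol = ncol(tc$counts),
                dimnames = list(peaks$id, colnames(tc$counts)))
  pos <- tc$positions
  assigned <- logical(nrow(pos))
  for (grp in split(seq_len(nrow(peaks)),
                    paste(peaks$chrom, peaks$strand))) {
    pk <- peaks[grp, , drop = FALSE]
    pk <- pk[order(pk$start), , drop = FALSE]
    sel <- which(pos$chrom == pk$chrom[1] & pos$strand == pk$strand[1])
    if (!length(sel)) next
    idx <- findInterval(pos$pos[sel], pk$start)
    inside <- idx >= 1L & pos$pos[sel] < pk$end[pmax(idx, 1L)]
    assigned[sel[inside]] <- TRUE
    if (!any(inside)) next
    sums <- rowsum(tc$counts[sel[inside], , drop = FALSE],
                   group = pk$id[idx[inside]], reorder = FALSE)
    out[rownames(sums), ] <- out[rownames(sums), , drop = FALSE] + sums
  }
  if (!all(assigned))
    message(sum(!assigned), " TSS positions outside any peak; ignored")
  out
}

#' Assign CAGE peaks to protein-coding transcript promoters
#'
#' A peak is assigned to a transcript when its strand-aware 5' end lies
#' within `window` bp of the transcript TSS on the same strand. Gene-level
#' assignments are the union over the gene's transcripts.
#'
#' @param peaks peak data.frame (id, chrom, start, end, strand).
#' @param gm [gene_models()] object; only protein-coding genes are used.
#' @param window promoter window in bp (default 500).
#' @return data.frame(peak_id, transcript_id, gene_id), one row per
#'   peak-transcript assignment.
#' @export
assign_promoters <- function(peaks, gm, window = 500L) {
  stopifnot(window > 0)
  tx <- protein_coding(gm)$transcripts
  p5 <- ifelse(peaks$strand == "+", peaks$start, peaks$end - 1L)
  out <- vector("list", 0L)
  for (grp in split(seq_len(nrow(tx)), paste(tx$chrom, tx$strand))) {
    t1 <- tx[grp, , drop = FALSE]
    sel <- which(peaks$chrom == t1$chrom[1] & peaks$strand == t1$strand[1])
    if (!length(sel)) next
    dd <- abs(outer(p5[sel], t1$tss, "-"))
    hit <- which(dd <= window, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      peak_id = peaks$id[sel][hit[, 1L]],
      transcript_id = t1$transcript_id[hit[, 2L]],
      gene_id = t1$gene_id[hit[, 2L]],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peak_id = character(), transcript_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$peak_id, res$transcript_id), , drop = FALSE]
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample scale factors computed by the TMM method (trim 30% of
#' M-value and 5% of A-value tails, precision-weighted mean of retained
#' M-values, reference sample chosen by upper-quartile closeness), rescaled
#' so their geometric mean is 1. Computation is delegated to
#' edgeR::calcNormFactors.
#'
#' @param counts raw count matrix (features x samples).
#' @return named numeric vector of positive factors, one per sample.
#' @export
tmm_factors <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize <= 0))
    stop("sample with all-zero counts: ",
         colnames(counts)[which(libsize <= 0)[1]])
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Convert raw counts to tags per million (TPM)
#'
#' `tpm[f, s] = counts[f, s] / (library_size[s] * factor[s]) * 1e6`. CAGE
#' tags are single points, so there is no feature-length normalization.
#'
#' @param counts raw count matrix.
#' @param factors normalization factors (default: all 1); typically from
#'   [tmm_factors()].
#' @return TPM matrix of the same shape.
#' @export
to_tpm <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  stopifnot(all(factors > 0), length(factors) == ncol(counts))
  eff <- colSums(counts) * factors
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Filter features by minimum expression in a sample subset
#'
#' Keeps features with at least `min_tpm` TPM in at least
#' `ceiling(frac * n)` of the `n` subset samples.
#'
#' @param tpm TPM matrix with feature rownames.
#' @param sample_ids subset of column names (e.g. macrophage samples).
#' @param min_tpm expression threshold (default 1 TPM).
#' @param frac required fraction of subset samples (default 0.10).
#' @return character vector of retained feature ids.
#' @export
filter_expressed <- function(tpm, sample_ids, min_tpm = 1, frac = 0.10) {
  stopifnot(length(sample_ids) > 0, all(sample_ids %in% colnames(tpm)))
  need <- ceiling(frac * length(sample_ids))
  n_ok <- rowSums(tpm[, sample_ids, drop = FALSE] >= min_tpm)
  rownames(tpm)[n_ok >= need]
}

#' Gene-level expression from promoter-level expression
#'
#' Gene expression is the per-sample sum over the gene's assigned promoter
#' peaks; a promoter shared by several genes contributes to each. Genes
#' without assigned promoters are absent from the result.
#'
#' @param tpm promoter-level expression matrix (rownames = peak ids).
#' @param assignments data.frame from [assign_promoters()].
#' @return gene-level matrix (rownames = gene ids).
#' @export
gene_expression <- function(tpm, assignments) {
  pg <- unique(assignments[c("peak_id", "gene_id")])
  pg <- pg[pg$peak_id %in% rownames(tpm), , drop = FALSE]
  if (!nrow(pg)) stop("no assignments reference the expression matrix")
  rowsum(tpm[pg$peak_id, , drop = FALSE], group = pg$gene_id)
}

#' Read a feature x sample count table (TSV, first column = feature id)
#' @param path TSV path.
#' @return numeric matrix with feature rownames.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("negative values in count table")
  m
}

#' Write a feature x sample matrix as TSV
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name of the feature id column.
#' @export
write_count_table <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
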