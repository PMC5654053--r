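# Enhancer-promoter-gene interactome: TAD containment, Spearman
# correlation across samples, BH FDR and link selection.

#' Candidate enhancer-promoter pairs within TADs
#'
#' Emits every (enhancer, promoter peak) pair where both features are
#' entirely contained in the same TAD. The genomic distance is measured
#' from the enhancer midpoint to the promoter peak's strand-aware 5' end.
#'
#' @param enhancers enhancer data.frame (id, chrom, start, end, midpoint).
#' @param promoters promoter peak data.frame (id, chrom, start, end,
#'   strand).
#' @param tads TAD data.frame (chrom, start, end, id).
#' @return data.frame(enhancer_id, promoter_id, tad_id, distance).
#' @export
tad_pairs <- function(enhancers, promoters, tads) {
  tg <- as_gr(tads, FALSE)
  eh <- GenomicRanges::findOverlaps(as_gr(enhancers, FALSE), tg,
                                    type = "within")
  ph <- GenomicRanges::findOverlaps(as_gr(promoters, FALSE), tg,
                                    type = "within")
  edf <- data.frame(ei = S4Vectors::queryHits(eh),
                    ti = S4Vectors::subjectHits(eh))
  pdf <- data.frame(pi = S4Vectors::queryHits(ph),
                    ti = S4Vectors::subjectHits(ph))
  m <- merge(edf, pdf, by = "ti")
  if (!nrow(m))
    return(data.frame(enhancer_id = character(), promoter_id = character(),
                      tad_id = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  p5 <- ifelse(promoters$strand == "+", promoters$start,
               promoters$end - 1L)
  out <- data.frame(
    enhancer_id = enhancers$id[m$ei],
    promoter_id = promoters$id[m$pi],
    tad_id = tads$id[m$ti],
    distance = abs(enhancers$midpoint[m$ei] - p5[m$pi]),
    stringsAsFactors = FALSE)
  out <- out[order(out$enhancer_id, out$promoter_id, out$tad_id), ]
  rownames(out) <- NULL
  out
}

#' Spearman correlation with t-approximation p-value
#'
#' Rho is computed on average ranks (ties get mean ranks); the two-sided
#' p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list(rho, p_value).
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Spearman correlation for many feature pairs
#'
#' Vectorized helper for [tad_pairs()] output: correlates enhancer eRNA and
#' promoter expression rows across the given samples. Pairs with a constant
#' vector are dropped with a message.
#'
#' @param pairs data.frame with enhancer_id and promoter_id columns.
#' @param enh_mat,prom_mat expression matrices (TPM) with feature rownames.
#' @param sample_ids samples over which to correlate.
#' @return `pairs` with added rho and p_value columns (constant pairs
#'   removed).
#' @export
pair_spearman <- function(pairs, enh_mat, prom_mat, sample_ids) {
  stopifnot(length(sample_ids) >= 3)
  ex <- enh_mat[pairs$enhancer_id, sample_ids, drop = FALSE]
  px <- prom_mat[pairs$promoter_id, sample_ids, drop = FALSE]
  const <- apply(ex, 1L, stats::sd) == 0 | apply(px, 1L, stats::sd) == 0
  if (any(const))
    message(sum(const), " pairs with constant expression dropped")
  pairs <- pairs[!const, , drop = FALSE]
  ex <- ex[!const, , drop = FALSE]
  px <- px[!const, , drop = FALSE]
  n <- length(sample_ids)
  # row-wise Pearson on ranks
  rex <- t(apply(ex, 1L, rank))
  rpx <- t(apply(px, 1L, rank))
  rex <- rex - rowMeans(rex)
  rpx <- rpx - rowMeans(rpx)
  rho <- rowSums(rex * rpx) /
    sqrt(rowSums(rex^2) * rowSums(rpx^2))
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- ifelse(abs(rho) >= 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2))
  pairs$rho <- as.numeric(rho)
  pairs$p_value <- as.numeric(p)
  rownames(pairs) <- NULL
  pairs
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment; input order is preserved.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Select significant positively correlated links
#'
#' BH q-values are computed jointly over all supplied pairs; links are kept
#' when `rho > 0` (if `require_positive`) and `q < fdr_threshold`.
#'
#' @param pairs data.frame from [pair_spearman()] (rho, p_value present).
#' @param fdr_threshold FDR cutoff (default 1e-4).
#' @param require_positive keep only positive correlations (default TRUE).
#' @return `pairs` subset with added q_value column.
#' @export
select_links <- function(pairs, fdr_threshold = 1e-4,
                         require_positive = TRUE) {
  pairs$q_value <- bh_fdr(pairs$p_value)
  keep <- pairs$q_value < fdr_threshold
  if (require_positive) keep <- keep & pairs$rho > 0
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map promoter-level links to genes and summarize per gene
#'
#' An enhancer regulates a gene when it is linked to at least one of the
#' gene's promoters; duplicated (enhancer, gene) pairs are collapsed.
#' Genes in `expressed_genes` without any link are reported with
#' `n_enhancers = 0`.
#'
#' @param links selected links (enhancer_id, promoter_id, ...).
#' @param assignments promoter-gene map from [assign_promoters()].
#' @param expressed_genes optional vector of gene ids passing expression
#'   filters.
#' @return list(gene_links = data.frame(enhancer_id, gene_id),
#'   summary = data.frame(gene_id, n_enhancers)).
#' @export
map_to_genes <- function(links, assignments, expressed_genes = NULL) {
  pg <- unique(assignments[c("peak_id", "gene_id")])
  m <- merge(links, pg, by.x = "promoter_id", by.y = "peak_id")
  gl <- unique(m[c("enhancer_id", "gene_id")])
  gl <- gl[order(gl$gene_id, gl$enhancer_id), , drop = FALSE]
  rownames(gl) <- NULL
  counts <- table(gl$gene_id)
  genes <- union(names(counts), expressed_genes)
  summary <- data.frame(
    gene_id = genes,
    n_enhancers = as.integer(ifelse(genes %in% names(counts),
                                    counts[genes], 0L)),
    stringsAsFactors = FALSE)
  summary <- summary[order(summary$gene_id), , drop = FALSE]
  rownames(summary) <- NULL
  list(gene_links = gl, summary = summary)
}

#' Compare enhancer-promoter distance distributions
#'
#' Medians of two distance sets plus a two-sided Wilcoxon rank-sum test.
#'
#' @param d1 distances of the first link set (e.g. selected links).
#' @param d2 optional distances of a comparison set (e.g. all TAD pairs).
#' @return list(median1, median2, p_value) — the latter two NULL/NA when
#'   `d2` is absent.
#' @export
distance_stats <- function(d1, d2 = NULL) {
  out <- list(median1 = stats::median(d1), median2 = NULL, p_value = NA_real_)
  if (!is.null(d2)) {
    out$median2 <- stats::median(d2)
    # distances are tied integers; use the normal approximation throughout
    out$p_value <- stats::wilcox.test(d1, d2, exact = FALSE)$p.value
  }
  out
}
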