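# Enhancer calling from divergent CAGE tag clusters.
#
# Gene-proximal peaks are masked first, then minus/plus peak pairs in
# divergent orientation within a short gap are turned into fixed-width
# candidate loci; balanced bidirectional candidates survive a
# directionality filter and overlapping survivors are resolved by pooled
# tag support.

#' Cluster TSS positions into CAGE peaks by single linkage
#'
#' Same-strand positions closer than or equal to `max_gap` are merged into
#' one peak. The summit is the member position with the highest pooled
#' (sample-summed) count, leftmost on ties. A distance-based stand-in for
#' profile-decomposition peak callers: adequate for well-separated clusters.
#'
#' @param tc [tss_counts()] object.
#' @param max_gap maximum within-peak gap in bp (default 20).
#' @return [cage_peaks()] object.
#' @export
cluster_tss <- function(tc, max_gap = 20L) {
  stopifnot(max_gap >= 0)
  pos <- tc$positions
  pooled <- rowSums(tc$counts)
  rows <- list()
  members <- list()
  for (sel in split(seq_len(nrow(pos)), paste(pos$chrom, pos$strand))) {
    sel <- sel[order(pos$pos[sel])]
    p <- pos$pos[sel]
    brk <- cumsum(c(0L, as.integer(diff(p) > max_gap)))
    for (cl in split(seq_along(sel), brk)) {
      i <- sel[cl]
      sm <- p[cl][which.max(pooled[i])]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pos$chrom[i[1]], start = min(p[cl]), end = max(p[cl]) + 1L,
        strand = pos$strand[i[1]], summit = sm, stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- i
    }
  }
  pk <- do.call(rbind, rows)
  pk$id <- sprintf("peak_%s_%s_%d", pk$chrom,
                   ifelse(pk$strand == "+", "p", "m"), pk$summit)
  o <- order(pk$chrom, pk$start, pk$strand)
  pk <- pk[o, c("id", "chrom", "start", "end", "strand", "summit")]
  rownames(pk) <- NULL
  counts <- sum_tss_to_peaks(tc, pk)
  cage_peaks(pk, counts)
}

#' Mask gene-proximal CAGE peaks
#'
#' Removes peaks lying within `tss_window` bp of any protein-coding
#' transcript TSS or within `exon_window` bp of any exon
#' (strand-agnostic; distance 0 for overlap).
#'
#' @param cp [cage_peaks()] object.
#' @param gm gene models; only protein-coding genes are used.
#' @param tss_window TSS exclusion window in bp (default 500).
#' @param exon_window exon exclusion window in bp (default 200).
#' @return filtered [cage_peaks()] object.
#' @export
mask_peaks <- function(cp, gm, tss_window = 500L, exon_window = 200L) {
  stopifnot(tss_window > 0, exon_window > 0)
  pc <- protein_coding(gm)
  pk <- cp$peaks
  tss_iv <- data.frame(chrom = pc$transcripts$chrom,
                       start = pc$transcripts$tss,
                       end = pc$transcripts$tss + 1L)
  d_tss <- nearest_feature_distance(pk, tss_iv)
  d_ex <- nearest_feature_distance(pk, pc$exons)
  keep <- d_tss > tss_window & d_ex > exon_window
  cage_peaks(pk[keep, , drop = FALSE], cp$counts[keep, , drop = FALSE])
}

# Candidate enhancer loci from all divergent (minus, plus) summit pairs on
# one chromosome. Shared by the caller below; the test suite re-derives the
# same quantities with an independent brute-force enumeration.
divergent_candidates <- function(pk, pooled, gap, halfwidth) {
  out <- list()
  for (chrom in unique(pk$chrom)) {
    mi <- which(pk$chrom == chrom & pk$strand == "-")
    pi <- which(pk$chrom == chrom & pk$strand == "+")
    if (!length(mi) || !length(pi)) next
    mi <- mi[order(pk$summit[mi])]
    pi <- pi[order(pk$summit[pi])]
    sm <- pk$summit[mi]; sp <- pk$summit[pi]
    pm <- pooled[mi]; pp <- pooled[pi]
    cum_m <- cumsum(pm); cum_p <- cumsum(pp)
    for (i in seq_along(mi)) {
      lo <- findInterval(sm[i], sp) + 1L          # first plus summit > sm
      hi <- findInterval(sm[i] + gap, sp)         # last plus summit <= sm+gap
      if (lo > hi) next
      for (j in lo:hi) {
        mid <- (sm[i] + sp[j]) %/% 2L
        start <- mid - halfwidth
        end <- mid + halfwidth + 1L
        # plus tags with summit in [mid, end); minus tags with summit in
        # [start, mid)
        p_tags <- sum_in_range(sp, cum_p, mid, end)
        m_tags <- sum_in_range(sm, cum_m, start, mid)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = start, end = end, midpoint = mid,
          minus_peak_id = pk$id[mi[i]], plus_peak_id = pk$id[pi[j]],
          plus_tags = p_tags, minus_tags = m_tags,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# total of `weights` for sorted positions in [lo, hi), via cumulative sums
sum_in_range <- function(sorted_pos, cum_w, lo, hi) {
  a <- findInterval(lo - 1L, sorted_pos)
  b <- findInterval(hi - 1L, sorted_pos)
  if (b <= a) return(0)
  cum_w[b] - if (a >= 1L) cum_w[a] else 0
}

#' Call bidirectional enhancer candidates from masked CAGE peaks
#'
#' Every (minus, plus) summit pair in divergent orientation (minus summit
#' left of plus summit) separated by at most `gap` bp yields a candidate
#' locus of width `2*halfwidth + 1` centred on the floored summit midpoint.
#' The pooled directionality score `D = (P - M) / (P + M)` uses plus-strand
#' peak tags with summits in the right half-window and minus-strand tags in
#' the left half-window; candidates with `|D| >= dmax` or no flanking tags
#' are discarded. Overlapping survivors are resolved by keeping the one
#' with the largest pooled support (ties: leftmost).
#'
#' @param cp masked [cage_peaks()] object.
#' @param gap maximum summit separation in bp (default 400).
#' @param halfwidth enhancer half-width in bp (default 200; 401-nt loci).
#' @param dmax directionality cutoff (default 0.8).
#' @return data.frame of enhancer regions: id, chrom, start, end, midpoint,
#'   minus_peak_id, plus_peak_id, directionality, pooled_tags.
#' @export
call_bidirectional <- function(cp, gap = 400L, halfwidth = 200L,
                               dmax = 0.8) {
  pk <- cp$peaks
  pooled <- stats::setNames(rowSums(cp$counts), pk$id)
  cand <- divergent_candidates(pk, pooled[pk$id], gap, halfwidth)
  empty <- data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      midpoint = integer(), minus_peak_id = character(),
                      plus_peak_id = character(), directionality = numeric(),
                      pooled_tags = numeric(), stringsAsFactors = FALSE)
  if (is.null(cand)) return(empty)
  tot <- cand$plus_tags + cand$minus_tags
  n_zero <- sum(tot == 0)
  if (n_zero > 0L)
    message(n_zero, " candidate loci without flanking tags; discarded")
  cand$directionality <- ifelse(tot > 0,
                                (cand$plus_tags - cand$minus_tags) / tot, NA)
  cand$pooled_tags <- tot
  cand <- cand[tot > 0 & abs(cand$directionality) < dmax, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # greedy resolution: strongest first, drop candidates overlapping a keeper
  o <- order(-cand$pooled_tags, cand$chrom, cand$midpoint,
             cand$minus_peak_id, cand$plus_peak_id)
  cand <- cand[o, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prior <- which(keep & cand$chrom == cand$chrom[i])
    keep[i] <- !any(cand$start[prior] < cand$end[i] &
                      cand$start[i] < cand$end[prior])
  }
  res <- cand[keep, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$id <- sprintf("enh_%s_%d_%d", res$chrom, res$start, res$end)
  rownames(res) <- NULL
  res[c("id", "chrom", "start", "end", "midpoint", "minus_peak_id",
        "plus_peak_id", "directionality", "pooled_tags")]
}

#' Quantify eRNA expression of enhancer regions
#'
#' Per sample: minus-strand tags in the left half-window
#' `[start, midpoint)` plus plus-strand tags in the right half-window
#' `[midpoint, end)` — the divergent configuration only.
#'
#' @param enhancers enhancer data.frame from [call_bidirectional()].
#' @param tc [tss_counts()] object.
#' @return matrix of eRNA counts (rownames = enhancer ids).
#' @export
quantify_ernas <- function(enhancers, tc) {
  pos <- tc$positions
  out <- matrix(0, nrow = nrow(enhancers), ncol = ncol(tc$counts),
                dimnames = list(enhancers$id, colnames(tc$counts)))
  for (chrom in unique(enhancers$chrom)) {
    ei <- which(enhancers$chrom == chrom)
    for (str in c("-", "+")) {
      sel <- which(pos$chrom == chrom & pos$strand == str)
      if (!length(sel)) next
      p <- pos$pos[sel]
      lo <- if (str == "-") enhancers$start[ei] else enhancers$midpoint[ei]
      hi <- if (str == "-") enhancers$midpoint[ei] else enhancers$end[ei]
      for (k in seq_along(ei)) {
        inw <- sel[p >= lo[k] & p < hi[k]]
        if (length(inw))
          out[ei[k], ] <- out[ei[k], ] +
            colSums(tc$counts[inw, , drop = FALSE])
      }
    }
  }
  out
}

#' Flag enhancers transcribed in a sample group
#'
#' An enhancer is transcribed when its eRNA count is nonzero in at least
#' `ceiling(frac * n)` of the `n` group samples.
#'
#' @param counts eRNA count matrix (rownames = enhancer ids).
#' @param sample_ids group sample ids (e.g. macrophage samples).
#' @param frac required fraction (default 0.10).
#' @return named logical vector per enhancer.
#' @export
flag_transcribed <- function(counts, sample_ids, frac = 0.10) {
  stopifnot(length(sample_ids) > 0, all(sample_ids %in% colnames(counts)))
  need <- ceiling(frac * length(sample_ids))
  n_nonzero <- rowSums(counts[, sample_ids, drop = FALSE] > 0)
  n_nonzero >= need
}

#' Flag enhancers supported by chromatin-state intervals
#'
#' An enhancer is chip-supported when it overlaps (>= `min_bp` bp) any
#' chromatin-state enhancer interval; its state is "active" if any
#' overlapped interval is active (H3K4me1 + H3K27ac), otherwise "poised"
#' (H3K4me1 only), or "none" without support.
#'
#' @param enhancers enhancer data.frame.
#' @param chip data.frame(chrom, start, end, state) with states
#'   "active"/"poised" (see [read_chip_bed()]).
#' @param min_bp minimum overlap (default 1).
#' @return data.frame(id, chip_supported, chip_state).
#' @export
chip_filter <- function(enhancers, chip, min_bp = 1L) {
  stopifnot(all(chip$state %in% c("active", "poised")))
  state <- rep("none", nrow(enhancers))
  if (nrow(chip)) {
    hits <- GenomicRanges::findOverlaps(as_gr(enhancers, FALSE),
                                        as_gr(chip, FALSE),
                                        minoverlap = min_bp)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    active <- tapply(chip$state[si] == "active", qi, any)
    idx <- as.integer(names(active))
    state[idx] <- ifelse(active, "active", "poised")
  }
  data.frame(id = enhancers$id, chip_supported = state != "none",
             chip_state = state, stringsAsFactors = FALSE)
}
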