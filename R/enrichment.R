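# Gene-set over-representation (hypergeometric) and TFBS enrichment by
# Monte-Carlo resampling against matched genomic backgrounds.

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member gene ids,
#'   tab-separated).
#' @return named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- read_tab_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("line %d: GMT line needs name, description and >= 1 gene",
                 short[1]))
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}

#' Write a GMT gene-set collection (internal; used by the simulator)
#' @keywords internal
#' @noRd
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail probability of observing the same or larger overlap between
#' the query set and each term, given the universe; BH correction across
#' all terms of the collection. Query and term sets are intersected with
#' the universe before testing.
#'
#' @param query character vector of query gene ids.
#' @param sets named list of term gene id vectors.
#' @param universe character vector of background gene ids.
#' @return data.frame(term, k_overlap, n_query, K_term, N_universe, p, q).
#' @export
hypergeom_test <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) < length(unique(query)))
    stop("universe smaller than query set")
  query <- intersect(unique(query), universe)
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(sets), function(nm) {
    term <- intersect(unique(sets[[nm]]), universe)
    K <- length(term)
    k <- length(intersect(query, term))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k_overlap = k, n_query = n, K_term = K,
               N_universe = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Fraction of query regions containing at least one TFBS summit
#'
#' Point-in-interval with half-open semantics: a summit at the region start
#' counts, one at the region end coordinate does not.
#'
#' @param regions interval data.frame (chrom, start, end).
#' @param summits data.frame(chrom, pos) of summit positions (pre-filtered
#'   by q-value).
#' @return observed fraction in `[0, 1]`.
#' @export
tfbs_overlap_stat <- function(regions, summits) {
  if (!nrow(regions)) stop("empty query region set")
  count_region_hits(regions, summits) / nrow(regions)
}

# number of query regions containing >= 1 summit
count_region_hits <- function(regions, summits) {
  hit <- 0L
  for (chrom in unique(regions$chrom)) {
    ri <- regions$chrom == chrom
    s <- sort(summits$pos[summits$chrom == chrom])
    if (!length(s)) next
    n_in <- findInterval(regions$end[ri] - 1L, s) -
      findInterval(regions$start[ri] - 1L, s)
    hit <- hit + sum(n_in >= 1L)
  }
  hit
}

#' Build a width-matched background-region sampler
#'
#' Precomputes, per TAD, the allowed space (the TAD minus every exclusion
#' interval) and returns a sampler function `f(widths)` drawing one region
#' per requested width, uniformly over all legal start positions such that
#' the region lies entirely inside a TAD and intersects no exclusion.
#'
#' @param tads TAD data.frame.
#' @param exclusions interval data.frame of excluded regions (gaps,
#'   repeats, coding regions, called enhancers; may be empty).
#' @return function(widths) -> interval data.frame.
#' @export
make_region_sampler <- function(tads, exclusions = NULL) {
  pieces <- list()
  for (i in seq_len(nrow(tads))) {
    tad <- IRanges::IRanges(tads$start[i] + 1L, tads$end[i])
    excl <- if (is.null(exclusions) || !nrow(exclusions)) IRanges::IRanges()
    else {
      ei <- exclusions$chrom == tads$chrom[i]
      IRanges::IRanges(exclusions$start[ei] + 1L, exclusions$end[ei])
    }
    free <- IRanges::setdiff(tad, IRanges::reduce(excl))
    if (length(free))
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = tads$chrom[i],
        start = IRanges::start(free) - 1L,
        end = IRanges::end(free),
        stringsAsFactors = FALSE)
  }
  pieces <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(), start = integer(), end = integer())
  plen <- pieces$end - pieces$start
  function(widths) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    starts <- integer(length(widths))
    chroms <- character(length(widths))
    for (k in seq_along(widths)) {
      w <- widths[k]
      slots <- pmax(0L, plen - w + 1L)
      total <- sum(slots)
      if (total == 0L)
        stop("no legal placement for a region of width ", w)
      u <- sample.int(total, 1L)
      pi <- findInterval(u - 1L, cumsum(slots), left.open = FALSE) + 1L
      off <- u - c(0L, cumsum(slots))[pi] - 1L
      chroms[k] <- pieces$chrom[pi]
      starts[k] <- pieces$start[pi] + off
    }
    data.frame(chrom = chroms, start = starts, end = starts + widths,
               stringsAsFactors = FALSE)
  }
}

#' Sample width-matched background regions within TADs
#'
#' Convenience wrapper over [make_region_sampler()]: draws `n` regions with
#' the given widths (recycled to length `n`), reproducibly under `seed`.
#'
#' @param n number of regions.
#' @param widths region widths (matched one-to-one to the query's widths).
#' @param tads TAD data.frame.
#' @param exclusions excluded interval data.frame.
#' @param seed optional integer seed.
#' @return interval data.frame with `n` rows.
#' @export
sample_background_regions <- function(n, widths, tads, exclusions = NULL,
                                      seed = NULL) {
  sampler <- make_region_sampler(tads, exclusions)
  with_local_seed(seed, sampler(rep_len(widths, n)))
}

#' Empirical Monte-Carlo p-value for TFBS over-representation
#'
#' Each trial draws `nrow(query)` regions from the background — without
#' replacement from a region pool, or freshly sampled when `background` is
#' a sampler function — and recomputes the overlap fraction. The
#' plus-one estimator `p = (1 + #(trial >= observed)) / (trials + 1)`
#' never returns zero.
#'
#' @param query query region data.frame.
#' @param summits summit data.frame(chrom, pos).
#' @param background a region data.frame (pool) or a `function(widths)`
#'   sampler as from [make_region_sampler()].
#' @param trials number of Monte-Carlo trials (default 1000).
#' @param seed optional integer seed.
#' @return list(observed_frac, p_value, trials).
#' @export
monte_carlo_p <- function(query, summits, background, trials = 1000L,
                          seed = NULL) {
  observed <- tfbs_overlap_stat(query, summits)
  nq <- nrow(query)
  widths <- query$end - query$start
  stat <- with_local_seed(seed, {
    vapply(seq_len(trials), function(t) {
      regions <- if (is.function(background)) background(widths)
      else {
        if (nrow(background) < nq)
          stop("background pool smaller than query set")
        background[sample.int(nrow(background), nq), , drop = FALSE]
      }
      tfbs_overlap_stat(regions, summits)
    }, numeric(1))
  })
  list(observed_frac = observed,
       p_value = (1 + sum(stat >= observed)) / (trials + 1),
       trials = trials)
}

#' Retain TFs significant against all backgrounds and expressed
#'
#' A TF is retained when its empirical p-value is below `alpha` for every
#' background and its expression is nonzero.
#'
#' @param p_table data.frame with a `tf` column and one p-value column per
#'   background.
#' @param tf_expression named vector of TF expression (TPM) by TF name.
#' @param alpha significance cutoff (default 0.01).
#' @return character vector of retained TF names.
#' @export
significant_tfbs <- function(p_table, tf_expression, alpha = 0.01) {
  pcols <- setdiff(names(p_table), "tf")
  if (length(pcols) < 1L) stop("no background p-value columns")
  if (anyNA(p_table[pcols])) stop("missing background p-value")
  expr <- tf_expression[p_table$tf]
  if (anyNA(expr)) stop("missing TF expression for: ",
                        p_table$tf[is.na(expr)][1])
  ok <- rowSums(as.matrix(p_table[pcols]) < alpha) == length(pcols) &
    expr > 0
  p_table$tf[ok]
}

# evaluate expr with a locally-set RNG seed, restoring global RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
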