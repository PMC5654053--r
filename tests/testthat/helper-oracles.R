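# Independent oracles used by the test suite. Each re-derives the expected
# result by brute force or direct formula, sharing no code path with the
# implementation it checks.

# ---- brute-force divergent enhancer caller -------------------------------

oracle_call_bidirectional <- function(peaks, counts, gap = 400L,
                                      halfwidth = 200L, dmax = 0.8) {
  pooled <- rowSums(counts)[peaks$id]
  cand <- list()
  for (i in seq_len(nrow(peaks))) {
    if (peaks$strand[i] != "-") next
    for (j in seq_len(nrow(peaks))) {
      if (peaks$strand[j] != "+") next
      if (peaks$chrom[i] != peaks$chrom[j]) next
      sm <- peaks$summit[i]; sp <- peaks$summit[j]
      if (!(sm < sp && sp - sm <= gap)) next
      mid <- floor((sm + sp) / 2)
      start <- mid - halfwidth
      end <- mid + halfwidth + 1L
      P <- 0; M <- 0
      for (k in seq_len(nrow(peaks))) {
        if (peaks$chrom[k] != peaks$chrom[i]) next
        s <- peaks$summit[k]
        if (peaks$strand[k] == "+" && s >= mid && s < end)
          P <- P + pooled[k]
        if (peaks$strand[k] == "-" && s >= start && s < mid)
          M <- M + pooled[k]
      }
      if (P + M == 0) next
      D <- (P - M) / (P + M)
      if (abs(D) >= dmax) next
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = peaks$chrom[i], start = start, end = end, midpoint = mid,
        minus_peak_id = peaks$id[i], plus_peak_id = peaks$id[j],
        directionality = D, pooled_tags = P + M, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$pooled_tags, cand$chrom, cand$midpoint,
                     cand$minus_peak_id, cand$plus_peak_id), , drop = FALSE]
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    clash <- FALSE
    for (j in which(keep)) {
      if (cand$chrom[j] == cand$chrom[i] &&
          cand$start[j] < cand$end[i] && cand$start[i] < cand$end[j])
        clash <- TRUE
    }
    keep[i] <- !clash
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

# random peak sets for oracle-equivalence checks
random_peak_set <- function(n_chrom = 2L, max_per_chrom = 50L) {
  rows <- list()
  for (c in seq_len(n_chrom)) {
    n <- sample.int(max_per_chrom, 1L)
    summits <- sample.int(5000L, n)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    rows[[c]] <- data.frame(
      chrom = paste0("chr", c),
      start = summits - sample(0:10, n, replace = TRUE),
      end = summits + sample(1:10, n, replace = TRUE),
      strand = strands, summit = summits, stringsAsFactors = FALSE)
  }
  pk <- do.call(rbind, rows)
  pk$start <- pmax(pk$start, 0L)
  pk$id <- sprintf("rp_%s_%s_%d", pk$chrom, ifelse(pk$strand == "+", "p",
                                                   "m"), pk$summit)
  pk <- pk[!duplicated(pk$id), , drop = FALSE]
  counts <- matrix(rpois(2L * nrow(pk), 5), ncol = 2L,
                   dimnames = list(pk$id, c("s1", "s2")))
  cage_peaks(pk[c("id", "chrom", "start", "end", "strand", "summit")],
             counts)
}

# ---- direct step-up BH formula -------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi)
    min(pmin(1, sp[js] * m / js))
  }, numeric(1))
}

# ---- rank-then-Pearson Spearman ------------------------------------------

oracle_avg_rank <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x)
  ry <- oracle_avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  rho <- num / den
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tt), n - 2))
}

# ---- direct-formula TMM on an explicitly retained feature set ------------

oracle_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    unname(quantile(counts[, j], 0.75)) / lib[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    fin <- obs > 0 & rf > 0
    logR <- log2((obs[fin] / nO) / (rf[fin] / nR))
    absE <- (log2(obs[fin] / nO) + log2(rf[fin] / nR)) / 2
    v <- (nO - obs[fin]) / (nO * obs[fin]) + (nR - rf[fin]) / (nR * rf[fin])
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# ---- exhaustive hypergeometric enumeration -------------------------------

# P(overlap >= k) for a random n-subset of 1..N against the term 1..K
oracle_hyper_tail <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- combn(N, n)
  ov <- colSums(subsets <= K)
  mean(ov >= k)
}
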