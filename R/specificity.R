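# z-score classification: tissue-specific, stimulus-responsive and marker
# features.

#' Expression z-scores of target samples against a background set
#'
#' For each feature, `z = (x - mean_bg) / sd_bg` with the background mean
#' and standard deviation (n - 1 denominator) taken over the background
#' samples. Features with a constant background get `z = Inf` where the
#' target value exceeds the background mean and `z = 0` otherwise.
#'
#' @param tpm expression matrix (TPM) with feature rownames.
#' @param target_ids target sample column names.
#' @param background_ids background sample column names (>= 2).
#' @return z-score matrix, features x target samples.
#' @export
zscores <- function(tpm, target_ids, background_ids) {
  stopifnot(length(background_ids) >= 2,
            all(target_ids %in% colnames(tpm)),
            all(background_ids %in% colnames(tpm)))
  bg <- tpm[, background_ids, drop = FALSE]
  mu <- rowMeans(bg)
  sdv <- apply(bg, 1L, stats::sd)
  x <- tpm[, target_ids, drop = FALSE]
  z <- (x - mu) / sdv
  if (any(sdv == 0)) {
    deg <- which(sdv == 0)
    z[deg, ] <- ifelse(x[deg, , drop = FALSE] >
                         mu[deg], Inf, 0)
  }
  z
}

#' Count of target samples with z above a threshold (strict)
#' @param z z-score matrix from [zscores()].
#' @param threshold z cutoff (default 3); strictly greater counts.
#' @return named integer vector per feature.
#' @export
count_above <- function(z, threshold = 3) {
  rowSums(z > threshold)
}

#' Classify tissue-specific features
#'
#' A feature is specific when `z > threshold` in at least
#' `ceiling(frac * n)` of the `n` target samples.
#'
#' @param z z-score matrix (targets = e.g. macrophage samples, background =
#'   non-macrophage samples).
#' @param frac required fraction of target samples (default 0.10).
#' @param threshold z cutoff (default 3).
#' @return character vector of specific feature ids.
#' @export
macrophage_specific <- function(z, frac = 0.10, threshold = 3) {
  need <- ceiling(frac * ncol(z))
  rownames(z)[count_above(z, threshold) >= need]
}

#' Classify stimulus-responsive features
#'
#' z-scores of the stimulated samples are computed against the unstimulated
#' background; a feature is responsive when `z > threshold` in strictly
#' more than `frac` of the stimulated samples (e.g. more than 25% of 16
#' samples means at least 5).
#'
#' @param tpm expression matrix.
#' @param stim_ids stimulated sample ids for one activation state.
#' @param unstim_ids unstimulated (background) sample ids.
#' @param frac strict fraction cutoff (default 0.25).
#' @param threshold z cutoff (default 3).
#' @return character vector of responsive feature ids.
#' @export
stimuli_responsive <- function(tpm, stim_ids, unstim_ids, frac = 0.25,
                               threshold = 3) {
  if (length(intersect(stim_ids, unstim_ids)))
    stop("stimulated and background samples must be disjoint")
  z <- zscores(tpm, stim_ids, unstim_ids)
  rownames(z)[count_above(z, threshold) > frac * length(stim_ids)]
}

#' Restrict links to one activation state by in-state correlation sign
#'
#' Recomputes Spearman rho over the state's samples for each link and keeps
#' strictly positive correlations (no p-value requirement). Links with
#' constant expression in the subset are dropped with a message.
#'
#' @param links link data.frame (enhancer_id, promoter_id columns).
#' @param enh_mat,prom_mat expression matrices.
#' @param state_ids sample ids of the activation state.
#' @return subset of `links` with an added rho_state column.
#' @export
condition_links <- function(links, enh_mat, prom_mat, state_ids) {
  if (!nrow(links)) {
    links$rho_state <- numeric(0)
    return(links)
  }
  keep <- logical(nrow(links))
  rho <- rep(NA_real_, nrow(links))
  n_const <- 0L
  for (i in seq_len(nrow(links))) {
    x <- enh_mat[links$enhancer_id[i], state_ids]
    y <- prom_mat[links$promoter_id[i], state_ids]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      n_const <- n_const + 1L
      next
    }
    rho[i] <- stats::cor(x, y, method = "spearman")
    keep[i] <- rho[i] > 0
  }
  if (n_const > 0L)
    message(n_const, " links with constant in-state expression dropped")
  out <- links[keep, , drop = FALSE]
  out$rho_state <- rho[keep]
  rownames(out) <- NULL
  out
}

#' Identify activation marker enhancers
#'
#' For each activation state, a marker enhancer is (i) responsive in that
#' state and not in the other, (ii) linked in-state to at least one known
#' marker gene of the state, and (iii) over-expressed versus the other
#' state: `z > threshold` (computed with the other state's samples as
#' background) in strictly more than `frac` of the state's samples.
#'
#' @param responsive named list of responsive enhancer id vectors, one per
#'   state (e.g. `list(ifng = ..., il4il13 = ...)`).
#' @param state_links named list of state-restricted gene-level link
#'   data.frames (enhancer_id, gene_id), as from [condition_links()] mapped
#'   to genes.
#' @param marker_genes data.frame(gene_id, state) of known marker genes.
#' @param enh_mat eRNA expression matrix (TPM).
#' @param state_samples named list of sample id vectors per state.
#' @param frac strict fraction cutoff (default 0.25).
#' @param threshold z cutoff (default 3).
#' @return data.frame(enhancer_id, state, marker_gene_ids).
#' @export
marker_enhancers <- function(responsive, state_links, marker_genes, enh_mat,
                             state_samples, frac = 0.25, threshold = 3) {
  states <- names(responsive)
  stopifnot(length(states) == 2L,
            setequal(states, names(state_samples)),
            setequal(states, names(state_links)))
  out <- list()
  for (s in states) {
    other <- setdiff(states, s)
    cand <- setdiff(responsive[[s]], responsive[[other]])
    mk <- marker_genes$gene_id[marker_genes$state == s]
    gl <- state_links[[s]]
    gl <- gl[gl$enhancer_id %in% cand & gl$gene_id %in% mk, , drop = FALSE]
    if (!nrow(gl)) next
    ids <- unique(gl$enhancer_id)
    z <- zscores(enh_mat[ids, , drop = FALSE], state_samples[[s]],
                 state_samples[[other]])
    pass <- count_above(z, threshold) > frac * length(state_samples[[s]])
    ids <- ids[pass]
    if (!length(ids)) next
    out[[s]] <- data.frame(
      enhancer_id = ids,
      state = s,
      marker_gene_ids = vapply(ids, function(e)
        paste(sort(unique(gl$gene_id[gl$enhancer_id == e])), collapse = ","),
        character(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(enhancer_id = character(), state = character(),
                      marker_gene_ids = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a marker gene table (TSV with gene_id and state columns)
#' @param path TSV path.
#' @return data.frame(gene_id, state).
#' @export
read_marker_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "state") %in% names(df)))
  df
}
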