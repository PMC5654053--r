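# End-to-end orchestration: quantify -> call -> chip-filter -> link ->
# classify -> enrich -> report, plus the summary-ratio report.

#' Analysis configuration
#'
#' Houses every numeric threshold of the pipeline: promoter/exon masking
#' windows, divergent-pairing geometry, directionality cutoff, expression
#' and transcription filters, link FDR, z-score classification rules and
#' Monte-Carlo settings.
#'
#' @param promoter_window_bp promoter assignment window (default 500).
#' @param exon_mask_bp exon masking window (default 200).
#' @param divergent_gap_bp maximum divergent summit separation (default
#'   400).
#' @param enhancer_halfwidth_bp enhancer half-width (default 200).
#' @param directionality_max directionality cutoff `|D|` (default 0.8).
#' @param tpm_min expression threshold in TPM (default 1).
#' @param expressed_frac fraction of macrophage samples required at
#'   `tpm_min` (default 0.10).
#' @param transcribed_frac fraction of macrophage samples with nonzero
#'   eRNA required (default 0.10).
#' @param link_fdr BH FDR cutoff for links (default 1e-4).
#' @param z_threshold z-score cutoff (default 3).
#' @param specific_frac fraction rule for tissue specificity (default
#'   0.10, at-least-ceiling).
#' @param responsive_frac fraction rule for stimulus response (default
#'   0.25, strictly-more-than).
#' @param mc_trials Monte-Carlo trials (default 1000).
#' @param mc_alpha Monte-Carlo significance cutoff (default 0.01).
#' @param tfbs_summit_fdr summit q-value cutoff (default 1e-4).
#' @param tss_cluster_gap single-linkage TSS clustering gap (default 20).
#' @return list of settings (class `pipeline_config`).
#' @export
pipeline_config <- function(promoter_window_bp = 500L,
                            exon_mask_bp = 200L,
                            divergent_gap_bp = 400L,
                            enhancer_halfwidth_bp = 200L,
                            directionality_max = 0.8,
                            tpm_min = 1,
                            expressed_frac = 0.10,
                            transcribed_frac = 0.10,
                            link_fdr = 1e-4,
                            z_threshold = 3,
                            specific_frac = 0.10,
                            responsive_frac = 0.25,
                            mc_trials = 1000L,
                            mc_alpha = 0.01,
                            tfbs_summit_fdr = 1e-4,
                            tss_cluster_gap = 20L) {
  cfg <- as.list(environment())
  stopifnot(cfg$expressed_frac > 0, cfg$expressed_frac < 1,
            cfg$transcribed_frac > 0, cfg$transcribed_frac < 1,
            cfg$specific_frac > 0, cfg$specific_frac < 1,
            cfg$responsive_frac > 0, cfg$responsive_frac < 1,
            cfg$promoter_window_bp > 0, cfg$exon_mask_bp > 0,
            cfg$divergent_gap_bp > 0, cfg$enhancer_halfwidth_bp > 0)
  structure(cfg, class = "pipeline_config")
}

#' Run the full enhancer-interactome analysis
#'
#' Executes every stage in order on an in-memory dataset (as produced by
#' [simulate_dataset()] or assembled from files with the package readers):
#' promoter quantification and filtering, enhancer calling and eRNA
#' quantification, chromatin-state filtering, TAD-constrained correlation
#' linking, specificity/responsiveness/marker classification, TFBS
#' Monte-Carlo enrichment and the summary report.
#'
#' @param data list with elements `tss` ([tss_counts()]), `samples`
#'   (metadata data.frame), `genome` (list with `genes` gene models, `tads`
#'   and `exclusions`), `chip` (state intervals), `tfbs` (named list of
#'   summit data.frames with q_value), `tf_expression` (named vector).
#' @param config [pipeline_config()].
#' @param markers marker gene data.frame(gene_id, state) or NULL to skip
#'   marker calling.
#' @param gene_sets optional named list of gene sets for over-
#'   representation testing of linked genes.
#' @param mc_seed integer seed for Monte-Carlo resampling.
#' @return list of stage outputs (peaks, promoters, enhancers, links,
#'   classification, enrichment, report).
#' @export
run_pipeline <- function(data, config = pipeline_config(), markers = NULL,
                         gene_sets = NULL, mc_seed = 1L) {
  for (need in c("tss", "samples", "genome", "chip"))
    if (is.null(data[[need]])) stop("input '", need, "' is missing")
  samples <- data$samples
  mac <- samples$sample_id[samples$group == "macrophage"]
  bg <- samples$sample_id[samples$group == "non_macrophage"]
  untx <- samples$sample_id[samples$condition == "untreated"]
  state_samples <- list(
    ifng = samples$sample_id[samples$condition == "ifng"],
    il4il13 = samples$sample_id[samples$condition == "il4il13"])

  ## stage 1: tag clusters and promoter expression
  peaks <- cluster_tss(data$tss, config$tss_cluster_gap)
  assignments <- assign_promoters(peaks$peaks, data$genome$genes,
                                  config$promoter_window_bp)
  prom_ids <- unique(assignments$peak_id)
  prom_counts <- peaks$counts[prom_ids, , drop = FALSE]
  prom_factors <- tmm_factors(prom_counts)
  prom_tpm <- to_tpm(prom_counts, prom_factors)
  expressed_proms <- filter_expressed(prom_tpm, mac, config$tpm_min,
                                      config$expressed_frac)
  assignments <- assignments[assignments$peak_id %in% expressed_proms, ,
                             drop = FALSE]
  prom_tpm <- prom_tpm[expressed_proms, , drop = FALSE]
  gene_tpm <- gene_expression(prom_tpm, assignments)

  ## stage 2: enhancer calling and eRNA quantification
  masked <- mask_peaks(peaks, data$genome$genes, config$promoter_window_bp,
                       config$exon_mask_bp)
  enhancers <- call_bidirectional(masked, config$divergent_gap_bp,
                                  config$enhancer_halfwidth_bp,
                                  config$directionality_max)
  erna_counts <- quantify_ernas(enhancers, data$tss)
  erna_tpm <- to_tpm(erna_counts, tmm_factors(erna_counts))
  enhancers$transcribed <- as.logical(
    flag_transcribed(erna_counts, mac, config$transcribed_frac))

  ## stage 3: chromatin-state filter
  cf <- chip_filter(enhancers, data$chip)
  enhancers$chip_supported <- cf$chip_supported
  enhancers$chip_state <- cf$chip_state
  active <- enhancers[enhancers$transcribed & enhancers$chip_supported, ,
                      drop = FALSE]

  ## stage 4: TAD-constrained correlation links
  prom_df <- peaks$peaks[peaks$peaks$id %in% expressed_proms, ,
                         drop = FALSE]
  pairs <- tad_pairs(active, prom_df, data$genome$tads)
  pairs <- pair_spearman(pairs, erna_tpm, prom_tpm, mac)
  links <- select_links(pairs, config$link_fdr)
  gene_map <- map_to_genes(links, assignments, rownames(gene_tpm))
  dstats <- distance_stats(links$distance, pairs$distance)

  ## stage 5: classification
  linked_enh <- unique(links$enhancer_id)
  z_enh <- zscores(erna_tpm[linked_enh, , drop = FALSE], mac, bg)
  spec_enh <- macrophage_specific(z_enh, config$specific_frac,
                                  config$z_threshold)
  z_gene <- zscores(gene_tpm, mac, bg)
  spec_gene <- macrophage_specific(z_gene, config$specific_frac,
                                   config$z_threshold)
  resp_enh <- lapply(state_samples, function(ss)
    stimuli_responsive(erna_tpm[linked_enh, , drop = FALSE], ss, untx,
                       config$responsive_frac, config$z_threshold))
  resp_gene <- lapply(state_samples, function(ss)
    stimuli_responsive(gene_tpm, ss, untx, config$responsive_frac,
                       config$z_threshold))
  pg <- unique(assignments[c("peak_id", "gene_id")])
  state_links <- list()
  for (s in names(state_samples)) {
    sub <- merge(links, pg, by.x = "promoter_id", by.y = "peak_id")
    sub <- sub[sub$enhancer_id %in% resp_enh[[s]] &
                 sub$gene_id %in% resp_gene[[s]], , drop = FALSE]
    sub <- condition_links(sub, erna_tpm, prom_tpm, state_samples[[s]])
    state_links[[s]] <- unique(sub[c("enhancer_id", "gene_id")])
  }
  marker_calls <- if (is.null(markers)) NULL else
    marker_enhancers(resp_enh, state_links, markers, erna_tpm,
                     state_samples, config$responsive_frac,
                     config$z_threshold)

  ## stage 6: enrichment
  gsea <- if (is.null(gene_sets)) NULL else
    hypergeom_test(gene_map$summary$gene_id[gene_map$summary$n_enhancers >
                                              0],
                   gene_sets, rownames(gene_tpm))
  tf_enrich <- NULL
  if (!is.null(data$tfbs)) {
    query <- active[active$id %in% spec_enh, , drop = FALSE]
    pool_all <- enhancers
    pool_nonmac <- enhancers[!enhancers$transcribed, , drop = FALSE]
    excl <- rbind(
      data$genome$exclusions[c("chrom", "start", "end")],
      data$genome$genes$exons[c("chrom", "start", "end")],
      enhancers[c("chrom", "start", "end")])
    sampler <- make_region_sampler(data$genome$tads, excl)
    rows <- list()
    for (tf in names(data$tfbs)) {
      sm <- data$tfbs[[tf]]
      sm <- sm[sm$q_value < config$tfbs_summit_fdr, , drop = FALSE]
      p <- vapply(
        list(all_enhancers = pool_all, non_macrophage = pool_nonmac,
             random_regions = sampler),
        function(bgset) monte_carlo_p(query, sm, bgset, config$mc_trials,
                                      seed = mc_seed)$p_value,
        numeric(1))
      rows[[tf]] <- data.frame(
        tf = tf,
        observed_frac = tfbs_overlap_stat(query, sm),
        p_all_enhancers = p[["all_enhancers"]],
        p_non_macrophage = p[["non_macrophage"]],
        p_random_regions = p[["random_regions"]],
        stringsAsFactors = FALSE)
    }
    tf_table <- do.call(rbind, rows)
    rownames(tf_table) <- NULL
    retained <- significant_tfbs(
      tf_table[c("tf", "p_all_enhancers", "p_non_macrophage",
                 "p_random_regions")],
      data$tf_expression, config$mc_alpha)
    tf_enrich <- list(table = tf_table, retained = retained,
                      query = query$id)
  }

  out <- list(
    config = config,
    samples = samples,
    peaks = peaks,
    assignments = assignments,
    prom_tpm = prom_tpm,
    gene_tpm = gene_tpm,
    enhancers = enhancers,
    erna_counts = erna_counts,
    erna_tpm = erna_tpm,
    active = active,
    pairs = pairs,
    links = links,
    gene_map = gene_map,
    distance_stats = dstats,
    specific_enhancers = spec_enh,
    specific_genes = spec_gene,
    responsive_enhancers = resp_enh,
    responsive_genes = resp_gene,
    state_links = state_links,
    markers = marker_calls,
    gsea = gsea,
    tf_enrichment = tf_enrich)
  out$report <- report_summary(out)
  out
}

#' Round half-up percentage
#'
#' `100 * a / b` rounded half-up to `digits` decimals — the convention used
#' for every percentage in the summary report.
#'
#' @param a numerator.
#' @param b denominator.
#' @param digits decimals (0 for integer percentages).
#' @return numeric percentage.
#' @export
pct_half_up <- function(a, b, digits = 0L) {
  x <- 100 * a / b
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summary report of counts and percentages
#'
#' Recomputes the headline counts and ratios of a pipeline run: enhancer
#' tallies through the calling/chip funnel, link counts, the gene-by-
#' enhancer-number breakdown, specificity and responsiveness tallies.
#' Percentages are `100 * numerator / denominator`, rounded half-up to the
#' stated decimals, and always recomputable from their own columns.
#'
#' @param pipe output list of [run_pipeline()].
#' @return data.frame(metric, numerator, denominator, digits, value).
#' @export
report_summary <- function(pipe) {
  rows <- list()
  count_row <- function(metric, n)
    data.frame(metric = metric, numerator = n, denominator = NA_real_,
               digits = NA_integer_, value = n, stringsAsFactors = FALSE)
  pct_row <- function(metric, a, b, digits)
    data.frame(metric = metric, numerator = a, denominator = b,
               digits = digits, value = pct_half_up(a, b, digits),
               stringsAsFactors = FALSE)
  enh <- pipe$enhancers
  n_tr <- sum(enh$transcribed)
  n_tr_chip <- sum(enh$transcribed & enh$chip_supported)
  rows$a <- count_row("enhancers_called", nrow(enh))
  rows$b <- count_row("enhancers_transcribed", n_tr)
  rows$c <- count_row("enhancers_transcribed_chip_supported", n_tr_chip)
  rows$d <- pct_row("pct_transcribed_chip_supported", n_tr_chip, n_tr, 0L)
  rows$e <- count_row("tad_pairs", nrow(pipe$pairs))
  rows$f <- count_row("links", nrow(pipe$links))
  linked <- unique(pipe$links$enhancer_id)
  rows$g <- count_row("linked_enhancers", length(linked))
  gs <- pipe$gene_map$summary
  rows$h <- count_row("expressed_genes", nrow(gs))
  rows$i <- pct_row("pct_genes_without_enhancer",
                    sum(gs$n_enhancers == 0L), nrow(gs), 1L)
  rows$j <- pct_row("pct_linked_enhancers_macrophage_specific",
                    length(pipe$specific_enhancers), length(linked), 1L)
  for (s in names(pipe$responsive_enhancers)) {
    rows[[paste0("re_", s)]] <- count_row(
      paste0("responsive_enhancers_", s),
      length(unique(pipe$state_links[[s]]$enhancer_id)))
    rows[[paste0("rg_", s)]] <- count_row(
      paste0("responsive_genes_", s),
      length(unique(pipe$state_links[[s]]$gene_id)))
  }
  if (!is.null(pipe$markers))
    for (s in unique(pipe$markers$state))
      rows[[paste0("mk_", s)]] <- count_row(
        paste0("marker_enhancers_", s), sum(pipe$markers$state == s))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
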