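#!/usr/bin/env Rscript
# Stage 5: enrichment analyses.
#
# TFBS over-representation in macrophage-specific enhancers by Monte-Carlo
# resampling (1000 trials) against three backgrounds: all called enhancers,
# enhancers not transcribed in macrophages, and width-matched random
# regions inside TADs avoiding repeats, coding exons and called enhancers.
# Also a hypergeometric check that linked genes are enriched for the
# planted target-gene set (a positive control read from the truth tables).

suppressMessages(library(ernalink))

dat <- "results/data"
cfg <- pipeline_config()
seed <- as.integer(Sys.getenv("ERNALINK_SEED", "1"))

enh <- read.delim("results/enhancers.tsv")
classification <- read.delim("results/enhancer_classification.tsv")
tads <- read_tads(file.path(dat, "tads.bed"))
repeats <- read_bed(file.path(dat, "repeats.bed"))
gm <- read_gene_models(file.path(dat, "genes.gtf"))
tf_expr_df <- read.delim(file.path(dat, "tf_expression.tsv"))
tf_expression <- setNames(tf_expr_df$mean_tpm, tf_expr_df$tf)

query <- enh[enh$id %in%
               classification$enhancer_id[classification$macrophage_specific], ]
pool_all <- enh
pool_nonmac <- enh[!enh$transcribed, ]
excl <- rbind(repeats[c("chrom", "start", "end")],
              gm$exons[c("chrom", "start", "end")],
              enh[c("chrom", "start", "end")])
sampler <- make_region_sampler(tads, excl)

tf_files <- list.files(file.path(dat, "tfbs"), full.names = TRUE)
rows <- list()
for (f in tf_files) {
  tf <- sub("\\.narrowPeak$", "", basename(f))
  np <- read_narrowpeak(f)
  sm <- data.frame(chrom = np$chrom, pos = np$summit)[
    np$q_value < cfg$tfbs_summit_fdr, ]
  p <- vapply(
    list(all_enhancers = pool_all, non_macrophage = pool_nonmac,
         random_regions = sampler),
    function(bgset) monte_carlo_p(query, sm, bgset, cfg$mc_trials,
                                  seed = seed + 1L)$p_value,
    numeric(1))
  rows[[tf]] <- data.frame(tf = tf,
                           observed_frac = tfbs_overlap_stat(query, sm),
                           p_all_enhancers = p[["all_enhancers"]],
                           p_non_macrophage = p[["non_macrophage"]],
                           p_random_regions = p[["random_regions"]])
}
tf_table <- do.call(rbind, rows)
retained <- significant_tfbs(
  tf_table[c("tf", "p_all_enhancers", "p_non_macrophage",
             "p_random_regions")], tf_expression, cfg$mc_alpha)
cat(sprintf("TFBS over-representation: %d of %d TFs retained: %s\n",
            length(retained), nrow(tf_table),
            paste(retained, collapse = ", ")))
write.table(tf_table, "results/tfbs_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(retained, "results/tfbs_retained.txt")

# positive-control gene-set test: are linked genes enriched for the genes
# the generator wired to an enhancer?
truth_links <- read.delim(file.path(dat, "truth_links.tsv"))
gene_counts <- read.delim("results/gene_enhancer_counts.tsv")
linked_genes <- gene_counts$gene_id[gene_counts$n_enhancers > 0]
sets <- list(planted_targets = unique(truth_links$gene_id))
gsea <- hypergeom_test(linked_genes, sets, gene_counts$gene_id)
cat(sprintf("linked genes vs planted targets: overlap %d/%d, hypergeometric p = %.3g\n",
            gsea$k_overlap, gsea$K_term, gsea$p))
write.table(gsea, "results/gene_set_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
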