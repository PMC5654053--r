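#!/usr/bin/env Rscript
# Stage 3: build the enhancer-promoter-gene interactome.
#
# Annotates promoters (500-bp same-strand rule), TMM-normalizes promoter
# and eRNA counts to TPM, filters lowly expressed promoters, pairs
# transcribed chromatin-supported enhancers with promoters inside shared
# TADs, and keeps positively correlated pairs at FDR < 1e-4 (Spearman over
# macrophage samples, BH across all TAD pairs).

suppressMessages(library(ernalink))

dat <- "results/data"
cfg <- pipeline_config()

tss <- read_tss_counts(file.path(dat, "tss_counts.tsv"))
gm <- read_gene_models(file.path(dat, "genes.gtf"))
tads <- read_tads(file.path(dat, "tads.bed"))
samples <- read.delim(file.path(dat, "samples.tsv"))
mac <- samples$sample_id[samples$group == "macrophage"]
enh <- read.delim("results/enhancers.tsv")
erna <- read_count_table("results/erna_counts.tsv")

peaks <- cluster_tss(tss, cfg$tss_cluster_gap)
asn <- assign_promoters(peaks$peaks, gm, cfg$promoter_window_bp)
prom_counts <- peaks$counts[unique(asn$peak_id), , drop = FALSE]
prom_tpm <- to_tpm(prom_counts, tmm_factors(prom_counts))
expressed <- filter_expressed(prom_tpm, mac, cfg$tpm_min,
                              cfg$expressed_frac)
asn <- asn[asn$peak_id %in% expressed, ]
prom_tpm <- prom_tpm[expressed, , drop = FALSE]
gene_tpm <- gene_expression(prom_tpm, asn)
cat(sprintf("%d promoter peaks pass the %g-TPM filter; %d genes expressed\n",
            length(expressed), cfg$tpm_min, nrow(gene_tpm)))

erna_tpm <- to_tpm(erna, tmm_factors(erna))
active <- enh[enh$transcribed & enh$chip_supported, ]
prom_df <- peaks$peaks[peaks$peaks$id %in% expressed, ]
pairs <- tad_pairs(active, prom_df, tads)
pairs <- pair_spearman(pairs, erna_tpm, prom_tpm, mac)
links <- select_links(pairs, cfg$link_fdr)
gmap <- map_to_genes(links, asn, rownames(gene_tpm))
ds <- distance_stats(links$distance, pairs$distance)

cat(sprintf("%d TAD-based pairs -> %d significant positive links (%d enhancers, %d genes)\n",
            nrow(pairs), nrow(links), length(unique(links$enhancer_id)),
            sum(gmap$summary$n_enhancers > 0)))
cat(sprintf("median enhancer-promoter distance: %.0f nt in links vs %.0f nt in all TAD pairs (rank-sum p = %.3g)\n",
            ds$median1, ds$median2, ds$p_value))

write.table(pairs, "results/tad_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(links, "results/links.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(gmap$gene_links, "results/gene_links.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gmap$summary, "results/gene_enhancer_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(asn, "results/promoter_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_count_table(prom_tpm, "results/promoter_tpm.tsv", "peak_id")
write_count_table(gene_tpm, "results/gene_tpm.tsv", "gene_id")
write_count_table(erna_tpm, "results/erna_tpm.tsv", "enhancer_id")
cat("wrote interactome tables under results/\n")
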