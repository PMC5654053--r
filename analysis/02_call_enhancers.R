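#!/usr/bin/env Rscript
# Stage 2: call bidirectional enhancer candidates from the CAGE signal.
#
# Clusters TSS positions into stranded tag clusters, masks clusters near
# protein-coding TSSs/exons, pairs divergent clusters into fixed-width
# 401-nt loci, quantifies eRNA, and flags loci transcribed in macrophages
# and supported by enhancer chromatin states.

suppressMessages(library(ernalink))

dat <- "results/data"
cfg <- pipeline_config()

tss <- read_tss_counts(file.path(dat, "tss_counts.tsv"))
gm <- read_gene_models(file.path(dat, "genes.gtf"))
chip <- read_chip_bed(file.path(dat, "chip_states.bed"))
samples <- read.delim(file.path(dat, "samples.tsv"))
mac <- samples$sample_id[samples$group == "macrophage"]

peaks <- cluster_tss(tss, cfg$tss_cluster_gap)
cat(sprintf("clustered %d TSS positions into %d tag clusters\n",
            nrow(tss$positions), nrow(peaks$peaks)))

masked <- mask_peaks(peaks, gm, cfg$promoter_window_bp, cfg$exon_mask_bp)
cat(sprintf("masking removed %d gene-proximal clusters (%d retained)\n",
            nrow(peaks$peaks) - nrow(masked$peaks), nrow(masked$peaks)))

enh <- call_bidirectional(masked, cfg$divergent_gap_bp,
                          cfg$enhancer_halfwidth_bp, cfg$directionality_max)
erna <- quantify_ernas(enh, tss)
enh$transcribed <- as.logical(flag_transcribed(erna, mac,
                                               cfg$transcribed_frac))
cf <- chip_filter(enh, chip)
enh$chip_supported <- cf$chip_supported
enh$chip_state <- cf$chip_state

cat(sprintf("called %d enhancers; %d transcribed in macrophages; %d of those chromatin-supported\n",
            nrow(enh), sum(enh$transcribed),
            sum(enh$transcribed & enh$chip_supported)))

write.table(enh, "results/enhancers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_bed(data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                     name = enh$id, score = enh$pooled_tags,
                     strand = "*"),
          "results/enhancers.bed")
write_count_table(erna, "results/erna_counts.tsv", "enhancer_id")
cat("wrote results/enhancers.{tsv,bed}, results/erna_counts.tsv\n")
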