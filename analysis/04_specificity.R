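#!/usr/bin/env Rscript
# Stage 4: z-score classification of the linked enhancers and genes.
#
# Macrophage specificity (z > 3 versus non-macrophage samples in >= 10% of
# macrophage samples), stimulus responsiveness per activation state (z > 3
# versus untreated macrophages in > 25% of stimulated samples),
# state-restricted links (positive in-state correlation) and activation
# marker enhancers (state-exclusive, linked to a known marker gene,
# over-expressed versus the opposite state).

suppressMessages(library(ernalink))

dat <- "results/data"
cfg <- pipeline_config()

samples <- read.delim(file.path(dat, "samples.tsv"))
mac <- samples$sample_id[samples$group == "macrophage"]
bg <- samples$sample_id[samples$group == "non_macrophage"]
untx <- samples$sample_id[samples$condition == "untreated"]
state_samples <- list(
  ifng = samples$sample_id[samples$condition == "ifng"],
  il4il13 = samples$sample_id[samples$condition == "il4il13"])

erna_tpm <- read_count_table("results/erna_tpm.tsv")
prom_tpm <- read_count_table("results/promoter_tpm.tsv")
gene_tpm <- read_count_table("results/gene_tpm.tsv")
links <- read.delim("results/links.tsv")
asn <- read.delim("results/promoter_assignments.tsv")
markers <- read_marker_genes(file.path(dat, "marker_genes.tsv"))

linked <- unique(links$enhancer_id)
z_enh <- zscores(erna_tpm[linked, , drop = FALSE], mac, bg)
spec_enh <- macrophage_specific(z_enh, cfg$specific_frac, cfg$z_threshold)
spec_gene <- macrophage_specific(zscores(gene_tpm, mac, bg),
                                 cfg$specific_frac, cfg$z_threshold)
cat(sprintf("%d of %d linked enhancers macrophage-specific (%.1f%%); %d genes\n",
            length(spec_enh), length(linked),
            pct_half_up(length(spec_enh), length(linked), 1),
            length(spec_gene)))

resp_enh <- lapply(state_samples, function(ss)
  stimuli_responsive(erna_tpm[linked, , drop = FALSE], ss, untx,
                     cfg$responsive_frac, cfg$z_threshold))
resp_gene <- lapply(state_samples, function(ss)
  stimuli_responsive(gene_tpm, ss, untx, cfg$responsive_frac,
                     cfg$z_threshold))

pg <- unique(asn[c("peak_id", "gene_id")])
state_links <- list()
for (s in names(state_samples)) {
  sub <- merge(links, pg, by.x = "promoter_id", by.y = "peak_id")
  sub <- sub[sub$enhancer_id %in% resp_enh[[s]] &
               sub$gene_id %in% resp_gene[[s]], ]
  sub <- condition_links(sub, erna_tpm, prom_tpm, state_samples[[s]])
  state_links[[s]] <- unique(sub[c("enhancer_id", "gene_id")])
  cat(sprintf("%s: %d responsive enhancers regulating %d responsive genes\n",
              s, length(unique(state_links[[s]]$enhancer_id)),
              length(unique(state_links[[s]]$gene_id))))
}

mk <- marker_enhancers(resp_enh, state_links, markers, erna_tpm,
                       state_samples, cfg$responsive_frac, cfg$z_threshold)
cat(sprintf("marker enhancers: %d ifng, %d il4il13\n",
            sum(mk$state == "ifng"), sum(mk$state == "il4il13")))

classification <- data.frame(
  enhancer_id = linked,
  macrophage_specific = linked %in% spec_enh,
  responsive_ifng = linked %in% resp_enh$ifng,
  responsive_il4il13 = linked %in% resp_enh$il4il13,
  n_z_above = as.integer(count_above(z_enh, cfg$z_threshold)))
write.table(classification, "results/enhancer_classification.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
for (s in names(state_links))
  write.table(state_links[[s]],
              sprintf("results/state_links_%s.tsv", s), sep = "\t",
              quote = FALSE, row.names = FALSE)
write.table(mk, "results/marker_enhancers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(spec_gene, "results/specific_genes.txt")
cat("wrote classification tables under results/\n")
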