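#!/usr/bin/env Rscript
# Stage 6: summary report and truth-based scoring.
#
# Tallies the stage outputs into the headline counts and half-up-rounded
# percentages, then scores the run against the planted truth: enhancer and
# link recovery, TAD containment of links and TF retention.

suppressMessages(library(ernalink))

dat <- "results/data"

enh <- read.delim("results/enhancers.tsv")
pairs <- read.delim("results/tad_pairs.tsv")
links <- read.delim("results/links.tsv")
gene_counts <- read.delim("results/gene_enhancer_counts.tsv")
classification <- read.delim("results/enhancer_classification.tsv")
markers <- read.delim("results/marker_enhancers.tsv")
state_links <- lapply(c(ifng = "ifng", il4il13 = "il4il13"), function(s)
  read.delim(sprintf("results/state_links_%s.tsv", s)))

pipe <- list(
  enhancers = enh, pairs = pairs, links = links,
  gene_map = list(summary = gene_counts),
  specific_enhancers =
    classification$enhancer_id[classification$macrophage_specific],
  responsive_enhancers = list(
    ifng = classification$enhancer_id[classification$responsive_ifng],
    il4il13 = classification$enhancer_id[classification$responsive_il4il13]),
  state_links = state_links,
  markers = markers)
report <- report_summary(pipe)
print(report, row.names = FALSE)
write.table(report, "results/report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim(file.path(dat, "truth_enhancers.tsv"))
truth_links <- read.delim(file.path(dat, "truth_links.tsv"))
mac_tr <- truth[truth$class == "macrophage", ]
active <- enh[enh$transcribed & enh$chip_supported, ]
matched <- vapply(seq_len(nrow(mac_tr)), function(i) {
  j <- which(active$chrom == mac_tr$chrom[i] &
               abs(active$midpoint - mac_tr$midpoint[i]) <= 100L)
  if (length(j)) active$id[j[1]] else NA_character_
}, character(1))
gl <- read.delim("results/gene_links.tsv")
recovered <- vapply(seq_len(nrow(mac_tr)), function(i) {
  !is.na(matched[i]) &&
    any(gl$enhancer_id == matched[i] & gl$gene_id == mac_tr$target_gene[i])
}, logical(1))
cat(sprintf("\nplanted-truth scoring: %.1f%% enhancers recovered, %.1f%% links recovered\n",
            pct_half_up(sum(!is.na(matched)), nrow(mac_tr), 1),
            pct_half_up(sum(recovered), nrow(mac_tr), 1)))

tads <- read_tads(file.path(dat, "tads.bed"))
ei <- match(links$enhancer_id, active$id)
ti <- match(links$tad_id, tads$id)
cross <- sum(!contained_within(active[ei, c("chrom", "start", "end")],
                               tads[ti, c("chrom", "start", "end")]))
cat(sprintf("links crossing a TAD boundary: %d of %d\n", cross,
            nrow(links)))
cat("wrote results/report.tsv\n")
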