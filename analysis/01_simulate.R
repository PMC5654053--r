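#!/usr/bin/env Rscript
# Stage 1: generate the synthetic macrophage CAGE study.
#
# Emits every input the downstream stages consume, in the standard formats
# (GTF gene models, BED TADs/chromatin states/repeats, narrowPeak TFBS
# summits, TSVs for counts and metadata) plus the planted-truth tables used
# for scoring. Seed comes from the ERNALINK_SEED environment variable
# (default 1); rerunning with the same seed reproduces every file.

suppressMessages(library(ernalink))

seed <- as.integer(Sys.getenv("ERNALINK_SEED", "1"))
out <- "results/data"

cfg <- sim_config(rng_seed = seed)
sim <- simulate_dataset(cfg)
write_dataset(sim, out)

tr <- sim$truth$enhancers
cat(sprintf("simulated %d samples (%d macrophage), %d genes, %d TADs\n",
            nrow(sim$samples),
            sum(sim$samples$group == "macrophage"),
            nrow(sim$genome$genes$genes), nrow(sim$genome$tads)))
cat(sprintf("planted: %d macrophage enhancers (%d specific, %d+%d responsive),\n",
            sum(tr$class == "macrophage"), sum(tr$specific),
            sum(tr$responsive == "ifng"), sum(tr$responsive == "il4il13")))
cat(sprintf("         %d non-macrophage enhancers, %d decoy peak pairs,\n",
            sum(tr$class == "non_macrophage"),
            nrow(sim$genome$decoy_slots)))
cat(sprintf("         %d planted + %d decoy TFs\n",
            sum(sim$truth$tfs$planted), sum(!sim$truth$tfs$planted)))
cat("wrote", out, "\n")
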