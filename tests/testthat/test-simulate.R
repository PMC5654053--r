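test_that("equal seeds give identical datasets; different seeds differ", {
  a <- simulate_dataset(sim_config(rng_seed = 42L))
  b <- simulate_dataset(sim_config(rng_seed = 42L))
  expect_identical(a$tss$counts, b$tss$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$chip, b$chip)
  c <- simulate_dataset(sim_config(rng_seed = 43L))
  expect_false(identical(a$tss$counts, c$tss$counts))
})

test_that("packing guards reject infeasible genomes", {
  expect_error(generate_genome(sim_config(tad_width_bp = 50000L)),
               "infeasible packing")
})

test_that("planted geometry: divergent arms inside TADs, decoys malformed", {
  sim <- default_sim()
  enh <- sim$truth$enhancers
  expect_true(all(enh$minus_summit < enh$plus_summit))
  expect_true(all(enh$plus_summit - enh$minus_summit <= 400L))
  tads <- sim$genome$tads
  iv <- genomic_intervals(enh$chrom, enh$midpoint - 200L,
                          enh$midpoint + 201L)
  tad_iv <- tads[match(enh$tad_id, tads$id), ]
  expect_true(all(contained_within(iv, tad_iv)))
  dec <- sim$genome$decoy_slots
  conv <- dec$kind == "convergent"
  expect_true(all(dec$minus_summit[conv] > dec$plus_summit[conv]))
  expect_true(all(dec$plus_summit[!conv] - dec$minus_summit[!conv] > 400L))
  # every planted link shares a TAD with its target gene
  gt <- sim$genome$gene_tad
  links <- sim$truth$links
  expect_equal(gt$tad_id[match(links$gene_id, gt$gene_id)], links$tad_id)
})

test_that("generator self-check: realized link correlation near target", {
  sim <- default_sim()
  mac <- sim$samples$sample_id[sim$samples$group == "macrophage"]
  tr <- sim$truth$enhancers
  mac_tr <- tr[tr$class == "macrophage", ]
  enh <- data.frame(id = mac_tr$truth_id, chrom = mac_tr$chrom,
                    start = mac_tr$midpoint - 200L,
                    end = mac_tr$midpoint + 201L,
                    midpoint = mac_tr$midpoint, stringsAsFactors = FALSE)
  er <- quantify_ernas(enh, sim$tss)
  pk <- suppressMessages(cluster_tss(sim$tss, 20L))
  asn <- assign_promoters(pk$peaks, sim$genome$genes)
  ge <- gene_expression(to_tpm(pk$counts), asn)
  rho <- vapply(seq_len(nrow(mac_tr)), function(i)
    cor(er[mac_tr$truth_id[i], mac], ge[mac_tr$target_gene[i], mac],
        method = "spearman"), numeric(1))
  cfg <- sim$config
  expect_lt(abs(median(rho) - cfg$link_rho_target), 0.1)
})

test_that("full chromatin support marks every planted enhancer", {
  sim <- simulate_dataset(sim_config(chip_support_frac = 1,
                                     n_tads_per_chrom = 4L,
                                     n_genes = 40L,
                                     n_planted_enhancers = 16L,
                                     n_nonmac_enhancers = 8L,
                                     n_decoy_peak_pairs = 16L,
                                     rng_seed = 3L))
  enh <- sim$truth$enhancers
  mac_enh <- enh[enh$class == "macrophage", ]
  regions <- data.frame(id = mac_enh$truth_id, chrom = mac_enh$chrom,
                        start = mac_enh$midpoint - 200L,
                        end = mac_enh$midpoint + 201L,
                        stringsAsFactors = FALSE)
  cf <- chip_filter(regions, sim$chip)
  expect_true(all(cf$chip_supported))
})

test_that("zero condition effect keeps responsive calls at the null rate", {
  sim <- simulate_dataset(sim_config(condition_effect_sd_units = 0))
  samples <- sim$samples
  untx <- samples$sample_id[samples$condition == "untreated"]
  stim <- samples$sample_id[samples$condition == "ifng"]
  tr <- sim$truth$enhancers
  mac_tr <- tr[tr$class == "macrophage", ]
  enh <- data.frame(id = mac_tr$truth_id, chrom = mac_tr$chrom,
                    start = mac_tr$midpoint - 200L,
                    end = mac_tr$midpoint + 201L,
                    midpoint = mac_tr$midpoint, stringsAsFactors = FALSE)
  etpm <- to_tpm(quantify_ernas(enh, sim$tss))
  called <- stimuli_responsive(etpm, stim, untx)
  # small-background z estimation keeps a ~1e-3 per-feature null rate;
  # a 3-sd binomial bound on 60 features allows at most a couple of calls
  expect_lte(length(called), 2L)
})

test_that("TFBS labels: planted summits inside enhancers, q filter works", {
  sim <- default_sim()
  enh <- sim$truth$enhancers
  spec <- enh[enh$specific %in% TRUE, ]
  regions <- data.frame(chrom = spec$chrom, start = spec$midpoint - 200L,
                        end = spec$midpoint + 201L, stringsAsFactors = FALSE)
  for (tf in sim$truth$tfs$tf[sim$truth$tfs$planted]) {
    sm <- sim$tfbs[[tf]]
    good <- sm[sm$q_value < 1e-4, ]
    # every low-q planted summit falls inside a specific planted enhancer
    hit <- vapply(seq_len(nrow(good)), function(i)
      any(regions$chrom == good$chrom[i] & regions$start <= good$pos[i] &
            good$pos[i] < regions$end), logical(1))
    expect_true(all(hit))
    expect_true(any(sm$q_value > 1e-4))  # junk summits present, filterable
  }
})

test_that("datasets round-trip through the standard file formats", {
  sim <- simulate_dataset(sim_config(n_tads_per_chrom = 4L, n_genes = 40L,
                                     n_planted_enhancers = 16L,
                                     n_nonmac_enhancers = 8L,
                                     n_decoy_peak_pairs = 16L,
                                     n_background_samples = 10L,
                                     rng_seed = 9L))
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  tss2 <- read_tss_counts(file.path(dir, "tss_counts.tsv"))
  expect_equal(tss2$positions, sim$tss$positions, ignore_attr = TRUE)
  expect_equal(unname(tss2$counts), unname(sim$tss$counts))
  gm2 <- read_gene_models(file.path(dir, "genes.gtf"))
  expect_setequal(gm2$genes$gene_id, sim$genome$genes$genes$gene_id)
  tss_by_tx <- setNames(sim$genome$genes$transcripts$tss,
                        sim$genome$genes$transcripts$transcript_id)
  expect_equal(setNames(gm2$transcripts$tss, gm2$transcripts$transcript_id)[
    names(tss_by_tx)], tss_by_tx)
  tads2 <- read_tads(file.path(dir, "tads.bed"))
  expect_equal(tads2$start, sim$genome$tads$start)
  chip2 <- read_chip_bed(file.path(dir, "chip_states.bed"))
  expect_equal(chip2$state, sim$chip$state)
  np <- read_narrowpeak(file.path(dir, "tfbs",
                                  paste0(names(sim$tfbs)[1],
                                         ".narrowPeak")))
  expect_equal(np$summit, sim$tfbs[[1]]$pos)
  expect_equal(np$q_value, sim$tfbs[[1]]$q_value, tolerance = 1e-10)
  mk <- read_marker_genes(file.path(dir, "marker_genes.tsv"))
  expect_setequal(mk$state, c("ifng", "il4il13"))
})
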