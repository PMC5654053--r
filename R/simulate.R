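# Seeded synthetic-data generator.
#
# Produces a miniature genome (genes, TADs, repeat exclusions), per-position
# stranded CAGE tag counts for macrophage and background samples, chromatin
# state intervals and TFBS summit sets, together with the planted ground
# truth against which every downstream stage can be scored. The sample
# structure mirrors a macrophage activation time-course: untreated,
# IFN-gamma-stimulated and IL-4/IL-13-stimulated macrophages plus a large
# non-macrophage background collection.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates:
#' 10 untreated + 16 IFN-gamma + 16 IL-4/IL-13 macrophage samples, 80
#' non-macrophage background samples, negative-binomial tag counts with a
#' shared log-normal activity factor inducing the target enhancer-promoter
#' Spearman correlation, a 5-standard-deviation condition effect in
#' stimulated samples, and chromatin/TFBS support for planted enhancers.
#'
#' @param n_chromosomes number of chromosomes.
#' @param n_tads_per_chrom TADs tiling each chromosome.
#' @param tad_width_bp TAD width in bp.
#' @param n_genes protein-coding genes (distributed round-robin over TADs).
#' @param n_planted_enhancers macrophage enhancers with a planted target
#'   gene link in the same TAD.
#' @param n_nonmac_enhancers enhancers transcribed only in background
#'   samples (background pool for TFBS enrichment).
#' @param n_decoy_peak_pairs convergent or over-spaced peak pairs that must
#'   not be called as enhancers.
#' @param n_untreated,n_ifng,n_il4il13 macrophage samples per condition.
#' @param n_background_samples non-macrophage samples.
#' @param nb_dispersion negative-binomial size parameter.
#' @param baseline_mean_tags mean promoter tag count per gene.
#' @param enhancer_mean_tags mean total eRNA tag count per enhancer.
#' @param link_rho_target target Spearman correlation of planted links.
#' @param activity_sdlog sd (log scale) of the latent activity shared by a
#'   planted enhancer and its target promoter; calibrated so the realized
#'   median Spearman rho of planted links is close to `link_rho_target`.
#' @param condition_effect_sd_units up-shift of responsive features in
#'   stimulated samples, in units of the untreated-sample SD.
#' @param specific_frac fraction of planted macrophage enhancers with
#'   macrophage-restricted eRNA expression.
#' @param responsive_frac fraction of planted macrophage enhancers
#'   responsive per activation state (two disjoint sets).
#' @param chip_support_frac fraction of planted macrophage enhancers
#'   covered by a chromatin-state interval.
#' @param chip_poised_frac fraction of covered enhancers whose interval is
#'   poised (H3K4me1 only) rather than active.
#' @param tf_planting_frac fraction of macrophage-specific planted
#'   enhancers that carry a summit of each planted TF.
#' @param n_planted_tfs,n_decoy_tfs TF counts.
#' @param decoy_summits_per_tf uniform summits per decoy TF.
#' @param rng_seed integer seed for the whole simulation.
#' @return list of configuration values (class `sim_config`).
#' @export
sim_config <- function(n_chromosomes = 2L,
                       n_tads_per_chrom = 10L,
                       tad_width_bp = 300000L,
                       n_genes = 200L,
                       n_planted_enhancers = 60L,
                       n_nonmac_enhancers = 60L,
                       n_decoy_peak_pairs = 120L,
                       n_untreated = 10L,
                       n_ifng = 16L,
                       n_il4il13 = 16L,
                       n_background_samples = 80L,
                       nb_dispersion = 10,
                       baseline_mean_tags = 100,
                       enhancer_mean_tags = 30,
                       link_rho_target = 0.8,
                       activity_sdlog = 0.4,
                       condition_effect_sd_units = 5,
                       specific_frac = 0.55,
                       responsive_frac = 0.2,
                       chip_support_frac = 0.95,
                       chip_poised_frac = 0.06,
                       tf_planting_frac = 0.5,
                       n_planted_tfs = 3L,
                       n_decoy_tfs = 20L,
                       decoy_summits_per_tf = 150L,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes > 0, cfg$n_planted_enhancers > 0,
            cfg$specific_frac >= 0, cfg$specific_frac <= 1,
            cfg$responsive_frac >= 0, cfg$responsive_frac <= 0.5,
            cfg$chip_support_frac >= 0, cfg$chip_support_frac <= 1,
            cfg$tf_planting_frac >= 0, cfg$tf_planting_frac <= 1,
            cfg$nb_dispersion > 0)
  structure(cfg, class = "sim_config")
}

# round-robin assignment of n items to k bins
rr_bins <- function(n, k) ((seq_len(n) - 1L) %% k) + 1L

#' Generate the miniature genome: genes, TADs and exclusions
#'
#' TADs tile each chromosome; genes, planted enhancer slots, decoy peak
#' slots and a repeat-like exclusion interval are laid out in
#' non-overlapping slots inside each TAD, so planted enhancer-promoter
#' pairs always share a TAD and features keep clear of each other's
#' masking windows.
#'
#' @param cfg a [sim_config()] object. Uses the current RNG state; seed
#'   via [simulate_dataset()] for reproducibility.
#' @return list(genes = gene_models, tads, exclusions, enh_slots,
#'   decoy_slots, gene_tad).
#' @export
generate_genome <- function(cfg) {
  n_tads <- cfg$n_chromosomes * cfg$n_tads_per_chrom
  tads <- data.frame(
    chrom = rep(paste0("chr", seq_len(cfg$n_chromosomes)),
                each = cfg$n_tads_per_chrom),
    start = rep((seq_len(cfg$n_tads_per_chrom) - 1L) * cfg$tad_width_bp,
                times = cfg$n_chromosomes),
    stringsAsFactors = FALSE)
  tads$end <- tads$start + cfg$tad_width_bp
  tads$id <- sprintf("tad_%03d", seq_len(n_tads))

  gene_bin <- rr_bins(cfg$n_genes, n_tads)
  mac_bin <- rr_bins(cfg$n_planted_enhancers, n_tads)
  non_bin <- rr_bins(cfg$n_nonmac_enhancers, n_tads)
  dec_bin <- rr_bins(cfg$n_decoy_peak_pairs, n_tads)

  genes_l <- list(); tx_l <- list(); ex_l <- list()
  enh_l <- list(); dec_l <- list(); excl_l <- list()
  gene_i <- 0L; mac_i <- 0L; non_i <- 0L; dec_i <- 0L

  for (t in seq_len(n_tads)) {
    items <- c(rep("gene", sum(gene_bin == t)),
               rep("enh_mac", sum(mac_bin == t)),
               rep("enh_non", sum(non_bin == t)),
               rep("decoy", sum(dec_bin == t)),
               "excl")
    items <- sample(items)
    u <- cfg$tad_width_bp %/% length(items)
    if (u < 12000L)
      stop("infeasible packing: ", length(items), " features in a ",
           cfg$tad_width_bp, " bp TAD")
    for (k in seq_along(items)) {
      slot0 <- tads$start[t] + (k - 1L) * u
      center <- slot0 + u %/% 2L + sample(-2000:2000, 1L)
      if (items[k] == "gene") {
        gene_i <- gene_i + 1L
        gid <- sprintf("gene_%03d", gene_i)
        strand <- sample(c("+", "-"), 1L)
        span <- sample(4000:8000, 1L)
        gstart <- slot0 + 3000L + sample(0:500, 1L)
        gend <- gstart + span
        n_tx <- sample(1:3, 1L)
        offs <- sort(sample(seq(0L, 1000L, by = 25L), n_tx))
        eoffs <- c(0L, sample(seq(25L, 800L, by = 25L), n_tx))[seq_len(n_tx)]
        for (j in seq_len(n_tx)) {
          txid <- sprintf("%s_tx%d", gid, j)
          ts <- gstart + offs[j]
          te <- gend - eoffs[j]
          tss <- if (strand == "+") ts else te - 1L
          tx_l[[length(tx_l) + 1L]] <- data.frame(
            transcript_id = txid, gene_id = gid, chrom = tads$chrom[t],
            strand = strand, tss = tss, stringsAsFactors = FALSE)
          ne <- sample(2:4, 1L)
          brk <- sort(sample(seq(ts + 300L, te - 300L, by = 50L),
                             2L * (ne - 1L)))
          es <- c(ts, brk[seq(2L, length(brk), by = 2L)])
          ee <- c(brk[seq(1L, length(brk), by = 2L)], te)
          ex_l[[length(ex_l) + 1L]] <- data.frame(
            chrom = tads$chrom[t], start = es, end = ee, strand = strand,
            gene_id = gid, transcript_id = txid, stringsAsFactors = FALSE)
        }
        genes_l[[length(genes_l) + 1L]] <- data.frame(
          gene_id = gid, biotype = "protein_coding", chrom = tads$chrom[t],
          strand = strand, tad_id = tads$id[t], stringsAsFactors = FALSE)
      } else if (items[k] %in% c("enh_mac", "enh_non")) {
        cls <- if (items[k] == "enh_mac") "macrophage" else "non_macrophage"
        idx <- if (cls == "macrophage") (mac_i <- mac_i + 1L)
               else (non_i <- non_i + 1L)
        sep <- sample(100:300, 1L)
        ms <- center - sep %/% 2L
        ps <- ms + sep
        enh_l[[length(enh_l) + 1L]] <- data.frame(
          truth_id = sprintf("%s_%03d",
                             if (cls == "macrophage") "tenh" else "nenh",
                             idx),
          class = cls, chrom = tads$chrom[t], tad_id = tads$id[t],
          minus_summit = ms, plus_summit = ps,
          midpoint = (ms + ps) %/% 2L, stringsAsFactors = FALSE)
      } else if (items[k] == "decoy") {
        dec_i <- dec_i + 1L
        kind <- sample(c("convergent", "distant"), 1L)
        if (kind == "convergent") {
          sep <- sample(100:300, 1L)
          plus <- center - sep %/% 2L
          minus <- plus + sep
        } else {
          sep <- sample(500:1500, 1L)
          minus <- center - sep %/% 2L
          plus <- minus + sep
        }
        dec_l[[length(dec_l) + 1L]] <- data.frame(
          decoy_id = sprintf("decoy_%03d", dec_i), kind = kind,
          chrom = tads$chrom[t], minus_summit = minus, plus_summit = plus,
          stringsAsFactors = FALSE)
      } else {
        excl_l[[length(excl_l) + 1L]] <- data.frame(
          chrom = tads$chrom[t], start = center - 750L, end = center + 750L,
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, genes_l)
  gm <- gene_models(genes[c("gene_id", "biotype", "chrom", "strand")],
                    do.call(rbind, tx_l), do.call(rbind, ex_l))
  list(genes = gm,
       tads = tads,
       exclusions = do.call(rbind, excl_l),
       enh_slots = do.call(rbind, enh_l),
       decoy_slots = do.call(rbind, dec_l),
       gene_tad = genes[c("gene_id", "tad_id")])
}

# sample metadata table for the emulated study
sim_samples <- function(cfg) {
  times <- rep(c(0.5, 1, 2, 4, 8, 12, 16, 24), length.out = cfg$n_ifng)
  data.frame(
    sample_id = c(sprintf("mac_untx_%02d", seq_len(cfg$n_untreated)),
                  sprintf("mac_ifng_%02d", seq_len(cfg$n_ifng)),
                  sprintf("mac_il4_%02d", seq_len(cfg$n_il4il13)),
                  sprintf("bg_%03d", seq_len(cfg$n_background_samples))),
    group = c(rep("macrophage", cfg$n_untreated + cfg$n_ifng +
                    cfg$n_il4il13),
              rep("non_macrophage", cfg$n_background_samples)),
    condition = c(rep("untreated", cfg$n_untreated),
                  rep("ifng", cfg$n_ifng),
                  rep("il4il13", cfg$n_il4il13),
                  rep("none", cfg$n_background_samples)),
    time_h = c(rep(0, cfg$n_untreated), times,
               rep(times, length.out = cfg$n_il4il13),
               rep(NA_real_, cfg$n_background_samples)),
    stringsAsFactors = FALSE)
}

#' Generate per-position CAGE counts, sample metadata and planted truth
#'
#' Promoter TSSs draw negative-binomial counts around gene-specific means;
#' each planted macrophage enhancer shares a log-normal latent activity
#' with the promoters of its target gene (same TAD) across macrophage
#' samples, inducing the configured Spearman correlation. Responsive
#' features gain a condition effect (in untreated-SD units) in the
#' corresponding stimulated samples; macrophage-specific features are
#' near-silent in background samples; decoy peak pairs are convergent or
#' too far apart to be called.
#'
#' @param cfg [sim_config()] object.
#' @param genome output of [generate_genome()].
#' @return list(tss = tss_counts, samples, truth).
#' @export
generate_expression <- function(cfg, genome) {
  samples <- sim_samples(cfg)
  sid <- samples$sample_id
  mac <- sid[samples$group == "macrophage"]
  untx <- sid[samples$condition == "untreated"]
  ifng <- sid[samples$condition == "ifng"]
  il4 <- sid[samples$condition == "il4il13"]
  bg <- sid[samples$group == "non_macrophage"]
  ns <- length(sid)

  enh <- genome$enh_slots
  mac_enh <- enh[enh$class == "macrophage", , drop = FALSE]
  n_mac <- nrow(mac_enh)

  # planted truth labels
  n_spec <- round(cfg$specific_frac * n_mac)
  spec_ids <- sample(mac_enh$truth_id, n_spec)
  n_resp <- round(cfg$responsive_frac * n_mac)
  resp_pool <- sample(mac_enh$truth_id, 2L * n_resp)
  resp_ifng <- resp_pool[seq_len(n_resp)]
  resp_il4 <- resp_pool[n_resp + seq_len(n_resp)]

  # planted links: one distinct target gene per macrophage enhancer,
  # drawn from the genes of its own TAD
  gene_tad <- genome$gene_tad
  target <- character(n_mac)
  for (t in unique(mac_enh$tad_id)) {
    ei <- which(mac_enh$tad_id == t)
    pool <- gene_tad$gene_id[gene_tad$tad_id == t]
    target[ei] <- sample(pool, length(ei))
  }

  enh$specific <- enh$truth_id %in% spec_ids
  enh$responsive <- ifelse(enh$truth_id %in% resp_ifng, "ifng",
                           ifelse(enh$truth_id %in% resp_il4, "il4il13",
                                  "none"))
  enh$target_gene <- NA_character_
  enh$target_gene[enh$class == "macrophage"] <- target

  tx <- genome$genes$transcripts
  gene_strand <- stats::setNames(genome$genes$genes$strand,
                                 genome$genes$genes$gene_id)
  gene_ids <- genome$genes$genes$gene_id
  mu_gene <- stats::setNames(
    stats::rlnorm(length(gene_ids), log(cfg$baseline_mean_tags), 0.5),
    gene_ids)
  n_tx_of <- table(tx$gene_id)
  r <- cfg$nb_dispersion
  # SD of an untreated-sample count for a link-carrying unit with base mean
  # mu: NB sampling noise plus the log-normal latent-activity variance
  el <- exp(cfg$activity_sdlog^2 / 2)
  el2 <- exp(2 * cfg$activity_sdlog^2)
  nb_sd <- function(mu)
    sqrt(mu * el + (mu^2 / r) * el2 + mu^2 * (el2 - el^2))

  # latent activity per planted link and macrophage sample
  lambda <- matrix(exp(cfg$activity_sdlog *
                         stats::rnorm(n_mac * length(mac))),
                   nrow = n_mac, dimnames = list(mac_enh$truth_id, mac))
  resp_gene <- stats::setNames(enh$responsive[enh$class == "macrophage"],
                               target)

  units <- list()      # unit descriptor rows
  unit_mean <- list()  # per-sample mean vectors
  # background (non-macrophage) samples span many tissues: every unit gets
  # per-sample log-normal expression heterogeneity there, so cross-tissue
  # variance is realistic and z-score backgrounds are not degenerate
  add_unit <- function(id, chrom, strand, positions, weights, mean_vec) {
    mean_vec[bg] <- mean_vec[bg] *
      exp(cfg$activity_sdlog * stats::rnorm(length(bg)))
    units[[length(units) + 1L]] <<- data.frame(
      id = id, chrom = chrom, strand = strand,
      pos = I(list(positions)), w = I(list(weights)),
      stringsAsFactors = FALSE)
    unit_mean[[length(unit_mean) + 1L]] <<- mean_vec
  }

  # promoter units: one per transcript
  for (i in seq_len(nrow(tx))) {
    g <- tx$gene_id[i]
    mu <- mu_gene[g] / n_tx_of[g]
    m <- stats::setNames(rep(mu, ns), sid)
    tid <- which(enh$target_gene %in% g)
    if (length(tid)) {
      m[mac] <- mu * lambda[enh$truth_id[tid[1]], mac]
      rs <- enh$responsive[tid[1]]
      if (rs == "ifng") m[ifng] <- m[ifng] +
          cfg$condition_effect_sd_units * nb_sd(mu)
      if (rs == "il4il13") m[il4] <- m[il4] +
          cfg$condition_effect_sd_units * nb_sd(mu)
    }
    strand <- tx$strand[i]
    tss <- tx$tss[i]
    positions <- if (strand == "+") tss + c(0L, 3L, 8L) else
      tss - c(0L, 3L, 8L)
    add_unit(paste0("prom_", tx$transcript_id[i]), tx$chrom[i], strand,
             positions, c(0.6, 0.3, 0.1), m)
  }

  # enhancer arm units (divergent: minus left, plus right)
  for (i in seq_len(nrow(enh))) {
    arm_mu <- cfg$enhancer_mean_tags / 2
    for (arm in c("minus", "plus")) {
      s <- if (arm == "minus") enh$minus_summit[i] else enh$plus_summit[i]
      strand <- if (arm == "minus") "-" else "+"
      m <- stats::setNames(numeric(ns), sid)
      if (enh$class[i] == "macrophage") {
        m[mac] <- arm_mu * lambda[enh$truth_id[i], mac]
        m[bg] <- if (enh$specific[i]) 0.02 else arm_mu * 1.5
        if (enh$responsive[i] == "ifng")
          m[ifng] <- m[ifng] + cfg$condition_effect_sd_units * nb_sd(arm_mu)
        if (enh$responsive[i] == "il4il13")
          m[il4] <- m[il4] + cfg$condition_effect_sd_units * nb_sd(arm_mu)
      } else {
        m[mac] <- 0.02
        m[bg] <- arm_mu * 1.5
      }
      positions <- if (arm == "minus") s - c(0L, 4L, 9L) else
        s + c(0L, 4L, 9L)
      add_unit(paste0(enh$truth_id[i], "_", arm), enh$chrom[i], strand,
               positions, c(0.6, 0.3, 0.1), m)
    }
  }

  # decoy peak pairs: same expression everywhere, wrong geometry
  dec <- genome$decoy_slots
  for (i in seq_len(nrow(dec))) {
    for (arm in c("minus", "plus")) {
      s <- if (arm == "minus") dec$minus_summit[i] else dec$plus_summit[i]
      strand <- if (arm == "minus") "-" else "+"
      mu <- stats::rlnorm(1, log(20), 0.4)
      positions <- if (arm == "minus") s - c(0L, 5L) else s + c(0L, 5L)
      add_unit(paste0(dec$decoy_id[i], "_", arm), dec$chrom[i], strand,
               positions, c(0.7, 0.3),
               stats::setNames(rep(mu, ns), sid))
    }
  }

  units <- do.call(rbind, units)
  mean_mat <- do.call(rbind, unit_mean)

  # expand unit means to per-position means and draw NB counts
  n_pos_per_unit <- lengths(units$pos)
  pos_df <- data.frame(
    chrom = rep(units$chrom, n_pos_per_unit),
    pos = unlist(units$pos),
    strand = rep(units$strand, n_pos_per_unit),
    stringsAsFactors = FALSE)
  w <- unlist(units$w)
  pos_mean <- mean_mat[rep(seq_len(nrow(units)), n_pos_per_unit), ,
                       drop = FALSE] * w
  counts <- matrix(
    stats::rnbinom(length(pos_mean), size = r, mu = as.numeric(pos_mean)),
    nrow = nrow(pos_mean), dimnames = list(NULL, sid))
  tss <- tss_counts(pos_df, counts)

  truth_links <- data.frame(
    truth_id = mac_enh$truth_id,
    gene_id = target,
    tad_id = mac_enh$tad_id,
    stringsAsFactors = FALSE)

  list(tss = tss, samples = samples,
       truth = list(enhancers = enh, links = truth_links,
                    responsive_genes = data.frame(
                      gene_id = target,
                      state = enh$responsive[enh$class == "macrophage"],
                      stringsAsFactors = FALSE)))
}

#' Generate chromatin-state intervals and TFBS summit sets
#'
#' Chromatin intervals cover `chip_support_frac` of the planted macrophage
#' enhancers (mostly active, a poised minority) plus a weakly supported
#' subset of the non-macrophage enhancers and background decoy intervals.
#' Planted TFs receive low-q summits inside `tf_planting_frac` of the
#' macrophage-specific planted enhancers (plus a few high-q summits that
#' must be filtered out); decoy TFs receive uniform summits.
#'
#' @param cfg [sim_config()] object.
#' @param genome output of [generate_genome()].
#' @param truth truth list from [generate_expression()].
#' @return list(chip, tfbs, tf_expression, tf_truth); `tfbs` is a named
#'   list of data.frames (chrom, pos, q_value) per TF.
#' @export
generate_chip_and_tfbs <- function(cfg, genome, truth) {
  enh <- truth$enhancers
  mac_enh <- enh[enh$class == "macrophage", , drop = FALSE]
  non_enh <- enh[enh$class == "non_macrophage", , drop = FALSE]
  genome_len <- cfg$n_tads_per_chrom * cfg$tad_width_bp

  n_cov <- round(cfg$chip_support_frac * nrow(mac_enh))
  covered <- sample(mac_enh$truth_id, n_cov)
  n_poised <- round(cfg$chip_poised_frac * n_cov)
  poised <- sample(covered, n_poised)
  chip_l <- list()
  for (i in which(enh$truth_id %in% covered)) {
    chip_l[[length(chip_l) + 1L]] <- data.frame(
      chrom = enh$chrom[i],
      start = enh$midpoint[i] - 200L - sample(0:300, 1L),
      end = enh$midpoint[i] + 201L + sample(0:300, 1L),
      state = if (enh$truth_id[i] %in% poised) "poised" else "active",
      stringsAsFactors = FALSE)
  }
  non_cov <- sample(non_enh$truth_id, round(0.2 * nrow(non_enh)))
  for (i in which(enh$truth_id %in% non_cov)) {
    chip_l[[length(chip_l) + 1L]] <- data.frame(
      chrom = enh$chrom[i], start = enh$midpoint[i] - 300L,
      end = enh$midpoint[i] + 301L, state = "active",
      stringsAsFactors = FALSE)
  }
  # unrelated background intervals in repeat-free intergenic space
  excl <- genome$exclusions
  for (i in seq_len(nrow(excl))) {
    if (i %% 2L == 0L) next
    chip_l[[length(chip_l) + 1L]] <- data.frame(
      chrom = excl$chrom[i], start = excl$end[i] + 2000L,
      end = excl$end[i] + 2600L,
      state = sample(c("active", "poised"), 1L), stringsAsFactors = FALSE)
  }
  chip <- do.call(rbind, chip_l)

  enh$chip_covered <- enh$truth_id %in% c(covered, non_cov)
  enh$chip_state <- ifelse(!enh$chip_covered, "none",
                           ifelse(enh$truth_id %in% poised, "poised",
                                  "active"))

  spec_enh <- mac_enh[mac_enh$truth_id %in%
                        enh$truth_id[enh$specific], , drop = FALSE]
  tfbs <- list()
  tf_truth <- list()
  tf_expression <- numeric(0)
  for (k in seq_len(cfg$n_planted_tfs)) {
    tf <- sprintf("tf_planted_%02d", k)
    hit <- sample(seq_len(nrow(spec_enh)),
                  round(cfg$tf_planting_frac * nrow(spec_enh)))
    good <- data.frame(
      chrom = spec_enh$chrom[hit],
      pos = spec_enh$midpoint[hit] + sample(-150:150, length(hit),
                                            replace = TRUE),
      q_value = 1e-6, stringsAsFactors = FALSE)
    junk <- data.frame(
      chrom = sample(paste0("chr", seq_len(cfg$n_chromosomes)), 10L,
                     replace = TRUE),
      pos = sample.int(genome_len, 10L),
      q_value = 1e-2, stringsAsFactors = FALSE)
    tfbs[[tf]] <- rbind(good, junk)
    tf_truth[[tf]] <- data.frame(tf = tf, planted = TRUE)
    tf_expression[tf] <- stats::rlnorm(1, log(50), 0.3)
  }
  for (k in seq_len(cfg$n_decoy_tfs)) {
    tf <- sprintf("tf_decoy_%02d", k)
    tfbs[[tf]] <- data.frame(
      chrom = sample(paste0("chr", seq_len(cfg$n_chromosomes)),
                     cfg$decoy_summits_per_tf, replace = TRUE),
      pos = sample.int(genome_len, cfg$decoy_summits_per_tf),
      q_value = 1e-6, stringsAsFactors = FALSE)
    tf_truth[[tf]] <- data.frame(tf = tf, planted = FALSE)
    tf_expression[tf] <- stats::rlnorm(1, log(5), 0.3)
  }
  list(chip = chip, tfbs = tfbs, tf_expression = tf_expression,
       tf_truth = do.call(rbind, tf_truth), enhancers = enh)
}

#' Run the full seeded simulation
#'
#' @param cfg [sim_config()] object; `cfg$rng_seed` drives every random
#'   choice, so equal seeds give byte-identical datasets.
#' @return list(config, genome, tss, samples, chip, tfbs, tf_expression,
#'   truth) where `truth` holds planted enhancers (with chip labels),
#'   links, responsive genes and TF labels.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  with_local_seed(cfg$rng_seed, {
    genome <- generate_genome(cfg)
    expr <- generate_expression(cfg, genome)
    ct <- generate_chip_and_tfbs(cfg, genome, expr$truth)
    truth <- expr$truth
    truth$enhancers <- ct$enhancers
    truth$tfs <- ct$tf_truth
    list(config = cfg, genome = genome, tss = expr$tss,
         samples = expr$samples, chip = ct$chip, tfbs = ct$tfbs,
         tf_expression = ct$tf_expression, truth = truth)
  })
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits the input formats the analysis consumes: a GTF of gene models,
#' BED3 TADs, BED4 chromatin states, per-TF narrowPeak summits, TSVs for
#' TSS positions/counts, sample metadata, TF expression and marker genes,
#' and truth tables.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(sim$genome$genes, file.path(dir, "genes.gtf"))
  write_bed(sim$genome$tads[c("chrom", "start", "end", "id")] |>
              stats::setNames(c("chrom", "start", "end", "name")),
            file.path(dir, "tads.bed"))
  write_bed(stats::setNames(sim$chip, c("chrom", "start", "end", "name")),
            file.path(dir, "chip_states.bed"))
  write_bed(sim$genome$exclusions, file.path(dir, "repeats.bed"))
  pos <- sim$tss$positions
  utils::write.table(
    data.frame(pos, sim$tss$counts, check.names = FALSE),
    file.path(dir, "tss_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tf_dir <- file.path(dir, "tfbs")
  dir.create(tf_dir, showWarnings = FALSE)
  for (tf in names(sim$tfbs)) {
    df <- sim$tfbs[[tf]]
    write_narrowpeak(
      data.frame(chrom = df$chrom, start = df$pos - 100L,
                 end = df$pos + 100L, name = tf, summit = df$pos,
                 q_value = df$q_value, stringsAsFactors = FALSE),
      file.path(tf_dir, paste0(tf, ".narrowPeak")))
  }
  utils::write.table(
    data.frame(tf = names(sim$tf_expression),
               mean_tpm = as.numeric(sim$tf_expression)),
    file.path(dir, "tf_expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  mk <- sim_marker_genes(sim$truth)
  utils::write.table(mk, file.path(dir, "marker_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- sim$truth$enhancers
  utils::write.table(tr, file.path(dir, "truth_enhancers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$links, file.path(dir, "truth_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$tfs, file.path(dir, "truth_tfs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Marker gene panel implied by the planted truth
#'
#' The target genes of enhancers responsive in exactly one activation
#' state, labelled with that state — the synthetic analogue of a
#' literature-derived activation marker panel.
#'
#' @param truth truth list from [simulate_dataset()].
#' @return data.frame(gene_id, state).
#' @export
sim_marker_genes <- function(truth) {
  rg <- truth$responsive_genes
  rg <- rg[rg$state != "none", , drop = FALSE]
  unique(rg[c("gene_id", "state")])
}

#' Read a per-position TSS count TSV written by [write_dataset()]
#' @param path TSV with chrom, pos, strand then sample columns.
#' @return [tss_counts()] object.
#' @export
read_tss_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(m) <- "integer"
  tss_counts(df[1:3], m)
}
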