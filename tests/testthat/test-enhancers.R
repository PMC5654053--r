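two_sample_counts <- function(ids, pooled) {
  matrix(c(pooled, rep(0, length(pooled))), ncol = 2,
         dimnames = list(ids, c("s1", "s2")))
}

peak_df <- function(strand, summit, chrom = "chr1") {
  n <- length(summit)
  data.frame(id = sprintf("pk%d", seq_len(n)), chrom = chrom,
             start = summit - 5L, end = summit + 6L, strand = strand,
             summit = summit, stringsAsFactors = FALSE)
}

test_that("TSS clustering splits on gaps and takes the leftmost tied summit", {
  counts <- matrix(c(5, 5, 9, 1), ncol = 1, dimnames = list(NULL, "s1"))
  tc <- tss_counts(data.frame(chrom = "chr1",
                              pos = c(100L, 105L, 200L, 210L),
                              strand = "+", stringsAsFactors = FALSE),
                   counts)
  cp <- cluster_tss(tc, max_gap = 20L)
  expect_equal(nrow(cp$peaks), 2L)       # 100/105 merge; 200/210 separate
  expect_equal(cp$peaks$summit, c(100L, 200L))  # tie 5/5 -> leftmost
  expect_equal(cp$peaks$start, c(100L, 200L))
  expect_equal(cp$peaks$end, c(106L, 211L))
  expect_equal(unname(cp$counts[, "s1"]), c(10, 10))

  cp2 <- cluster_tss(tc, max_gap = 200L)
  expect_equal(nrow(cp2$peaks), 1L)
})

test_that("gene-proximal peaks are masked by TSS and exon windows", {
  gm <- tiny_gene_models()  # tss at 1000/1300/9999, exons up to [8000,10000)
  pk <- peak_df("+", c(545L, 1700L, 4000L, 7850L, 8500L))
  # peak 1: edge 550 -> 450 bp from tss 1000 => excluded
  # peak 2: inside exon [1300,2500) => excluded (overlap, distance 0)
  # peak 3: ~1496 bp from nearest exon, >500 from any tss => retained
  # peak 4: edge 7855 -> 145 bp from exon [8000,10000) => excluded
  # peak 5: overlaps exon => excluded
  cp <- cage_peaks(pk, two_sample_counts(pk$id, rep(1, 5)))
  kept <- mask_peaks(cp, gm, 500L, 200L)
  expect_equal(kept$peaks$id, "pk3")
})

test_that("divergent pairing arithmetic and orientation rules", {
  # minus summit 1000, plus summit 1200 -> midpoint 1100, region [900,1301)
  pk <- peak_df(c("-", "+"), c(1000L, 1200L))
  cp <- cage_peaks(pk, two_sample_counts(pk$id, c(10, 10)))
  enh <- call_bidirectional(cp)
  expect_equal(nrow(enh), 1L)
  expect_equal(enh$midpoint, 1100L)
  expect_equal(c(enh$start, enh$end), c(900L, 1301L))
  expect_equal(enh$end - enh$start, 401L)
  expect_equal(enh$directionality, 0)

  # convergent orientation yields nothing
  pk2 <- peak_df(c("+", "-"), c(1000L, 1200L))
  cp2 <- cage_peaks(pk2, two_sample_counts(pk2$id, c(10, 10)))
  expect_equal(nrow(call_bidirectional(cp2)), 0L)

  # separation 401 exceeds the 400-bp gap
  pk3 <- peak_df(c("-", "+"), c(1000L, 1401L))
  cp3 <- cage_peaks(pk3, two_sample_counts(pk3$id, c(10, 10)))
  expect_equal(nrow(call_bidirectional(cp3)), 0L)
  # separation exactly 400 is allowed
  pk4 <- peak_df(c("-", "+"), c(1000L, 1400L))
  cp4 <- cage_peaks(pk4, two_sample_counts(pk4$id, c(10, 10)))
  expect_equal(nrow(call_bidirectional(cp4)), 1L)
})

test_that("one-sided candidates fail the directionality cutoff", {
  pk <- peak_df(c("-", "+"), c(1000L, 1200L))
  cp <- cage_peaks(pk, two_sample_counts(pk$id, c(1, 100)))
  # D = (100 - 1) / 101 = 0.980 >= 0.8
  expect_equal(nrow(call_bidirectional(cp)), 0L)
  expect_equal(nrow(call_bidirectional(cp, dmax = 0.99)), 1L)
})

test_that("caller output matches the brute-force oracle on random inputs", {
  set.seed(101)
  for (i in 1:40) {
    cp <- random_peak_set()
    got <- suppressMessages(call_bidirectional(cp))
    want <- oracle_call_bidirectional(cp$peaks, cp$counts)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      cols <- c("chrom", "start", "end", "midpoint", "minus_peak_id",
                "plus_peak_id")
      expect_equal(got[cols], want[cols], ignore_attr = TRUE)
      expect_equal(got$directionality, want$directionality,
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_true(all(got$end - got$start == 401L))
      expect_true(all(abs(got$directionality) < 0.8))
    }
  }
})

test_that("no called enhancer midpoint survives near a protein-coding TSS", {
  sim <- default_sim()
  pk <- suppressMessages(cluster_tss(sim$tss, 20L))
  masked <- mask_peaks(pk, sim$genome$genes)
  enh <- suppressMessages(call_bidirectional(masked))
  tss <- protein_coding(sim$genome$genes)$transcripts$tss
  chrom <- protein_coding(sim$genome$genes)$transcripts$chrom
  for (i in seq_len(nrow(enh))) {
    d <- abs(tss[chrom == enh$chrom[i]] - enh$midpoint[i])
    expect_gt(min(d), 500L)
  }
})

test_that("eRNA quantification counts only the divergent configuration", {
  # enhancer [900,1301), midpoint 1100
  enh <- data.frame(id = "e1", chrom = "chr1", start = 900L, end = 1301L,
                    midpoint = 1100L, stringsAsFactors = FALSE)
  counts <- matrix(c(3, 5, 7, 2), ncol = 1, dimnames = list(NULL, "s1"))
  tc <- tss_counts(data.frame(
    chrom = "chr1", pos = c(1000L, 1200L, 1000L, 1200L),
    strand = c("-", "+", "+", "-"), stringsAsFactors = FALSE), counts)
  m <- quantify_ernas(enh, tc)
  # minus 3 tags left + plus 5 tags right; plus@left and minus@right ignored
  expect_equal(m["e1", "s1"], 8)
  tc0 <- tss_counts(data.frame(chrom = "chr1", pos = 5000L, strand = "+",
                               stringsAsFactors = FALSE),
                    matrix(9, dimnames = list(NULL, "s1")))
  expect_equal(quantify_ernas(enh, tc0)["e1", "s1"], 0)
})

test_that("transcription flag uses the at-least-ceiling rule", {
  n <- 184L
  ids <- sprintf("m%03d", 1:n)
  mk <- function(k) {
    m <- matrix(0, 1, n, dimnames = list("e", ids))
    if (k > 0) m[1, seq_len(k)] <- 2
    m
  }
  expect_true(flag_transcribed(mk(19L), ids)[["e"]])
  expect_false(flag_transcribed(mk(18L), ids)[["e"]])
  expect_false(flag_transcribed(mk(0L), ids)[["e"]])
})

test_that("chromatin support prefers the active state on any overlap", {
  enh <- data.frame(id = c("e1", "e2", "e3"), chrom = "chr1",
                    start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L),
                    stringsAsFactors = FALSE)
  chip <- data.frame(chrom = "chr1", start = c(199L, 400L, 450L),
                     end = c(300L, 550L, 520L),
                     state = c("active", "poised", "poised"),
                     stringsAsFactors = FALSE)
  cf <- chip_filter(enh, chip)
  expect_equal(cf$chip_supported, c(TRUE, TRUE, FALSE))  # 1-bp overlap counts
  expect_equal(cf$chip_state, c("active", "poised", "none"))
  # active wins over poised when both overlap
  chip2 <- rbind(chip, data.frame(chrom = "chr1", start = 500L, end = 600L,
                                  state = "active"))
  expect_equal(chip_filter(enh, chip2)$chip_state[2], "active")
})
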