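# Shared fixtures. The default synthetic run (seed 1) is computed once and
# reused by every test that scores recovery against the planted truth.

.run_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.run_cache$sim))
    .run_cache$sim <- simulate_dataset(sim_config())
  .run_cache$sim
}

default_pipeline <- function() {
  if (is.null(.run_cache$pipe)) {
    sim <- default_sim()
    .run_cache$pipe <- suppressMessages(
      run_pipeline(sim, markers = sim_marker_genes(sim$truth)))
  }
  .run_cache$pipe
}

# called enhancer ids matched to each planted macrophage enhancer
# (midpoint within tol bp), NA where unmatched
match_planted <- function(called, truth_enh, tol = 100L) {
  vapply(seq_len(nrow(truth_enh)), function(i) {
    j <- which(called$chrom == truth_enh$chrom[i] &
                 abs(called$midpoint - truth_enh$midpoint[i]) <= tol)
    if (length(j)) called$id[j[1]] else NA_character_
  }, character(1))
}

# tiny two-gene model used across reader and masking tests
tiny_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), biotype = "protein_coding",
    chrom = "chr1", strand = c("+", "-"), stringsAsFactors = FALSE)
  tx <- data.frame(
    transcript_id = c("gA_t1", "gA_t2", "gB_t1"),
    gene_id = c("gA", "gA", "gB"), chrom = "chr1",
    strand = c("+", "+", "-"), tss = c(1000L, 1300L, 9999L),
    stringsAsFactors = FALSE)
  ex <- data.frame(
    chrom = "chr1",
    start = c(1000L, 2000L, 1300L, 8000L),
    end = c(1500L, 2500L, 2500L, 10000L),
    strand = c("+", "+", "+", "-"),
    gene_id = c("gA", "gA", "gA", "gB"),
    transcript_id = c("gA_t1", "gA_t1", "gA_t2", "gB_t1"),
    stringsAsFactors = FALSE)
  gene_models(genes, tx, ex)
}
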