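# Genomic interval primitives and flat-file readers/writers.
#
# All coordinates inside the package are 0-based half-open (BED convention).
# Intervals travel as plain data frames with columns chrom/start/end and
# optional strand; GenomicRanges does the heavy interval work behind
# small conversion helpers.

#' Build a genomic interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `end > start`.
#' @param strand optional strand ("+", "-", "*"); defaults to "*".
#' @param ... further equal-length columns (e.g. `id`).
#' @return data.frame with validated interval columns.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be integers")
  if (any(start < 0L)) stop("start must be non-negative")
  if (any(end <= start)) stop("end must be greater than start")
  if (is.null(strand)) strand <- rep("*", length(chrom))
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be +, - or *")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             ..., stringsAsFactors = FALSE)
}

#' Convert an interval data frame to GRanges (internal)
#'
#' 0-based half-open columns become the 1-based closed GRanges convention.
#' @keywords internal
#' @noRd
as_gr <- function(df, keep_strand = TRUE) {
  strand <- if (keep_strand && !is.null(df$strand)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Pairwise interval overlap test
#'
#' `a` and `b` are interval data frames of equal length (or length one,
#' recycled). Strand is ignored.
#'
#' @param a,b interval data frames.
#' @param min_bp minimum intersection width in bp (>= 1).
#' @return logical vector.
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  if (min_bp < 1L) stop("min_bp must be >= 1")
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  inter <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  a$chrom[ai] == b$chrom[bi] & inter >= min_bp
}

#' Pairwise interval containment test
#'
#' True where interval `a` lies entirely within interval `b` on the same
#' chromosome (boundary-touching counts as contained).
#'
#' @inheritParams overlaps
#' @return logical vector.
#' @export
contained_within <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    b$start[bi] <= a$start[ai] & a$end[ai] <= b$end[bi]
}

#' Which query intervals overlap any subject interval
#' @keywords internal
#' @noRd
overlap_any <- function(query, subject, min_bp = 1L) {
  GenomicRanges::countOverlaps(as_gr(query, FALSE), as_gr(subject, FALSE),
                               minoverlap = min_bp) > 0L
}

#' Distance from each query interval to the nearest subject interval
#'
#' Distance is the coordinate distance between the closest bases: 0 for
#' overlapping features, 1 for directly adjacent ones. Queries with no
#' subject on their chromosome get Inf. Strand is ignored.
#' @keywords internal
#' @noRd
nearest_feature_distance <- function(query, subject) {
  qg <- as_gr(query, FALSE)
  sg <- as_gr(subject, FALSE)
  d <- rep(Inf, nrow(query))
  if (nrow(subject) == 0L) return(d)
  hits <- GenomicRanges::distanceToNearest(qg, sg)
  qi <- S4Vectors::queryHits(hits)
  dd <- S4Vectors::mcols(hits)$distance
  ov <- GenomicRanges::countOverlaps(qg, sg) > 0L
  d[qi] <- dd + 1L
  d[ov] <- 0
  d
}

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
}

parse_int_field <- function(x, line_no, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad))
    stop(sprintf("line %d: non-integer %s '%s'", line_no[bad[1]], what,
                 x[bad[1]]))
  v
}

#' Read a BED file
#'
#' Supports BED3/BED4/BED6 (and wider; extra columns beyond 6 are ignored).
#' Coordinates are returned exactly as stored (0-based half-open). Malformed
#' lines raise an error naming the offending line.
#'
#' @param path BED file path.
#' @param expected_columns minimum number of columns required (>= 3).
#' @return data.frame with chrom/start/end and, when present, name, score,
#'   strand.
#' @export
read_bed <- function(path, expected_columns = 3L) {
  lines <- read_tab_lines(path)
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < max(3L, expected_columns)))
    stop(sprintf("line %d: expected at least %d columns, found %d",
                 which(ncols < max(3L, expected_columns))[1],
                 max(3L, expected_columns),
                 min(ncols)))
  ln <- seq_along(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_int_field(vapply(fields, `[[`, "", 2L), ln, "start")
  end <- parse_int_field(vapply(fields, `[[`, "", 3L), ln, "end")
  bad <- which(end <= start | start < 0L)
  if (length(bad))
    stop(sprintf("line %d: invalid interval [%d,%d)", bad[1], start[bad[1]],
                 end[bad[1]]))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(ncols >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncols >= 5L)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    out$score <- sc
  }
  if (all(ncols >= 6L)) {
    strand <- vapply(fields, `[[`, "", 6L)
    if (!all(strand %in% c("+", "-", ".")))
      stop(sprintf("line %d: invalid strand '%s'",
                   which(!strand %in% c("+", "-", "."))[1],
                   strand[!strand %in% c("+", "-", ".")][1]))
    out$strand <- ifelse(strand == ".", "*", strand)
  }
  out
}

#' Write intervals as BED
#'
#' Emits BED3, BED4 or BED6 depending on which of name/score/strand are
#' present. Round-trips with [read_bed()].
#'
#' @param df interval data frame.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$name) || !is.null(df$score) || !is.null(df$strand)) {
    cols <- c(cols, list(if (is.null(df$name)) rep(".", nrow(df)) else df$name))
    if (!is.null(df$score) || !is.null(df$strand)) {
      cols <- c(cols,
                list(if (is.null(df$score)) rep(0, nrow(df)) else df$score))
      if (!is.null(df$strand))
        cols <- c(cols, list(ifelse(df$strand == "*", ".", df$strand)))
    }
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a MACS-style narrowPeak file
#'
#' Ten tab-separated columns. The summit is `start + offset`; an offset of
#' -1 (summit not determined) falls back to the interval midpoint. The
#' q-value column stores -log10(q) and is decoded to a plain q-value.
#'
#' @param path narrowPeak file path.
#' @return data.frame with chrom, start, end, name, strand, summit, q_value.
#' @export
read_narrowpeak <- function(path) {
  lines <- read_tab_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(fields) && any(ncols != 10L))
    stop(sprintf("line %d: narrowPeak requires 10 columns, found %d",
                 which(ncols != 10L)[1], ncols[ncols != 10L][1]))
  ln <- seq_along(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_int_field(vapply(fields, `[[`, "", 2L), ln, "start")
  end <- parse_int_field(vapply(fields, `[[`, "", 3L), ln, "end")
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("line %d: invalid interval", bad[1]))
  offset <- parse_int_field(vapply(fields, `[[`, "", 10L), ln, "summit offset")
  bad <- which(offset != -1L & (offset < 0L | start + offset >= end))
  if (length(bad))
    stop(sprintf("line %d: summit offset %d outside interval", bad[1],
                 offset[bad[1]]))
  summit <- ifelse(offset >= 0L, start + offset,
                   (start + end) %/% 2L)
  nlq <- as.numeric(vapply(fields, `[[`, "", 9L))
  strand <- vapply(fields, `[[`, "", 6L)
  data.frame(chrom = chrom, start = start, end = end,
             name = vapply(fields, `[[`, "", 4L),
             strand = ifelse(strand == ".", "*", strand),
             summit = as.integer(summit),
             q_value = 10^(-nlq),
             stringsAsFactors = FALSE)
}

#' Write a narrowPeak file (internal; used by the simulator)
#' @keywords internal
#' @noRd
write_narrowpeak <- function(df, path) {
  nlq <- -log10(df$q_value)
  out <- paste(df$chrom, df$start, df$end,
               if (is.null(df$name)) "." else df$name,
               0, ".", 0, -1, nlq, df$summit - df$start, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read TAD intervals from BED3
#'
#' @param path BED3 file.
#' @return data.frame with chrom/start/end and a generated `id`.
#' @export
read_tads <- function(path) {
  df <- read_bed(path, 3L)
  df$id <- if (!is.null(df$name)) df$name else
    sprintf("tad_%s_%d_%d", df$chrom, df$start, df$end)
  df[c("chrom", "start", "end", "id")]
}

#' Read chromatin-state enhancer intervals (BED4)
#'
#' Column 4 must be "active" (H3K4me1 + H3K27ac) or "poised" (H3K4me1 only).
#'
#' @param path BED4 file.
#' @return data.frame with chrom/start/end/state.
#' @export
read_chip_bed <- function(path) {
  df <- read_bed(path, 4L)
  if (is.null(df$name)) stop("chromatin-state BED needs a 4th (state) column")
  if (!all(df$name %in% c("active", "poised")))
    stop("chromatin states must be 'active' or 'poised'")
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             state = df$name, stringsAsFactors = FALSE)
}

#' Read gene models from a GTF file
#'
#' Parses transcript and exon features (via rtracklayer) into the package's
#' gene-model object: transcript TSSs are the strand-aware 5' ends, and
#' exons are kept per transcript. Coordinates are converted to 0-based
#' half-open.
#'
#' @param path GTF file.
#' @return A `gene_models` object: list with data frames `genes`
#'   (gene_id, biotype, chrom, strand), `transcripts` (transcript_id,
#'   gene_id, chrom, strand, tss) and `exons` (chrom, start, end, strand,
#'   gene_id, transcript_id).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand[type %in% c("transcript", "exon")] == "*"))
    stop("unknown strand in gene model file")
  biotype <- if (!is.null(md$gene_biotype)) as.character(md$gene_biotype)
             else rep(NA_character_, length(gr))
  tx_idx <- which(type == "transcript")
  ex_idx <- which(type == "exon")
  if (!length(tx_idx)) stop("no transcript features in ", path)
  tx <- data.frame(
    transcript_id = as.character(md$transcript_id[tx_idx]),
    gene_id = as.character(md$gene_id[tx_idx]),
    chrom = as.character(GenomicRanges::seqnames(gr))[tx_idx],
    strand = strand[tx_idx],
    tss = ifelse(strand[tx_idx] == "+",
                 GenomicRanges::start(gr)[tx_idx] - 1L,
                 GenomicRanges::end(gr)[tx_idx] - 1L),
    stringsAsFactors = FALSE
  )
  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr))[ex_idx],
    start = GenomicRanges::start(gr)[ex_idx] - 1L,
    end = GenomicRanges::end(gr)[ex_idx],
    strand = strand[ex_idx],
    gene_id = as.character(md$gene_id[ex_idx]),
    transcript_id = as.character(md$transcript_id[ex_idx]),
    stringsAsFactors = FALSE
  )
  missing_ex <- setdiff(tx$transcript_id, ex$transcript_id)
  if (length(missing_ex))
    stop("transcript without exons: ", missing_ex[1])
  gidx <- !duplicated(tx$gene_id)
  genes <- data.frame(
    gene_id = tx$gene_id[gidx],
    biotype = biotype[tx_idx][gidx],
    chrom = tx$chrom[gidx],
    strand = tx$strand[gidx],
    stringsAsFactors = FALSE
  )
  gene_models(genes, tx, ex)
}

#' Construct a gene_models object from its component tables
#'
#' @param genes data.frame(gene_id, biotype, chrom, strand).
#' @param transcripts data.frame(transcript_id, gene_id, chrom, strand, tss)
#'   with `tss` the 0-based position of the 5' end.
#' @param exons data.frame(chrom, start, end, strand, gene_id,
#'   transcript_id), 0-based half-open.
#' @return gene_models object.
#' @export
gene_models <- function(genes, transcripts, exons) {
  stopifnot(all(c("gene_id", "biotype") %in% names(genes)),
            all(c("transcript_id", "gene_id", "tss", "strand", "chrom") %in%
                  names(transcripts)),
            all(c("chrom", "start", "end", "gene_id") %in% names(exons)))
  chrom_of_gene <- stats::setNames(genes$chrom, genes$gene_id)
  if (any(transcripts$chrom != chrom_of_gene[transcripts$gene_id]))
    stop("transcript on a different chromosome than its gene")
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Subset gene models to protein-coding genes
#' @param gm gene_models object.
#' @return gene_models object restricted to biotype "protein_coding".
#' @export
protein_coding <- function(gm) {
  keep <- gm$genes$gene_id[gm$genes$biotype %in% "protein_coding"]
  gene_models(gm$genes[gm$genes$gene_id %in% keep, , drop = FALSE],
              gm$transcripts[gm$transcripts$gene_id %in% keep, , drop = FALSE],
              gm$exons[gm$exons$gene_id %in% keep, , drop = FALSE])
}

#' Write gene models as GTF (internal; used by the simulator)
#' @keywords internal
#' @noRd
write_gtf <- function(gm, path) {
  attr_str <- function(gene, tx, biotype) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
            gene, tx, biotype)
  }
  bio <- stats::setNames(gm$genes$biotype, gm$genes$gene_id)
  tx <- gm$transcripts
  ex <- gm$exons
  ex_first <- ex[order(ex$transcript_id, ex$start), ]
  tx_span <- do.call(rbind, lapply(split(ex_first, ex_first$transcript_id),
    function(e) data.frame(transcript_id = e$transcript_id[1],
                           start = min(e$start), end = max(e$end))))
  span_start <- stats::setNames(tx_span$start, tx_span$transcript_id)
  span_end <- stats::setNames(tx_span$end, tx_span$transcript_id)
  tx_lines <- sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom, span_start[tx$transcript_id] + 1L,
                      span_end[tx$transcript_id], tx$strand,
                      attr_str(tx$gene_id, tx$transcript_id, bio[tx$gene_id]))
  ex_lines <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                      ex$chrom, ex$start + 1L, ex$end, ex$strand,
                      attr_str(ex$gene_id, ex$transcript_id, bio[ex$gene_id]))
  writeLines(c(tx_lines, ex_lines), path)
  invisible(path)
}

#' Parse a region string like "chr10:25119065...25119466"
#'
#' Region strings are interpreted as 0-based start with half-open end, so a
#' printed 401-nt enhancer has width 401.
#'
#' @param x character vector of region strings (separator ":", positions
#'   separated by "..." or an ellipsis character).
#' @return interval data frame.
#' @export
parse_region_string <- function(x) {
  x2 <- gsub("…", "...", x)
  m <- regmatches(x2, regexec("^([^:]+):([0-9]+)\\.{3}([0-9]+)$", x2))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) stop("malformed region string: ", x[bad[1]])
  genomic_intervals(chrom = vapply(m, `[[`, "", 2L),
                    start = as.integer(vapply(m, `[[`, "", 3L)),
                    end = as.integer(vapply(m, `[[`, "", 4L)))
}
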