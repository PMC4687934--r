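# 6-mer enrichment between high- and low-readthrough quartiles in the 3'
# region upstream of polyA sites, and positional motif coverage.

#' Build the ranked gene set for motif analysis
#'
#' Starting from genes that passed all readthrough filters: drops the bottom
#' `bottom_exclude` genes by readthrough ratio (their spuriously negative
#' ratios reflect increased mutant expression), drops genes without a
#' well-defined polyA site, and assigns quartiles by readthrough score rank
#' (quartile 1 = highest readthrough, 4 = lowest). `rank_by = "ratio"`
#' switches the quartile statistic to the readthrough ratio.
#'
#' @param records `data.table` from [readthrough_analysis()] (or any table
#'   with `id`, `mean_ratio`, `score_mut_1`, `score_mut_2`, `pass_filters`).
#' @param polyA_ids Character vector of gene ids with well-defined polyA
#'   sites.
#' @param bottom_exclude Genes to drop from the bottom of the ratio ranking
#'   (0 disables).
#' @param rank_by `"score"` (mean mutant readthrough score) or `"ratio"`.
#' @return `data.table` with `id`, `value`, `quartile` (1-4).
#' @export
build_motif_gene_set <- function(records, polyA_ids, bottom_exclude = 250L,
                                 rank_by = c("score", "ratio")) {
  rank_by <- match.arg(rank_by)
  dt <- data.table::as.data.table(records)
  if ("pass_filters" %in% names(dt)) dt <- dt[pass_filters == TRUE]
  if (bottom_exclude > 0L && nrow(dt) > bottom_exclude) {
    dt <- dt[order(mean_ratio)][-seq_len(bottom_exclude)]
  }
  dt <- dt[id %in% polyA_ids]
  .assert(nrow(dt) >= 8L, "fewer than 8 genes left for motif analysis")
  dt[, value := if (rank_by == "score") (score_mut_1 + score_mut_2) / 2 else
    mean_ratio]
  dt <- dt[order(-value)]
  dt[, quartile := ceiling(seq_len(.N) / (.N / 4))]
  dt[quartile > 4L, quartile := 4L]
  dt[, c("id", "value", "quartile"), with = FALSE]
}

#' Extract the RNA-sense 3' region upstream of a polyA site
#'
#' Returns the sense-strand sequence covering offsets `[from, to)` relative
#' to the polyA site (reverse-complemented for minus-strand genes), with T
#' written as U. Defaults give the 60-nt -80..-20 region.
#'
#' @param gene Length-1 `GRanges` with a `polyA` coordinate (0-based,
#'   strand-aware 3' boundary).
#' @param genome A `DNAStringSet`.
#' @param from,to Sense offsets relative to the polyA site.
#' @return Character scalar over A/C/G/U.
#' @export
extract_3prime_region <- function(gene, genome, from = -80L, to = -20L) {
  .assert(length(gene) == 1L, "one gene at a time")
  p <- gene$polyA
  .assert(!is.na(p), "gene has no polyA site")
  seqn <- as.character(GenomicRanges::seqnames(gene))
  clen <- length(genome[[seqn]])
  if (as.character(GenomicRanges::strand(gene)) == "+") {
    a <- p + from; b <- p + to # 0-based half-open [a, b)
    .assert(a >= 0L && b <= clen, "3' region [%d,%d) off contig", a, b)
    s <- Biostrings::subseq(genome[[seqn]], a + 1L, b)
  } else {
    a <- p - to; b <- p - from
    .assert(a >= 0L && b <= clen, "3' region [%d,%d) off contig", a, b)
    s <- Biostrings::reverseComplement(
      Biostrings::subseq(genome[[seqn]], a + 1L, b))
  }
  chartr("T", "U", as.character(s))
}

#' Per-motif gene counts (presence/absence) for sequence groups
#'
#' Counts, for every k-mer over A/C/G/U, how many sequences in each group
#' contain it at least once (a gene counts once regardless of occurrence
#' count). Windows containing ambiguous bases are skipped.
#'
#' @param sequences_by_group Named list of character vectors (RNA-sense
#'   sequences, one per gene).
#' @param k Motif length.
#' @return Integer matrix: `4^k` motifs (rownames) x groups (colnames), plus
#'   attribute `n` giving group sizes.
#' @export
kmer_gene_counts <- function(sequences_by_group, k = 6L) {
  counts <- sapply(sequences_by_group, function(seqs) {
    rss <- Biostrings::RNAStringSet(seqs)
    freq <- Biostrings::oligonucleotideFrequency(rss, width = k)
    as.integer(colSums(freq > 0))
  })
  rn <- colnames(Biostrings::oligonucleotideFrequency(
    Biostrings::RNAStringSet("AAAAAAA"), width = k))
  rownames(counts) <- rn
  attr(counts, "n") <- vapply(sequences_by_group, length, integer(1))
  counts
}

#' Pooled two-proportion enrichment z-score
#'
#' `z = (p_low - p_high) / sqrt(phat (1 - phat) (1/n_low + 1/n_high))` with
#' `phat` the pooled proportion; positive z means enrichment in the
#' low-readthrough group. Degenerate pooled proportions (0 or 1) yield z = 0
#' with the `degenerate` attribute set.
#'
#' @param n_low_with,n_low Genes containing the motif / group size, low
#'   group. Vectorized.
#' @param n_high_with,n_high Same for the high group.
#' @return Numeric z vector with logical attribute `degenerate`.
#' @export
enrichment_z <- function(n_low_with, n_low, n_high_with, n_high) {
  .assert(all(n_low > 0) && all(n_high > 0), "group sizes must be > 0")
  p_low <- n_low_with / n_low
  p_high <- n_high_with / n_high
  phat <- (n_low_with + n_high_with) / (n_low + n_high)
  degenerate <- phat <= 0 | phat >= 1
  se <- sqrt(phat * (1 - phat) * (1 / n_low + 1 / n_high))
  z <- ifelse(degenerate, 0, (p_low - p_high) / se)
  attr(z, "degenerate") <- degenerate
  z
}

#' Motif enrichment table between two sequence groups
#'
#' Runs [kmer_gene_counts()] on the low- and high-readthrough groups and
#' scores every k-mer with [enrichment_z()].
#'
#' @param low_seqs,high_seqs Character vectors of RNA-sense sequences.
#' @param k Motif length.
#' @return `data.table` sorted by decreasing z: `motif`, `n_low_with`,
#'   `n_high_with`, `n_low`, `n_high`, `z`, `degenerate`.
#' @export
motif_enrichment <- function(low_seqs, high_seqs, k = 6L) {
  cnt <- kmer_gene_counts(list(low = low_seqs, high = high_seqs), k = k)
  n <- attr(cnt, "n")
  z <- enrichment_z(cnt[, "low"], n[["low"]], cnt[, "high"], n[["high"]])
  dt <- data.table::data.table(motif = rownames(cnt),
                               n_low_with = cnt[, "low"],
                               n_high_with = cnt[, "high"],
                               n_low = n[["low"]], n_high = n[["high"]],
                               z = as.numeric(z),
                               degenerate = attr(z, "degenerate"))
  dt[order(-z)]
}

#' Positional motif coverage around polyA sites
#'
#' For each offset in `window` (sense coordinates relative to the polyA
#' site), counts the genes with a motif occurrence covering that offset
#' (union of occurrences per gene: a gene contributes at most 1 per offset).
#'
#' @param transcripts TranscriptSet `GRanges` for the gene group (with
#'   `polyA`).
#' @param genome A `DNAStringSet`.
#' @param motif RNA motif, e.g. `"UAUAUA"`.
#' @param window Length-2 sense-offset window `c(from, to)` (half-open).
#' @return `data.table` with `offset` and `coverage`.
#' @export
motif_positional_coverage <- function(transcripts, genome, motif = "UAUAUA",
                                      window = c(-120L, 40L)) {
  from <- window[1]; to <- window[2]
  offsets <- seq.int(from, to - 1L)
  L <- nchar(motif)
  cover <- numeric(length(offsets))
  for (i in seq_along(transcripts)) {
    seq_i <- extract_3prime_region(transcripts[i], genome, from, to)
    m <- Biostrings::matchPattern(Biostrings::RNAString(motif),
                                  Biostrings::RNAString(seq_i))
    if (length(m) == 0L) next
    covered <- logical(length(offsets))
    for (q in Biostrings::start(m)) {
      covered[q:(q + L - 1L)] <- TRUE
    }
    cover <- cover + covered
  }
  data.table::data.table(offset = offsets, coverage = cover)
}

#' Select crosslinked reads for binding-site motif analysis
#'
#' Retains reads that (a) carry at least `min_tc` T-to-C substitutions
#' (crosslink signature) and (b) belong to a cluster — a connected component
#' of same-strand overlapping reads — with at least `min_cluster` members.
#' When `fdr` is given, clusters are additionally tested against a uniform
#' background (Poisson upper tail on cluster read count over the covered
#' span) with BH control at that level.
#'
#' @param readset A `ReadSet` whose reads carry an integer `tc_subs`
#'   metadata column.
#' @param min_tc Minimum T-C substitutions per read.
#' @param min_cluster Minimum cluster size.
#' @param fdr Optional FDR level for the cluster background test.
#' @return A `ReadSet` with the retained reads (same `total_mapped`).
#' @export
select_crosslinked_reads <- function(readset, min_tc = 1L, min_cluster = 5L,
                                     fdr = NULL) {
  gr <- readset$reads
  .assert(!is.null(gr$tc_subs), "reads carry no substitution information")
  clusters <- GenomicRanges::reduce(gr, ignore.strand = FALSE)
  memb <- GenomicRanges::findOverlaps(gr, clusters, select = "first")
  size <- tabulate(memb, nbins = length(clusters))
  keep_cluster <- size >= min_cluster
  if (!is.null(fdr) && any(keep_cluster)) {
    # expected reads per cluster under a uniform background over covered span
    rate <- length(gr) / sum(GenomicRanges::width(clusters))
    lambda <- rate * GenomicRanges::width(clusters)
    p <- stats::ppois(size - 1L, lambda, lower.tail = FALSE)
    keep_cluster <- keep_cluster & bh_fdr(pmin(pmax(p, .Machine$double.xmin),
                                               1), fdr)
  }
  keep <- gr$tc_subs >= min_tc & keep_cluster[memb]
  ReadSet(gr[keep], readset$total_mapped)
}
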