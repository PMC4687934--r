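# In-code fixtures shared across test files. All coordinates 0-based
# half-open unless a GRanges is built directly.

# small annotation from a compact spec: list of c(start, end, strand, class)
make_tx <- function(..., chrom = "chr1", chrom_length = 100000L) {
  rows <- list(...)
  gr <- do.call(c, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    g <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(as.integer(r[[1]]) + 1L,
                                                 as.integer(r[[2]])),
                                strand = r[[3]])
    g$id <- if (length(r) >= 5) r[[5]] else sprintf("T%02d", i)
    g$rna_class <- factor(if (length(r) >= 4) r[[4]] else "mRNA",
                          levels = readthroughr:::RNA_CLASSES)
    g$sno_class <- if (length(r) >= 6) r[[6]] else NA_character_
    g
  }))
  gr$polyA <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                     GenomicRanges::end(gr), GenomicRanges::start(gr) - 1L)
  names(gr) <- gr$id
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(chrom_length, chrom)
  gr
}

# probe track with constant per-sample intensity over [start, end) at `step`
make_probes <- function(start, end, strand = "+", step = 8L, chrom = "chr1",
                        wt_1 = 0, wt_2 = 0, mut_1 = 0, mut_2 = 0) {
  pos <- seq.int(start, end - 1L, by = step)
  rep1 <- function(x) if (length(x) == 1L) rep(x, length(pos)) else x
  data.table::data.table(chrom = chrom, position = pos, strand = strand,
                         wt_1 = rep1(wt_1), wt_2 = rep1(wt_2),
                         mut_1 = rep1(mut_1), mut_2 = rep1(mut_2))
}

probe_track_of <- function(...) {
  as_probe_track(data.table::rbindlist(list(...)))
}

# ReadSet from vectors of 0-based starts/ends
make_reads <- function(start, end, strand = "+", chrom = "chr1",
                       tail3 = NA_character_, total_mapped = NULL, ...) {
  n <- length(start)
  gr <- GenomicRanges::GRanges(rep(chrom, length.out = n),
                               IRanges::IRanges(start + 1L, end),
                               strand = rep(strand, length.out = n))
  names(gr) <- sprintf("r%03d", seq_len(n))
  gr$tail3 <- rep(tail3, length.out = n)
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  ReadSet(gr, total_mapped %||% n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genome of one contig from an explicit sequence string
make_genome <- function(seq, chrom = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}

random_genome <- function(len, chrom = "chr1", seed = 99) {
  set.seed(seed)
  make_genome(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = ""), chrom)
}
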