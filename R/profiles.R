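# CRAC read analytics: class assignment, oligo(A) detection, metagene and
# pileup profiles, Pol II 3'-end group profiles, snoRNA flank ratios.

# class priority for reads overlapping several sense features
CLASS_PRIORITY <- c("rRNA", "tRNA", "snoRNA", "snRNA", "mRNA", "intron",
                    "CUT", "SUT", "ncRNA-other")

#' Assign each read to an RNA class
#'
#' A read belongs to a feature when at least `min_frac` of its length lies
#' within the feature on the same strand; among several sense features the
#' highest-priority class wins (rRNA > tRNA > snoRNA > snRNA > mRNA >
#' intron > CUT > SUT > ncRNA-other). Reads with no sense feature but an
#' opposite-strand overlap are `antisense`; the rest are `intergenic`.
#'
#' @param readset A `ReadSet`.
#' @param annotation TranscriptSet `GRanges` (metadata `rna_class`; a
#'   literal `"intron"` class is honored if present).
#' @param min_frac Minimum overlap as a fraction of read length.
#' @return Character vector of class labels, one per read.
#' @export
assign_read_class <- function(readset, annotation, min_frac = 0.5) {
  gr <- readset$reads
  n <- length(gr)
  if (n == 0L) return(character(0))
  cls <- as.character(annotation$rna_class)
  prio <- match(cls, CLASS_PRIORITY)

  need <- ceiling(min_frac * GenomicRanges::width(gr))
  hits <- GenomicRanges::findOverlaps(gr, annotation, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[qh], IRanges::ranges(annotation)[sh]))
  keep <- ov >= need[qh] &
    as.character(GenomicRanges::seqnames(gr))[qh] ==
    as.character(GenomicRanges::seqnames(annotation))[sh]
  qh <- qh[keep]; sh <- sh[keep]
  same <- as.character(GenomicRanges::strand(gr))[qh] ==
    as.character(GenomicRanges::strand(annotation))[sh]

  out <- rep("intergenic", n)
  if (any(!same)) out[unique(qh[!same])] <- "antisense"
  if (any(same)) {
    best <- tapply(prio[sh[same]], qh[same], min)
    out[as.integer(names(best))] <- CLASS_PRIORITY[best]
  }
  out
}

#' Tally read counts and fractions per RNA class
#' @param readset A `ReadSet`.
#' @param annotation TranscriptSet `GRanges`.
#' @param ... Passed to [assign_read_class()].
#' @return `data.table` with `class`, `count`, `fraction` (fractions sum
#'   to 1 over assigned reads).
#' @export
class_tally <- function(readset, annotation, ...) {
  labels <- assign_read_class(readset, annotation, ...)
  tab <- table(labels)
  data.table::data.table(class = names(tab), count = as.integer(tab),
                         fraction = as.numeric(tab) / length(labels))
}

#' Detect non-templated 3' oligo(A) tails
#'
#' A read is flagged when its recorded 3' tail is non-empty, all A, at least
#' 2 nt, and non-templated: the genomic bases the tail would occupy
#' (immediately 3' of the aligned read, in read orientation) differ from the
#' tail in at least one position. Tails running past the contig end count as
#' non-templated.
#'
#' @param readset A `ReadSet` whose reads carry `tail3`.
#' @param genome A `DNAStringSet`.
#' @return Logical vector, one flag per read (reads without a tail are
#'   `FALSE`).
#' @export
detect_oligoA <- function(readset, genome) {
  gr <- readset$reads
  tails <- gr$tail3
  out <- logical(length(gr))
  cand <- which(!is.na(tails) & nchar(tails) >= 2L &
                  grepl("^A+$", tails))
  for (i in cand) {
    tmpl <- .template_bases(gr[i], genome, nchar(tails[i]))
    out[i] <- is.na(tmpl) || tmpl != tails[i]
  }
  out
}

#' Fraction of reads carrying non-templated oligo(A) tails
#'
#' @param readset A `ReadSet`.
#' @param genome A `DNAStringSet`.
#' @param annotation Optional TranscriptSet: when given, also reports the
#'   fraction per read class.
#' @return List with `fraction` (overall; `NA` for an empty set), `n`, and
#'   optionally `by_class` (a `data.table`).
#' @export
oligoA_fraction <- function(readset, genome, annotation = NULL) {
  n <- length(readset$reads)
  if (n == 0L) {
    message("empty ReadSet: oligo(A) fraction undefined")
    return(list(fraction = NA_real_, n = 0L))
  }
  flag <- detect_oligoA(readset, genome)
  out <- list(fraction = mean(flag), n = n)
  if (!is.null(annotation)) {
    cls <- assign_read_class(readset, annotation)
    out$by_class <- data.table::data.table(class = cls, flag = flag)[
      , list(fraction = mean(flag), n = .N), by = "class"]
  }
  out
}

# strand-aware coverage lookup: per-offset read coverage for a gene window.
# `anchor0` is the 0-based genomic position of the offset-0 base; offsets run
# in the transcription direction.
.strand_cov <- function(readset) {
  gr <- readset$reads
  list("+" = GenomicRanges::coverage(gr[GenomicRanges::strand(gr) == "+"]),
       "-" = GenomicRanges::coverage(gr[GenomicRanges::strand(gr) == "-"]))
}

.cov_window <- function(cov, chrom, anchor0, offsets, strand) {
  genomic <- if (strand == "+") anchor0 + offsets else anchor0 - offsets
  covchr <- cov[[strand]][[chrom]]
  vals <- numeric(length(genomic))
  if (!is.null(covchr)) {
    pos1 <- genomic + 1L # Rle is 1-based
    inb <- pos1 >= 1L & pos1 <= length(covchr)
    vals[inb] <- as.numeric(covchr[pos1[inb]])
  }
  vals
}

.anchor_base <- function(tx, anchor) {
  st <- as.character(GenomicRanges::strand(tx))
  s0 <- .gr_start0(tx); e0 <- .gr_end0(tx)
  switch(anchor,
         TSS = ifelse(st == "+", s0, e0 - 1L),
         end3 = ifelse(st == "+", e0 - 1L, s0),
         polyA = {
           p <- tx$polyA
           .assert(!anyNA(p), "polyA anchor requested but polyA is missing")
           ifelse(st == "+", p - 1L, p)
         })
}

#' Endpoint-anchored metagene profile
#'
#' Sums per-nucleotide read coverage across genes after anchoring each at a
#' common landmark. Offsets run in the transcription direction: for `TSS`,
#' `-flank_out .. flank_in - 1` (0 = first transcribed base); for `end3` /
#' `polyA`, `-(flank_in - 1) .. flank_out` (0 = last transcribed base, so
#' positive offsets extend past the 3' end).
#'
#' @param readset A `ReadSet`.
#' @param transcripts TranscriptSet `GRanges`.
#' @param anchor `"TSS"`, `"end3"` or `"polyA"`.
#' @param flank_out Nucleotides outside the transcript.
#' @param flank_in Nucleotides into the transcript.
#' @param min_len Transcripts at or below this length are dropped.
#' @param normalization `"per_million"` (divide by `total_mapped / 1e6`),
#'   `"sum_to_one"`, or `"none"`.
#' @param top_n Optionally restrict to the `top_n` most-bound transcripts
#'   (by total overlapping reads), as done for mRNA profiles.
#' @return A `MetageneProfile`: list with `anchor`, `offsets`, `values`,
#'   `normalization`, `gene_set_size`.
#' @export
metagene_endpoint_profile <- function(readset, transcripts,
                                      anchor = c("TSS", "end3", "polyA"),
                                      flank_out = 100L, flank_in = 100L,
                                      min_len = 150L,
                                      normalization = c("per_million",
                                                        "sum_to_one", "none"),
                                      top_n = NULL) {
  anchor <- match.arg(anchor)
  normalization <- match.arg(normalization)
  tx <- transcripts[GenomicRanges::width(transcripts) > min_len]
  .assert(length(tx) > 0L, "empty gene set after length filter")
  if (!is.null(top_n) && length(tx) > top_n) {
    nhit <- GenomicRanges::countOverlaps(tx, readset$reads)
    tx <- tx[order(nhit, decreasing = TRUE)[seq_len(top_n)]]
  }
  offsets <- if (anchor == "TSS") seq.int(-flank_out, flank_in - 1L) else
    seq.int(-(flank_in - 1L), flank_out)
  cov <- .strand_cov(readset)
  anch <- .anchor_base(tx, anchor)
  st <- as.character(GenomicRanges::strand(tx))
  chrom <- as.character(GenomicRanges::seqnames(tx))
  values <- numeric(length(offsets))
  for (i in seq_along(tx))
    values <- values + .cov_window(cov, chrom[i], anch[i], offsets, st[i])
  values <- switch(normalization,
                   per_million = {
                     .assert(readset$total_mapped > 0, "total_mapped is 0")
                     values / (readset$total_mapped / 1e6)
                   },
                   sum_to_one = {
                     .assert(sum(values) > 0, "all-zero profile")
                     values / sum(values)
                   },
                   none = values)
  structure(list(anchor = anchor, offsets = offsets, values = values,
                 normalization = normalization, gene_set_size = length(tx)),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf("MetageneProfile: anchor %s, offsets %d..%d, %d genes, %s\n",
              x$anchor, min(x$offsets), max(x$offsets), x$gene_set_size,
              x$normalization))
  invisible(x)
}

#' Rolling-mean smoother for metagene profiles
#' @param values Numeric vector.
#' @param k Odd window width.
#' @return Smoothed vector (edges use shrinking windows); raw values are
#'   always kept by the caller.
#' @export
smooth_profile <- function(values, k = 11L) {
  .assert(k %% 2L == 1L, "k must be odd")
  h <- (k - 1L) %/% 2L
  n <- length(values)
  vapply(seq_len(n), function(i) {
    mean(values[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Length-normalized binned coverage profile
#'
#' Maps each transcript's per-nucleotide coverage onto `n_bins` equal
#' fractions of its length and sums across transcripts. Each nucleotide's
#' coverage is split fractionally across the bins it spans, so total binned
#' mass equals total per-nucleotide mass.
#'
#' @param readset A `ReadSet`.
#' @param transcripts TranscriptSet `GRanges`.
#' @param n_bins Number of bins (>= 1).
#' @return Numeric vector of length `n_bins` (bin 1 = 5' end).
#' @export
length_normalized_profile <- function(readset, transcripts, n_bins = 50L) {
  .assert(n_bins >= 1L, "n_bins must be >= 1")
  cov <- .strand_cov(readset)
  out <- numeric(n_bins)
  st <- as.character(GenomicRanges::strand(transcripts))
  chrom <- as.character(GenomicRanges::seqnames(transcripts))
  s0 <- .gr_start0(transcripts); e0 <- .gr_end0(transcripts)
  for (i in seq_along(transcripts)) {
    L <- e0[i] - s0[i]
    offs <- seq.int(0L, L - 1L)
    anchor <- if (st[i] == "+") s0[i] else e0[i] - 1L
    v <- .cov_window(cov, chrom[i], anchor, offs, st[i])
    lo <- offs * n_bins / L
    hi <- (offs + 1L) * n_bins / L
    for (j in which(v > 0)) {
      b1 <- floor(lo[j]); b2 <- min(ceiling(hi[j]) - 1, n_bins - 1)
      for (b in b1:b2) {
        frac <- (min(hi[j], b + 1) - max(lo[j], b)) / (hi[j] - lo[j])
        out[b + 1L] <- out[b + 1L] + v[j] * frac
      }
    }
  }
  out
}

#' Per-nucleotide pileup in hits per million mapped reads
#'
#' `value(nt) = #reads covering nt * 1e6 / total_mapped` over a single-strand
#' region.
#'
#' @param readset A `ReadSet`.
#' @param chrom Chromosome.
#' @param start,end Region, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param total_mapped Library size (default from the ReadSet; must be > 0).
#' @return Named numeric vector (names = 0-based positions).
#' @export
pileup <- function(readset, chrom, start, end, strand,
                   total_mapped = readset$total_mapped) {
  .check_strand(strand)
  .assert(total_mapped > 0, "total_mapped is 0")
  cov <- .strand_cov(readset)
  pos <- seq.int(start, end - 1L)
  covchr <- cov[[strand]][[chrom]]
  vals <- numeric(length(pos))
  if (!is.null(covchr)) {
    pos1 <- pos + 1L
    inb <- pos1 >= 1L & pos1 <= length(covchr)
    vals[inb] <- as.numeric(covchr[pos1[inb]])
  }
  setNames(vals * 1e6 / total_mapped, pos)
}

#' Max-normalized Pol II 3'-end profile for a gene group
#'
#' For each gene, takes per-nucleotide coverage in the window
#' `[3' end - window_up, 3' end + window_down]` (transcription direction),
#' linearly scales it so its maximum equals 1, and sums over the group.
#' Genes without a hit in the window are dropped with a warning.
#'
#' @param readset A `ReadSet`.
#' @param transcripts TranscriptSet `GRanges`.
#' @param gene_ids Genes in the group.
#' @param window_up,window_down Window half-widths (nt).
#' @return A `MetageneProfile` (normalization `max_one_then_sum`); its
#'   `gene_set_size` counts the genes actually used.
#' @export
polii_3prime_group_profile <- function(readset, transcripts, gene_ids,
                                       window_up = 500L, window_down = 500L) {
  .assert(length(gene_ids) > 0L, "empty gene group")
  tx <- transcripts[gene_ids]
  offsets <- seq.int(-window_up, window_down)
  cov <- .strand_cov(readset)
  anch <- .anchor_base(tx, "end3")
  st <- as.character(GenomicRanges::strand(tx))
  chrom <- as.character(GenomicRanges::seqnames(tx))
  values <- numeric(length(offsets))
  used <- 0L
  for (i in seq_along(tx)) {
    v <- .cov_window(cov, chrom[i], anch[i], offsets, st[i])
    if (max(v) <= 0) next
    values <- values + v / max(v)
    used <- used + 1L
  }
  if (used < length(tx))
    warning(sprintf("%d gene(s) without hits dropped from group profile",
                    length(tx) - used))
  .assert(used > 0L, "no gene in the group has hits in its window")
  structure(list(anchor = "end3", offsets = offsets, values = values,
                 normalization = "max_one_then_sum", gene_set_size = used),
            class = "MetageneProfile")
}

#' snoRNA 3'-flank readthrough ratio between strains
#'
#' Sums hits in the `flank_len` nt immediately 3' of the snoRNA relative to
#' hits within the snoRNA body, per strain, and reports
#' `fold = (flank/body)_mut / (flank/body)_wt`.
#'
#' @param reads_wt,reads_mut `ReadSet`s for the two strains.
#' @param snoRNA A length-1 `GRanges`.
#' @param flank_len Flank length (nt).
#' @return List with per-strain `body_hits`, `flank_hits`, `score`, and
#'   `fold` (`NA` with a message when a body count is zero).
#' @export
snoRNA_flank_ratio <- function(reads_wt, reads_mut, snoRNA,
                               flank_len = 500L) {
  .assert(length(snoRNA) == 1L, "one snoRNA at a time")
  st <- as.character(GenomicRanges::strand(snoRNA))
  s0 <- .gr_start0(snoRNA); e0 <- .gr_end0(snoRNA)
  if (st == "+") {
    fl <- c(e0, e0 + flank_len)
  } else {
    fl <- c(s0 - flank_len, s0)
  }
  count <- function(rs, a, b) {
    gr <- rs$reads
    sum(as.character(GenomicRanges::seqnames(gr)) ==
          as.character(GenomicRanges::seqnames(snoRNA)) &
          as.character(GenomicRanges::strand(gr)) == st &
          .gr_start0(gr) < b & .gr_end0(gr) > a)
  }
  res <- lapply(list(wt = reads_wt, mut = reads_mut), function(rs) {
    list(body = count(rs, s0, e0), flank = count(rs, fl[1], fl[2]))
  })
  score <- function(x) if (x$body > 0) x$flank / x$body else NA_real_
  s_wt <- score(res$wt); s_mut <- score(res$mut)
  fold <- if (is.na(s_wt) || is.na(s_mut) || s_wt == 0) {
    message("zero body hits (or zero WT flank score): fold undefined")
    NA_real_
  } else s_mut / s_wt
  list(body_hits = c(wt = res$wt$body, mut = res$mut$body),
       flank_hits = c(wt = res$wt$flank, mut = res$mut$flank),
       score = c(wt = s_wt, mut = s_mut), fold = fold)
}

#' Tally snoRNA readthrough calls by transcript class
#'
#' Counts flagged snoRNAs among monocistronic and polycistronic transcripts;
#' intron-encoded snoRNAs are excluded from the denominator (they cannot show
#' independent readthrough).
#'
#' @param calls `data.frame`/`data.table` with columns `id` and `readthrough`
#'   (logical).
#' @param annotation TranscriptSet `GRanges` (snoRNAs carry `sno_class`).
#' @return `data.table` with rows `monocistronic`, `polycistronic`, `all`:
#'   columns `n_rt`, `n_total`.
#' @export
tally_snoRNA_readthrough <- function(calls, annotation) {
  sno <- annotation[annotation$rna_class == "snoRNA"]
  dt <- data.table::data.table(id = sno$id, sno_class = sno$sno_class)
  calls <- data.table::as.data.table(calls)
  dt <- merge(dt, calls[, c("id", "readthrough"), with = FALSE],
              by = "id", all.x = TRUE)
  dt[is.na(readthrough), readthrough := FALSE]
  eligible <- dt[sno_class %in% c("monocistronic", "polycistronic")]
  row <- function(cls) {
    sub <- if (cls == "all") eligible else eligible[sno_class == cls]
    data.table::data.table(sno_class = cls, n_rt = sum(sub$readthrough),
                           n_total = nrow(sub))
  }
  data.table::rbindlist(lapply(c("monocistronic", "polycistronic", "all"),
                               row))
}
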