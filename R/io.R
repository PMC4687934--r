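#' Map GFF3 feature types to transcript classes
#'
#' The mapping follows Ensembl/SGD conventions (`snoRNA_gene` -> `snoRNA`,
#' `gene`/`mRNA` -> `mRNA`, ...). Unknown types fall back to `ncRNA-other`
#' with a warning, per the annotation contract.
#' @keywords internal
GFF_CLASS_MAP <- c(
  gene = "mRNA", mRNA = "mRNA", protein_coding_gene = "mRNA",
  snoRNA = "snoRNA", snoRNA_gene = "snoRNA",
  snRNA = "snRNA", snRNA_gene = "snRNA",
  CUT = "CUT", cut = "CUT",
  SUT = "SUT", sut = "SUT",
  tRNA = "tRNA", tRNA_gene = "tRNA",
  rRNA = "rRNA", rRNA_gene = "rRNA",
  ncRNA = "ncRNA-other", ncRNA_gene = "ncRNA-other"
)

#' Read a stranded transcript annotation from GFF3
#'
#' Parses a GFF3 file into a `GRanges` with metadata columns `id`, `rna_class`
#' (one of `r paste(RNA_CLASSES, collapse = ", ")`), optional `polyA`
#' (0-based coordinate of the polyadenylation site) and optional `sno_class`
#' (`monocistronic`, `polycistronic`, `intronic`). GFF3 coordinates (1-based
#' inclusive) are stored in the `GRanges` convention; all package APIs that
#' take raw coordinates use 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges` ("TranscriptSet") with metadata columns described above.
#' @export
read_annotation <- function(path) {
  .assert(file.exists(path), "annotation file not found: %s", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields",
                 bad, path), call. = FALSE)
  }
  gff <- rtracklayer::import(path, format = "gff3")
  .assert(all(as.character(GenomicRanges::strand(gff)) %in% c("+", "-")),
          "annotation contains unstranded features")

  type <- as.character(gff$type)
  cls <- unname(GFF_CLASS_MAP[type])
  if (anyNA(cls)) {
    warning(sprintf("unknown feature type(s) %s recorded as ncRNA-other",
                    paste(unique(type[is.na(cls)]), collapse = ", ")))
    cls[is.na(cls)] <- "ncRNA-other"
  }
  # rna_class attribute (emitted by write_annotation) overrides the type map
  if (!is.null(gff$rna_class)) {
    keep <- !is.na(gff$rna_class) & gff$rna_class %in% RNA_CLASSES
    cls[keep] <- as.character(gff$rna_class)[keep]
  }

  id <- gff$ID %||% gff$Name
  .assert(!is.null(id) && !anyNA(id), "every feature needs an ID attribute")
  polyA <- if (!is.null(gff$polyA)) suppressWarnings(as.integer(gff$polyA)) else
    rep(NA_integer_, length(gff))
  sno_class <- if (!is.null(gff$sno_class)) as.character(gff$sno_class) else
    rep(NA_character_, length(gff))

  tx <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gff),
    ranges = IRanges::ranges(gff),
    strand = GenomicRanges::strand(gff),
    id = as.character(id),
    rna_class = factor(cls, levels = RNA_CLASSES),
    polyA = polyA,
    sno_class = sno_class)
  names(tx) <- tx$id
  tx
}

#' Write a transcript annotation to GFF3
#'
#' Inverse of [read_annotation()]; round-trips intervals, classes, ids,
#' polyA sites and snoRNA transcript classes.
#' @param tx A TranscriptSet `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(tx, path) {
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(tx)),
    source = "readthroughr",
    type = as.character(tx$rna_class),
    start = GenomicRanges::start(tx),
    end = GenomicRanges::end(tx),
    score = ".",
    strand = as.character(GenomicRanges::strand(tx)),
    phase = ".",
    attributes = sprintf("ID=%s;rna_class=%s%s%s", tx$id, tx$rna_class,
                         ifelse(is.na(tx$polyA), "",
                                sprintf(";polyA=%d", tx$polyA)),
                         ifelse(is.na(tx$sno_class), "",
                                sprintf(";sno_class=%s", tx$sno_class))),
    stringsAsFactors = FALSE)
  # type must be a valid GFF3 term for rtracklayer to re-import cleanly
  df$type <- c("mRNA" = "gene", "snoRNA" = "snoRNA_gene",
               "snRNA" = "snRNA_gene", "CUT" = "CUT", "SUT" = "SUT",
               "tRNA" = "tRNA_gene", "rRNA" = "rRNA_gene",
               "ncRNA-other" = "ncRNA_gene")[df$type]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a strand-specific tiling-array probe table
#'
#' Expects a TSV with header `chrom`, `position`, `strand` followed by one
#' numeric log2-intensity column per sample. `position` is the probe center
#' (0-based). Duplicate (chrom, position, strand) rows are rejected.
#'
#' @param path Path to the TSV.
#' @param samples Expected sample column names.
#' @return A `ProbeTrack`: a keyed `data.table` with class `"ProbeTrack"`.
#' @export
read_probe_table <- function(path, samples = SAMPLE_IDS) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  .assert(all(c("chrom", "position", "strand") %in% names(dt)),
          "probe table needs columns chrom, position, strand")
  missing <- setdiff(samples, names(dt))
  .assert(length(missing) == 0L, "probe table missing sample column(s): %s",
          paste(missing, collapse = ", "))
  for (s in samples) {
    v <- dt[[s]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric intensity in column %s, row %d", s, bad),
           call. = FALSE)
    }
    .assert(all(is.finite(v)), "non-finite intensity in column %s", s)
  }
  as_probe_track(dt[, c("chrom", "position", "strand", samples), with = FALSE],
                 samples)
}

#' Construct a ProbeTrack from a data.frame/data.table
#' @param dt Columns chrom, position (0-based probe center), strand, samples.
#' @param samples Sample column names.
#' @return A keyed `data.table` of class `"ProbeTrack"`.
#' @export
as_probe_track <- function(dt, samples = SAMPLE_IDS) {
  dt <- data.table::as.data.table(dt)
  .assert(all(dt$strand %in% c("+", "-")), "probe strand must be + or -")
  data.table::setkeyv(dt, c("chrom", "strand", "position"))
  .assert(!anyDuplicated(dt, by = c("chrom", "strand", "position")),
          "duplicate (chrom, position, strand) probe rows")
  data.table::setattr(dt, "samples", samples)
  data.table::setattr(dt, "class", c("ProbeTrack", class(dt)))
  dt
}

#' Write a ProbeTrack to TSV
#' @param track A ProbeTrack.
#' @param path Output path.
#' @export
write_probe_table <- function(track, path) {
  data.table::fwrite(data.table::as.data.table(track), path, sep = "\t")
  invisible(path)
}

#' Query probes by genomic window
#'
#' Returns probes whose center lies in `[start, end)` (0-based half-open) on
#' the given strand — the probe-membership convention used throughout.
#'
#' @param track A ProbeTrack.
#' @param chrom Chromosome.
#' @param start,end Window, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return A `data.table` subset of the track.
#' @export
probe_query <- function(track, chrom, start, end, strand) {
  .check_strand(strand)
  .assert(start < end, "empty window [%s, %s)", start, end)
  .qchrom <- chrom; .qstrand <- strand; .qstart <- start; .qend <- end
  dt <- track[list(.qchrom, .qstrand)]
  dt[!is.na(position) & position >= .qstart & position < .qend]
}

#' Read mapped reads from BED6 or BAM into a ReadSet
#'
#' BED6 files give stranded intervals (no 3' tails). BAM records additionally
#' yield `tail3`: the soft-clipped bases at the read's 3' end in read
#' orientation (trailing clip for `+` alignments, reverse complement of the
#' leading clip for `-`).
#'
#' @param path Path to a `.bed` or `.bam` file.
#' @param total_mapped Library size; defaults to the record count.
#' @param seqlengths Optional named contig lengths for bounds checking.
#' @return A `ReadSet`: list with elements `reads` (`GRanges` with `tail3`
#'   metadata) and `total_mapped`.
#' @export
read_reads <- function(path, total_mapped = NULL, seqlengths = NULL) {
  .assert(file.exists(path), "read file not found: %s", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    rs <- .read_reads_bam(path)
  } else {
    rs <- .read_reads_bed(path)
  }
  if (!is.null(seqlengths)) {
    chr <- as.character(GenomicRanges::seqnames(rs))
    .assert(all(chr %in% names(seqlengths)), "reads on unknown contig")
    .assert(all(GenomicRanges::end(rs) <= seqlengths[chr]) &&
              all(GenomicRanges::start(rs) >= 1L),
            "read interval off contig end")
  }
  ReadSet(rs, total_mapped %||% length(rs))
}

.read_reads_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(GenomicRanges::GRanges(tail3 = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  .assert(all(lengths(fields) >= 6L),
          "BED input needs >= 6 columns (strand in column 6)")
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  gr <- .gr_from_0based(chrom = m[, 1], start = as.integer(m[, 2]),
                        end = as.integer(m[, 3]), strand = m[, 6])
  names(gr) <- m[, 4]
  gr$tail3 <- rep(NA_character_, length(gr))
  gr
}

.read_reads_bam <- function(path) {
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1L]]
  if (length(b$pos) == 0L)
    return(GenomicRanges::GRanges(tail3 = character(0)))
  width <- .cigar_ref_width(b$cigar)
  gr <- GenomicRanges::GRanges(
    seqnames = b$rname,
    ranges = IRanges::IRanges(start = b$pos, width = width),
    strand = b$strand)
  names(gr) <- b$qname
  gr$tail3 <- .bam_tail3(b$cigar, as.character(b$seq), as.character(b$strand))
  gr
}

# reference-consumed width from a CIGAR string (M/D/N/=/X)
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

.bam_tail3 <- function(cigar, seq, strand) {
  out <- rep(NA_character_, length(cigar))
  for (i in seq_along(cigar)) {
    toks <- regmatches(cigar[i], gregexpr("\\d+[MIDNSHP=X]", cigar[i]))[[1L]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    if (strand[i] == "+") {
      k <- length(op)
      if (op[k] == "S") {
        L <- nchar(seq[i])
        out[i] <- substr(seq[i], L - n[k] + 1L, L)
      }
    } else {
      if (op[1L] == "S") {
        # BAM stores seq in reference orientation; the read's 3' tail is the
        # leading clip, reverse-complemented back to read orientation
        clip <- substr(seq[i], 1L, n[1L])
        out[i] <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(clip)))
      }
    }
  }
  out
}

#' Construct a ReadSet
#' @param reads `GRanges` with optional `tail3` metadata column.
#' @param total_mapped Library size (>= number of reads).
#' @return A list of class `"ReadSet"`.
#' @export
ReadSet <- function(reads, total_mapped = length(reads)) {
  .assert(.is_count(total_mapped) && total_mapped >= length(reads),
          "total_mapped must be a count >= number of reads")
  if (is.null(reads$tail3)) reads$tail3 <- rep(NA_character_, length(reads))
  tails <- reads$tail3[!is.na(reads$tail3)]
  .assert(all(grepl("^[ACGTN]*$", tails)), "tail3 may contain only ACGTN")
  structure(list(reads = reads, total_mapped = as.integer(total_mapped)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads (%d mapped), %d with 3' tails\n",
              length(x$reads), x$total_mapped, sum(!is.na(x$reads$tail3))))
  invisible(x)
}

#' Write a ReadSet to BED6
#' @param rs A ReadSet.
#' @param path Output path.
#' @export
write_reads_bed <- function(rs, path) {
  gr <- rs$reads
  nm <- names(gr) %||% paste0("r", seq_along(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = .gr_start0(gr), end = .gr_end0(gr),
                   name = nm, score = 0L,
                   strand = as.character(GenomicRanges::strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write per-nucleotide values as bedGraph
#'
#' Values are run-length merged; zeros are omitted so an all-zero input
#' produces an empty body. One strand per call (bedGraph itself is
#' strand-blind, so strands go to separate files).
#'
#' @param values Named numeric vector: names are 0-based positions.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"` (validated; recorded in a track comment).
#' @param path Output path.
#' @export
write_bedgraph <- function(values, chrom, strand, path) {
  .check_strand(strand)
  .assert(all(is.finite(values)), "bedGraph values must be finite")
  pos <- as.integer(names(values))
  .assert(!anyNA(pos), "values must be named by integer positions")
  o <- order(pos)
  pos <- pos[o]; val <- unname(values[o])
  keep <- val != 0
  pos <- pos[keep]; val <- val[keep]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# strand=%s", strand), con)
  if (length(pos)) {
    # break runs where value changes or positions are non-contiguous
    brk <- c(TRUE, diff(pos) != 1L | diff(val) != 0)
    grp <- cumsum(brk)
    s <- tapply(pos, grp, min)
    e <- tapply(pos, grp, max) + 1L
    v <- tapply(val, grp, `[`, 1L)
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, as.integer(s), as.integer(e),
                       format(v, trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a per-nucleotide vector
#' @param path bedGraph path.
#' @return Named numeric vector (names are 0-based positions).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) return(setNames(numeric(0), character(0)))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  start <- as.integer(f[, 2]); end <- as.integer(f[, 3])
  val <- as.numeric(f[, 4])
  pos <- unlist(Map(seq, start, end - 1L))
  setNames(rep(val, end - start), pos)
}

#' Read a genome from FASTA
#' @param path FASTA path.
#' @return A `DNAStringSet` named by contig.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome to FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
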