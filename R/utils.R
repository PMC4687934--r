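#' @import methods
#' @importFrom stats median rnorm rlnorm runif rbinom setNames complete.cases
#' @importFrom utils head tail write.table
#' @importFrom data.table data.table setkey setkeyv as.data.table := .N .SD fwrite fread setorder copy rbindlist
NULL

# Closed set of annotation classes; assignment-only labels (intron, antisense,
# intergenic) are deliberately not part of this set.
RNA_CLASSES <- c("mRNA", "snoRNA", "snRNA", "CUT", "SUT", "tRNA", "rRNA",
                 "ncRNA-other")

SAMPLE_IDS <- c("wt_1", "wt_2", "mut_1", "mut_2")

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

.check_strand <- function(strand) {
  .assert(length(strand) == 1L && strand %in% c("+", "-"),
          "strand must be '+' or '-', got '%s'", paste(strand, collapse = ","))
  strand
}

#' Strand-aware 3' end of intervals (0-based half-open internally)
#'
#' For a `+` feature `[start, end)` the 3' terminus is `end` (the first base
#' beyond the feature is `end`); for `-` it is `start`.
#' @param gr A `GRanges`.
#' @return Integer vector of 3'-end boundary coordinates (0-based).
#' @keywords internal
.end3 <- function(gr) {
  ifelse(as.character(GenomicRanges::strand(gr)) == "+",
         GenomicRanges::end(gr), GenomicRanges::start(gr) - 1L)
}

# GRanges are 1-based closed; all exported coordinate arguments in this package
# are 0-based half-open. These two converters are the only place the shift
# happens.
.gr_from_0based <- function(chrom, start, end, strand, ...) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start + 1L, end = end),
                         strand = strand, ...)
}

.gr_start0 <- function(gr) GenomicRanges::start(gr) - 1L
.gr_end0 <- function(gr) GenomicRanges::end(gr)
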