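# Genomic-environment classification of down-regulated genes: convergent vs
# tandem orientation, neighbor readthrough flags, and category tallies.

#' Classify a gene's orientation with respect to its nearest downstream mRNA
#'
#' Looks beyond the gene's strand-aware 3' end for the nearest annotated
#' mRNA within `horizon`; the orientation is `"C"` (convergent) when that
#' neighbor lies on the opposite strand (its 3' end faces the gene) and
#' `"T"` (tandem) when it lies on the same strand.
#'
#' @param gene Length-1 `GRanges`.
#' @param annotation TranscriptSet `GRanges`.
#' @param horizon Maximum distance (nt) to the neighbor.
#' @return `"C"`, `"T"`, or `NA` when no mRNA neighbor exists within the
#'   horizon.
#' @export
classify_orientation <- function(gene, annotation, horizon = 5000L) {
  nb <- .nearest_downstream(gene, annotation, horizon, classes = "mRNA")
  if (is.na(nb)) return(NA_character_)
  same <- as.character(GenomicRanges::strand(annotation[nb])) ==
    as.character(GenomicRanges::strand(gene))
  if (same) "T" else "C"
}

# index of the nearest feature beyond the gene's 3' end within horizon,
# optionally restricted by class and/or strand relation; NA if none
.nearest_downstream <- function(gene, annotation, horizon,
                                classes = NULL, relation = c("any", "same",
                                                             "opposite")) {
  relation <- match.arg(relation)
  st <- as.character(GenomicRanges::strand(gene))
  e3 <- .end3(gene)
  cand <- seq_along(annotation)
  cand <- cand[as.character(GenomicRanges::seqnames(annotation)) ==
                 as.character(GenomicRanges::seqnames(gene))]
  self <- !is.null(names(gene)) &&
    !is.null(annotation$id) # drop the gene itself by id when possible
  if (self) cand <- cand[annotation$id[cand] != gene$id]
  if (!is.null(classes))
    cand <- cand[as.character(annotation$rna_class[cand]) %in% classes]
  if (relation != "any") {
    same <- as.character(GenomicRanges::strand(annotation[cand])) == st
    cand <- if (relation == "same") cand[same] else cand[!same]
  }
  if (!length(cand)) return(NA_integer_)
  s0 <- .gr_start0(annotation)[cand]; e0 <- .gr_end0(annotation)[cand]
  if (st == "+") {
    ds <- cand[s0 >= e3]
    if (!length(ds)) return(NA_integer_)
    j <- ds[which.min(.gr_start0(annotation)[ds])]
    if (.gr_start0(annotation)[j] - e3 > horizon) return(NA_integer_)
  } else {
    ds <- cand[e0 <= e3 + 1L]
    if (!length(ds)) return(NA_integer_)
    j <- ds[which.max(.gr_end0(annotation)[ds])]
    if (e3 + 1L - .gr_end0(annotation)[j] > horizon) return(NA_integer_)
  }
  j
}

# upstream same-strand neighbor (the gene whose readthrough would run into
# this gene's 5' end); NA if none within horizon
.nearest_upstream_same <- function(gene, annotation, horizon) {
  st <- as.character(GenomicRanges::strand(gene))
  s0 <- .gr_start0(gene); e0 <- .gr_end0(gene)
  tss <- if (st == "+") s0 else e0 # 5' boundary
  cand <- seq_along(annotation)
  cand <- cand[as.character(GenomicRanges::seqnames(annotation)) ==
                 as.character(GenomicRanges::seqnames(gene)) &
                 as.character(GenomicRanges::strand(annotation)) == st]
  if (!is.null(annotation$id)) cand <- cand[annotation$id[cand] != gene$id]
  if (!length(cand)) return(NA_integer_)
  as0 <- .gr_start0(annotation)[cand]; ae0 <- .gr_end0(annotation)[cand]
  if (st == "+") {
    us <- cand[.gr_end0(annotation)[cand] <= s0]
    if (!length(us)) return(NA_integer_)
    j <- us[which.max(.gr_end0(annotation)[us])]
    if (s0 - .gr_end0(annotation)[j] > horizon) return(NA_integer_)
  } else {
    us <- cand[.gr_start0(annotation)[cand] >= e0]
    if (!length(us)) return(NA_integer_)
    j <- us[which.min(.gr_start0(annotation)[us])]
    if (.gr_start0(annotation)[j] - e0 > horizon) return(NA_integer_)
  }
  j
}

#' Annotate the genomic environment of one down-regulated gene
#'
#' Combines orientation, neighbor readthrough calls and the expression
#' change into an environment record: `conv_mRNA_RT` is set when a
#' convergent (opposite-strand downstream) mRNA neighbor is readthrough-
#' flagged, `conv_ncRNA_RT` likewise for CUT/SUT/snoRNA neighbors, and
#' `tandem_RT` when the upstream same-strand gene is flagged.
#'
#' @param gene Length-1 `GRanges`.
#' @param annotation TranscriptSet `GRanges`.
#' @param readthrough_calls `data.frame`/`data.table` with `id` and logical
#'   `readthrough`.
#' @param de_table `data.frame` with `id` and `log2fc`; the gene must be
#'   present.
#' @param horizon Neighbor search distance (nt).
#' @return One-row `data.table`: `id`, `expression_change`, `orientation`,
#'   `conv_mRNA_RT`, `conv_ncRNA_RT`, `tandem_RT`, `no_interference`.
#' @export
annotate_environment <- function(gene, annotation, readthrough_calls,
                                 de_table, horizon = 5000L) {
  de <- data.table::as.data.table(de_table)
  .assert(gene$id %in% de$id, "gene %s absent from DE table", gene$id)
  calls <- data.table::as.data.table(readthrough_calls)
  rt_of <- function(j) {
    if (is.na(j)) return(FALSE)
    hit <- calls$readthrough[calls$id == annotation$id[j]]
    length(hit) == 1L && isTRUE(hit)
  }
  orientation <- classify_orientation(gene, annotation, horizon)
  conv_mRNA <- .nearest_downstream(gene, annotation, horizon,
                                   classes = "mRNA", relation = "opposite")
  conv_ncRNA <- .nearest_downstream(gene, annotation, horizon,
                                    classes = c("CUT", "SUT", "snoRNA"),
                                    relation = "opposite")
  tandem_up <- .nearest_upstream_same(gene, annotation, horizon)
  rec <- data.table::data.table(
    id = gene$id,
    expression_change = de$log2fc[match(gene$id, de$id)],
    orientation = orientation,
    conv_mRNA_RT = rt_of(conv_mRNA),
    conv_ncRNA_RT = rt_of(conv_ncRNA),
    tandem_RT = rt_of(tandem_up))
  rec[, no_interference := !(conv_mRNA_RT | conv_ncRNA_RT | tandem_RT)]
  rec[]
}

#' Annotate environments for a set of genes
#' @param genes TranscriptSet `GRanges` subset to annotate.
#' @inheritParams annotate_environment
#' @return `data.table` of environment records.
#' @export
annotate_environments <- function(genes, annotation, readthrough_calls,
                                  de_table, horizon = 5000L) {
  data.table::rbindlist(lapply(seq_along(genes), function(i)
    annotate_environment(genes[i], annotation, readthrough_calls, de_table,
                         horizon)))
}

#' Tally environment categories over the most down-regulated genes
#'
#' Orders records by expression change (most down-regulated first), drops
#' `exclude` ids (e.g. the gene deleted in the mutant, whose apparent
#' down-regulation is trivial), keeps the top `top_n`, and counts:
#' convergent orientation, convergent with mRNA readthrough, convergent
#' ncRNA readthrough, tandem-readthrough-only, and no interference.
#'
#' @param records Environment records (`data.table` with the columns of
#'   [annotate_environment()]; `conv_*`/`tandem_RT` may be logical or
#'   `"Y"`/`""`).
#' @param top_n Genes to tally after exclusions.
#' @param exclude Ids to drop before ranking.
#' @return Named list of counts: `n`, `convergent`, `conv_mRNA_RT`,
#'   `conv_ncRNA_RT`, `tandem_RT_only`, `no_interference`.
#' @export
tally_environments <- function(records, top_n, exclude = character(0)) {
  dt <- data.table::as.data.table(records)
  to_flag <- function(x) {
    if (is.logical(x)) x else !is.na(x) & toupper(trimws(x)) == "Y"
  }
  for (col in c("conv_mRNA_RT", "conv_ncRNA_RT", "tandem_RT"))
    dt[, (col) := to_flag(dt[[col]])]
  dt <- dt[!id %in% exclude]
  .assert(top_n <= nrow(dt), "top_n = %d exceeds %d available records",
          top_n, nrow(dt))
  dt <- dt[order(expression_change)][seq_len(top_n)]
  list(n = nrow(dt),
       convergent = sum(dt$orientation == "C", na.rm = TRUE),
       conv_mRNA_RT = sum(dt$orientation == "C" & dt$conv_mRNA_RT,
                          na.rm = TRUE),
       conv_ncRNA_RT = sum(dt$conv_ncRNA_RT),
       tandem_RT_only = sum(dt$tandem_RT & !dt$conv_mRNA_RT &
                              !dt$conv_ncRNA_RT),
       no_interference = sum(!dt$conv_mRNA_RT & !dt$conv_ncRNA_RT &
                               !dt$tandem_RT))
}

#' Load the shipped top-30 down-regulated gene table
#'
#' A TSV transcription of the published table of the 30 most down-regulated
#' genes (plus the deleted gene itself) with orientation and neighbor-
#' readthrough annotations, used for exact environment-tally checks.
#'
#' @return `data.table` with columns `id`, `expression_change`,
#'   `orientation`, `conv_mRNA_RT`, `conv_ncRNA_RT`, `tandem_RT`.
#' @export
load_downregulated_table <- function() {
  path <- system.file("extdata", "downregulated_top30.tsv",
                      package = "readthroughr")
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = ".",
                    colClasses = "character")[
                      , expression_change := as.numeric(expression_change)][]
}
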