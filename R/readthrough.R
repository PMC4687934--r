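# Genome-wide readthrough statistic: per-transcript windows, median-based
# scores, mutant-vs-WT ratios, a WT-replicate empirical null, BH-FDR calls,
# inclusion and expression filters, and ranking.

#' Define the DN100/DN200/TRAN windows for one transcript
#'
#' DN100 is the 100 nt immediately 3' of the transcript end (strand-aware),
#' DN200 the 200 nt starting immediately after DN100, and TRAN the transcript
#' minus its first and last 50 nt. All coordinates 0-based half-open.
#'
#' @param transcript A length-1 `GRanges`.
#' @return List with elements `dn100`, `dn200`, `tran`, each a list
#'   `(chrom, start, end, strand)`.
#' @export
define_windows <- function(transcript) {
  .assert(length(transcript) == 1L, "define_windows takes a single transcript")
  s0 <- .gr_start0(transcript); e0 <- .gr_end0(transcript)
  .assert(e0 - s0 > 100L, "transcript length %d <= 100 nt: TRAN window empty",
          e0 - s0)
  st <- as.character(GenomicRanges::strand(transcript))
  chrom <- as.character(GenomicRanges::seqnames(transcript))
  iv <- function(a, b) list(chrom = chrom, start = as.integer(a),
                            end = as.integer(b), strand = st)
  if (st == "+") {
    list(dn100 = iv(e0, e0 + 100L), dn200 = iv(e0 + 100L, e0 + 300L),
         tran = iv(s0 + 50L, e0 - 50L))
  } else {
    list(dn100 = iv(s0 - 100L, s0), dn200 = iv(s0 - 300L, s0 - 100L),
         tran = iv(s0 + 50L, e0 - 50L))
  }
}

# vectorized window table for all transcripts longer than 100 nt
.windows_table <- function(tx) {
  s0 <- .gr_start0(tx); e0 <- .gr_end0(tx)
  st <- as.character(GenomicRanges::strand(tx))
  plus <- st == "+"
  data.table::data.table(
    id = tx$id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = st,
    length = e0 - s0,
    dn100_start = ifelse(plus, e0, s0 - 100L),
    dn100_end = ifelse(plus, e0 + 100L, s0),
    dn200_start = ifelse(plus, e0 + 100L, s0 - 300L),
    dn200_end = ifelse(plus, e0 + 300L, s0 - 100L),
    tran_start = s0 + 50L,
    tran_end = e0 - 50L)
}

#' Inclusion filter for the genome-wide readthrough analysis
#'
#' A transcript is retained when (a) it is at least `min_length` nt long,
#' (b) the nearest same-strand annotated feature beyond its 3' end is at
#' least `clearance` nt away — except when the transcript is an mRNA and
#' that feature is a CUT or SUT (such ncRNAs often are the mRNA's own
#' readthrough product) — and (c) each of DN100, DN200 and TRAN contains at
#' least `min_probes` probes.
#'
#' @param transcripts TranscriptSet `GRanges` (all features participate in
#'   spacing checks).
#' @param probe_track A `ProbeTrack`.
#' @param min_length Minimum transcript length (nt).
#' @param clearance Required same-strand downstream gap (nt).
#' @param min_probes Minimum probes per window.
#' @param classes Classes entering the analysis (others only serve as
#'   spacing neighbors).
#' @return `data.table` with per-gene pass flags `incl_length`,
#'   `incl_spacing`, `incl_probes`, overall `eligible`, and probe counts.
#' @export
inclusion_filter <- function(transcripts, probe_track, min_length = 200L,
                             clearance = 400L, min_probes = 8L,
                             classes = c("mRNA", "snoRNA", "CUT", "SUT")) {
  tx <- transcripts
  st <- as.character(GenomicRanges::strand(tx))
  chr <- as.character(GenomicRanges::seqnames(tx))
  s0 <- .gr_start0(tx); e0 <- .gr_end0(tx)
  e3 <- .end3(tx)
  len <- e0 - s0
  n <- length(tx)
  cls <- as.character(tx$rna_class)

  incl_spacing <- rep(TRUE, n)
  for (i in seq_len(n)) {
    same <- which(st == st[i] & chr == chr[i])
    same <- same[same != i]
    if (!length(same)) next
    if (st[i] == "+") {
      ds <- same[s0[same] >= e3[i]]
      if (!length(ds)) next
      j <- ds[which.min(s0[ds])]
      gap <- s0[j] - e3[i]
    } else {
      ds <- same[e0[same] <= e3[i] + 1L]
      if (!length(ds)) next
      j <- ds[which.max(e0[ds])]
      gap <- e3[i] + 1L - e0[j]
    }
    if (gap < clearance) {
      incl_spacing[i] <- cls[i] == "mRNA" && cls[j] %in% c("CUT", "SUT")
    }
  }

  win <- .windows_table(tx)
  cache <- .probe_cache(probe_track)
  counts <- t(.window_probe_counts(win, cache))
  counts[len <= 100L, ] <- 0L

  out <- data.table::data.table(
    id = tx$id,
    rna_class = as.character(tx$rna_class),
    length = len,
    incl_length = len >= min_length,
    incl_spacing = incl_spacing,
    n_dn100 = counts[, 1], n_dn200 = counts[, 2], n_tran = counts[, 3],
    incl_probes = counts[, 1] >= min_probes & counts[, 2] >= min_probes &
      counts[, 3] >= min_probes)
  out[, eligible := incl_length & incl_spacing & incl_probes &
        rna_class %in% classes]
  out[]
}

#' Readthrough score for one gene and one sample
#'
#' Median log2 probe intensity in DN200 minus the median in TRAN.
#'
#' @param windows Output of [define_windows()].
#' @param probe_track A `ProbeTrack`.
#' @param sample Sample column name.
#' @param min_probes Windows with fewer probes are invalid.
#' @return Log2 score (scalar).
#' @export
readthrough_score <- function(windows, probe_track, sample, min_probes = 8L) {
  med <- function(w) {
    v <- probe_query(probe_track, w$chrom, w$start, w$end, w$strand)[[sample]]
    .assert(length(v) >= min_probes,
            "window [%d,%d) has %d probes (< %d): invalid window",
            w$start, w$end, length(v), min_probes)
    median(v)
  }
  med(windows$dn200) - med(windows$tran)
}

#' Readthrough ratio: mutant score minus wild-type score
#' @param score_mut,score_wt Per-sample readthrough scores (log2).
#' @return `score_mut - score_wt` (antisymmetric in its arguments).
#' @export
readthrough_ratio <- function(score_mut, score_wt) {
  .assert(all(is.finite(score_mut)) && all(is.finite(score_wt)),
          "scores must be finite")
  score_mut - score_wt
}

#' Empirical null distribution of readthrough ratios
#'
#' One null ratio per eligible gene: the wild-type replicate 2 score minus
#' the wild-type replicate 1 score. Identical tracks give exactly zero.
#'
#' @param scores `data.table`/data.frame with columns `wt_1` and `wt_2`
#'   holding per-gene readthrough scores for the eligible genes.
#' @return Numeric vector of null ratios (one per eligible gene).
#' @export
empirical_null <- function(scores) {
  .assert(nrow(scores) > 0L, "empty eligible gene set: no null distribution")
  scores$wt_2 - scores$wt_1
}

#' One-sided empirical p-value against a null distribution
#'
#' `p = (1 + #{null >= ratio}) / (1 + n_null)`: larger ratios (more
#' readthrough) are more significant; ties with the null count against the
#' observation; p is never 0.
#'
#' @param ratio Observed ratio(s).
#' @param null_distribution Numeric vector of null ratios.
#' @return p-value(s) in (0, 1].
#' @export
empirical_pvalue <- function(ratio, null_distribution) {
  .assert(length(null_distribution) > 0L, "null distribution is empty")
  .assert(all(is.finite(ratio)), "non-finite ratio")
  vapply(ratio, function(r) (1 + sum(null_distribution >= r)) /
           (1 + length(null_distribution)), numeric(1))
}

#' Benjamini-Hochberg step-up at level alpha
#'
#' Own implementation of the standard step-up rule (kept independent of
#' `stats::p.adjust`, which the tests use as the reference oracle).
#'
#' @param pvalues p-values in (0, 1].
#' @param alpha FDR level.
#' @return Logical significance flags aligned with the input order.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0L) return(logical(0))
  .assert(all(pvalues > 0 & pvalues <= 1), "p-values must lie in (0, 1]")
  o <- order(pvalues)
  ps <- pvalues[o]
  ok <- ps <= seq_len(m) * alpha / m
  if (!any(ok)) return(rep(FALSE, m))
  k <- max(which(ok))
  flags <- rep(FALSE, m)
  flags[o[seq_len(k)]] <- TRUE
  flags
}

#' Expression filters for readthrough reliability
#'
#' Implements the four per-gene filters: (i) fewer than `max_cbc1` Cbc1 CRAC
#' reads overlapping DN100 (evidence of independent downstream initiation),
#' (ii) mean-of-replicates TRAN median above `expr_floor` in both strains,
#' (iii) mutant DN100 median above `frac` of the mutant TRAN median, and
#' (iv) mutant TRAN median at least `frac` of the wild-type TRAN median.
#' Filters (ii)-(iv) use the mean of the two replicates.
#'
#' "`frac` of" is taken as a linear fraction of the median log2 value
#' (`fraction_scale = "linear_on_log2"`, the Methods' literal reading —
#' note log2 medians can be negative); `"linear_on_intensity"` instead
#' compares on the linear intensity scale (`x > y + log2(frac)`).
#'
#' @param medians One row per gene: window medians per sample, columns
#'   `dn100_<s>` and `tran_<s>` for each of `wt_1,wt_2,mut_1,mut_2`.
#' @param cbc1_dn100 Integer vector: Cbc1 reads overlapping DN100 per gene,
#'   or `NULL` if unavailable.
#' @param max_cbc1,expr_floor,frac Thresholds.
#' @param fraction_scale See above.
#' @param cbc1_missing `"fail"` (default, fail closed) or `"pass"` when no
#'   Cbc1 data are supplied.
#' @return `data.table` of flags `f_cbc1`, `f_expr_floor`, `f_dn100_frac`,
#'   `f_tran_frac` and overall `pass` (TRUE = filter passed).
#' @export
expression_filters <- function(medians, cbc1_dn100 = NULL, max_cbc1 = 10L,
                               expr_floor = -4.88, frac = 0.7,
                               fraction_scale = c("linear_on_log2",
                                                  "linear_on_intensity"),
                               cbc1_missing = c("fail", "pass")) {
  fraction_scale <- match.arg(fraction_scale)
  cbc1_missing <- match.arg(cbc1_missing)
  md <- data.table::as.data.table(medians)
  n <- nrow(md)
  tran_wt <- (md$tran_wt_1 + md$tran_wt_2) / 2
  tran_mut <- (md$tran_mut_1 + md$tran_mut_2) / 2
  dn100_mut <- (md$dn100_mut_1 + md$dn100_mut_2) / 2

  f_cbc1 <- if (is.null(cbc1_dn100)) {
    rep(cbc1_missing == "pass", n)
  } else cbc1_dn100 < max_cbc1
  f_expr_floor <- tran_wt > expr_floor & tran_mut > expr_floor
  cmp_frac <- function(x, y) {
    if (fraction_scale == "linear_on_log2") x > frac * y
    else x > y + log2(frac)
  }
  f_dn100_frac <- cmp_frac(dn100_mut, tran_mut)
  f_tran_frac <- cmp_frac(tran_mut, tran_wt)

  data.table::data.table(f_cbc1 = f_cbc1, f_expr_floor = f_expr_floor,
                         f_dn100_frac = f_dn100_frac,
                         f_tran_frac = f_tran_frac,
                         pass = f_cbc1 & f_expr_floor & f_dn100_frac &
                           f_tran_frac)
}

#' Rank genes by readthrough ratio
#'
#' Rank 1 is the largest mean-of-experiments ratio; ties receive the average
#' rank.
#'
#' @param ratios Numeric vector (mean readthrough ratio per gene).
#' @return Numeric ranks aligned with the input.
#' @export
rank_genes <- function(ratios) {
  rank(-ratios, ties.method = "average")
}

#' Spearman correlation of readthrough ratio with gene length
#' @param ratio,length Aligned numeric vectors (>= 3 genes).
#' @return List with `rho` and two-sided `p`.
#' @export
length_correlation <- function(ratio, length) {
  .assert(length(ratio) >= 3L, "need >= 3 records")
  .assert(stats::sd(ratio) > 0 && stats::sd(length) > 0,
          "constant vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(ratio, length, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# Sorted-position cache for fast window lookups: probe_query's keyed join is
# convenient interactively but too slow for thousands of windows.
.probe_cache <- function(track, samples = attr(track, "samples")) {
  grp <- paste(track$chrom, track$strand)
  idx <- split(seq_len(nrow(track)), grp)
  lapply(idx, function(ix) {
    list(pos = track$position[ix], # sorted: track is keyed on position
         mat = as.matrix(track[ix, samples, with = FALSE]))
  })
}

# row index range of probes with a <= pos < b (binary search); NULL if none
.cache_range <- function(g, a, b) {
  if (is.null(g)) return(NULL)
  lo <- findInterval(a - 0.5, g$pos) + 1L
  hi <- findInterval(b - 0.5, g$pos)
  if (hi < lo) NULL else c(lo, hi)
}

.window_probe_counts <- function(win, cache) {
  vapply(seq_len(nrow(win)), function(i) {
    g <- cache[[paste(win$chrom[i], win$strand[i])]]
    cnt <- function(a, b) {
      r <- .cache_range(g, a, b)
      if (is.null(r)) 0L else r[2] - r[1] + 1L
    }
    c(cnt(win$dn100_start[i], win$dn100_end[i]),
      cnt(win$dn200_start[i], win$dn200_end[i]),
      cnt(win$tran_start[i], win$tran_end[i]))
  }, integer(3))
}

# window medians for eligible genes: one row per gene, columns
# <window>_<sample>
.window_medians <- function(win, probe_track,
                            samples = attr(probe_track, "samples")) {
  cache <- .probe_cache(probe_track, samples)
  res <- lapply(seq_len(nrow(win)), function(i) {
    g <- cache[[paste(win$chrom[i], win$strand[i])]]
    meds <- lapply(list(dn100 = c(win$dn100_start[i], win$dn100_end[i]),
                        dn200 = c(win$dn200_start[i], win$dn200_end[i]),
                        tran = c(win$tran_start[i], win$tran_end[i])),
                   function(ab) {
      r <- .cache_range(g, ab[1], ab[2])
      if (is.null(r)) return(setNames(rep(NA_real_, length(samples)),
                                      samples))
      apply(g$mat[r[1]:r[2], , drop = FALSE], 2, median)
    })
    unlist(lapply(names(meds), function(wn)
      setNames(meds[[wn]], paste0(wn, "_", samples))))
  })
  dt <- data.table::as.data.table(do.call(rbind, res))
  dt[, id := win$id]
  dt
}

#' Genome-wide readthrough analysis
#'
#' Runs the full statistic: inclusion filters, per-sample scores, per-
#' experiment ratios (experiment 1 pairs `mut_1` vs `wt_1`, experiment 2
#' `mut_2` vs `wt_2`), the shared `wt_2 - wt_1` empirical null, one-sided
#' empirical p-values, per-experiment BH-FDR calls and their intersection,
#' expression filters, and ranking of the genes passing all filters.
#'
#' @param transcripts TranscriptSet `GRanges`.
#' @param probe_track A `ProbeTrack` with the four standard samples.
#' @param cbc1 Optional Cbc1 `ReadSet` for filter (i).
#' @param alpha BH-FDR level.
#' @param min_length,clearance,min_probes Inclusion thresholds.
#' @param max_cbc1,expr_floor,frac,fraction_scale,cbc1_missing Passed to
#'   [expression_filters()].
#' @return `data.table`, one row per transcript, with filter flags, scores,
#'   ratios, p/q flags, `significant_both`, `mean_ratio` and `rank` (NA for
#'   genes failing any filter).
#' @export
readthrough_analysis <- function(transcripts, probe_track, cbc1 = NULL,
                                 alpha = 0.05, min_length = 200L,
                                 clearance = 400L, min_probes = 8L,
                                 max_cbc1 = 10L, expr_floor = -4.88,
                                 frac = 0.7,
                                 fraction_scale = "linear_on_log2",
                                 cbc1_missing = "fail") {
  incl <- inclusion_filter(transcripts, probe_track, min_length, clearance,
                           min_probes)
  win <- .windows_table(transcripts)
  elig <- incl$eligible
  res <- data.table::copy(incl)

  for (col in c(paste0("score_", SAMPLE_IDS), "ratio_1", "ratio_2",
                "null_ratio", "p_1", "p_2", "mean_ratio", "rank"))
    res[, (col) := NA_real_]
  for (col in c("sig_1", "sig_2", "significant_both", "f_cbc1",
                "f_expr_floor", "f_dn100_frac", "f_tran_frac",
                "pass_filters"))
    res[, (col) := NA]

  if (!any(elig)) return(res[])

  md <- .window_medians(win[elig], probe_track)
  scores <- data.table::data.table(id = md$id)
  for (s in SAMPLE_IDS)
    scores[, (s) := md[[paste0("dn200_", s)]] - md[[paste0("tran_", s)]]]

  # locals carry a dot prefix: bare names would resolve to the (all-NA)
  # columns inside the `:=` call below
  .ratio_1 <- readthrough_ratio(scores$mut_1, scores$wt_1)
  .ratio_2 <- readthrough_ratio(scores$mut_2, scores$wt_2)
  .null <- empirical_null(scores)
  .p_1 <- empirical_pvalue(.ratio_1, .null)
  .p_2 <- empirical_pvalue(.ratio_2, .null)
  .sig_1 <- bh_fdr(.p_1, alpha)
  .sig_2 <- bh_fdr(.p_2, alpha)

  cbc1_dn100 <- if (!is.null(cbc1)) {
    .count_overlapping_reads(cbc1, win[elig],
                             c("dn100_start", "dn100_end"))
  } else NULL
  ef <- expression_filters(md, cbc1_dn100, max_cbc1, expr_floor, frac,
                           fraction_scale, cbc1_missing)

  idx <- which(elig)
  res[idx, `:=`(score_wt_1 = scores$wt_1, score_wt_2 = scores$wt_2,
                score_mut_1 = scores$mut_1, score_mut_2 = scores$mut_2,
                ratio_1 = .ratio_1, ratio_2 = .ratio_2, null_ratio = .null,
                p_1 = .p_1, p_2 = .p_2, sig_1 = .sig_1, sig_2 = .sig_2,
                significant_both = .sig_1 & .sig_2,
                f_cbc1 = ef$f_cbc1, f_expr_floor = ef$f_expr_floor,
                f_dn100_frac = ef$f_dn100_frac, f_tran_frac = ef$f_tran_frac,
                pass_filters = ef$pass,
                mean_ratio = (.ratio_1 + .ratio_2) / 2)]
  pass <- which(elig)[ef$pass]
  if (length(pass))
    res[pass, rank := rank_genes(res$mean_ratio[pass])]
  res[]
}

# reads overlapping (>= 1 nt, matching strand) the given window per gene
.count_overlapping_reads <- function(readset, win, cols) {
  gr <- readset$reads
  vapply(seq_len(nrow(win)), function(i) {
    w <- win[i]
    a <- w[[cols[1]]]; b <- w[[cols[2]]]
    hit <- as.character(GenomicRanges::seqnames(gr)) == w$chrom &
      as.character(GenomicRanges::strand(gr)) == w$strand &
      .gr_start0(gr) < b & .gr_end0(gr) > a
    sum(hit)
  }, numeric(1))
}
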