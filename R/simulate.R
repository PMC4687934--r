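# Ground-truth simulator emulating the statistical structure of strand-specific
# yeast tiling arrays (log2 probe intensities, Gaussian probe noise, injected
# 3'-extension signal in the mutant) and CRAC-style stranded short reads
# (positional binding bias, non-templated oligo(A) tails).

#' Simulation configuration
#'
#' Defaults describe a yeast-like chromosome: ~1.4 kb log-normal transcripts,
#' a few hundred nt intergenic gaps, 8-nt tiling probe step, log2 expression
#' around 2 with probe noise sd 0.5, and in the mutant a +3 log2 readthrough
#' signal decaying with a 500 nt half-length downstream of affected 3' ends.
#'
#' @param n_genes Number of transcripts to place.
#' @param chrom_length Chromosome length (nt); `NULL` sizes it to fit.
#' @param probe_step Tiling probe spacing (nt), both strands.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal transcript length.
#' @param gap_meanlog,gap_sdlog Log-normal intergenic gap.
#' @param fraction_readthrough_genes Proportion of genes given a 3' extension
#'   in the mutant.
#' @param readthrough_delta Log2 units added at distance 0 downstream of an
#'   affected gene's 3' end in the mutant samples.
#' @param readthrough_decay_halflength Distance (nt) at which the injected
#'   signal halves: the added intensity is `delta * 2^(-d/halflength)`.
#' @param noise_sd Gaussian probe noise sd (log2 units).
#' @param background_intensity Log2 intensity outside transcripts.
#' @param expr_mean,expr_sd Per-gene true log2 expression distribution.
#' @param fraction_convergent_pairs Proportion of genes arranged as convergent
#'   (3'-facing, opposite-strand) pairs.
#' @param crac_bias Positional read bias: `"five_prime"`, `"three_prime"` or
#'   `"uniform"`.
#' @param oligoA_fraction Proportion of reads carrying a non-templated 3'
#'   oligo(A) tail (length >= 2).
#' @param reads_per_sample Reads to draw per simulated CRAC sample.
#' @param read_length Read length (nt).
#' @param seed Integer seed; every operation derives its stream from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 500,
                       chrom_length = NULL,
                       probe_step = 8,
                       gene_length_meanlog = log(1400),
                       gene_length_sdlog = 0.35,
                       gap_meanlog = log(700),
                       gap_sdlog = 0.6,
                       fraction_readthrough_genes = 0.3,
                       readthrough_delta = 3,
                       readthrough_decay_halflength = 500,
                       noise_sd = 0.5,
                       background_intensity = -7,
                       expr_mean = 2,
                       expr_sd = 1.5,
                       fraction_convergent_pairs = 0.15,
                       crac_bias = c("five_prime", "three_prime", "uniform"),
                       oligoA_fraction = 0.25,
                       reads_per_sample = 50000,
                       read_length = 30,
                       seed = 1) {
  crac_bias <- match.arg(crac_bias)
  cfg <- list(n_genes = n_genes, chrom_length = chrom_length,
              probe_step = probe_step,
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
              fraction_readthrough_genes = fraction_readthrough_genes,
              readthrough_delta = readthrough_delta,
              readthrough_decay_halflength = readthrough_decay_halflength,
              noise_sd = noise_sd, background_intensity = background_intensity,
              expr_mean = expr_mean, expr_sd = expr_sd,
              fraction_convergent_pairs = fraction_convergent_pairs,
              crac_bias = crac_bias, oligoA_fraction = oligoA_fraction,
              reads_per_sample = reads_per_sample, read_length = read_length,
              seed = seed)
  for (p in c("fraction_readthrough_genes", "fraction_convergent_pairs",
              "oligoA_fraction"))
    .assert(cfg[[p]] >= 0 && cfg[[p]] <= 1, "%s must be in [0,1]", p)
  .assert(cfg$noise_sd > 0, "noise_sd must be > 0")
  .assert(cfg$probe_step >= 1, "probe_step must be >= 1")
  .assert(.is_count(cfg$n_genes) && cfg$n_genes >= 1, "n_genes must be >= 1")
  structure(cfg, class = "sim_config")
}

# Run expr with a private RNG stream (seed + fixed per-operation offset) so
# that draws in one operation never perturb another.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.SEED_OFFSETS <- c(genome = 11L, probes = 23L, reads = 37L, sequence = 53L,
                   motif = 71L)

#' Simulate a transcript annotation with known ground truth
#'
#' Places non-overlapping genes along one chromosome with log-normal lengths
#' and gaps, arranges the requested fraction into convergent (3'-facing)
#' pairs, assigns classes (mRNA majority plus snoRNA/CUT/SUT), and draws the
#' per-gene truth: log2 expression, readthrough flag and delta, and the
#' realized genomic-environment label.
#'
#' @param config A [sim_config()].
#' @return List with `transcripts` (a TranscriptSet `GRanges` with
#'   `polyA` = annotated 3' end) and `truth` (a `data.table`: `id`, `expr`,
#'   `readthrough`, `delta`, `environment`, `conv_pair`). `environment` is
#'   the realized layout label (random strands also create incidental
#'   convergent neighbors); `conv_pair` marks genes in deliberately arranged
#'   convergent pairs.
#' @export
simulate_genome <- function(config) {
  cfg <- config
  .with_seed(cfg$seed + .SEED_OFFSETS[["genome"]], {
    n <- cfg$n_genes
    len <- pmax(200L, as.integer(round(
      rlnorm(n, cfg$gene_length_meanlog, cfg$gene_length_sdlog))))
    gap <- pmax(150L, as.integer(round(
      rlnorm(n, cfg$gap_meanlog, cfg$gap_sdlog))))

    # convergent pairs occupy consecutive slots (+ gene then - gene); each
    # disjoint slot pair independently becomes convergent with the configured
    # probability, so the realized paired fraction is binomial around it
    strand <- sample(c("+", "-"), n, replace = TRUE)
    heads <- seq(1L, n - 1L, by = 2L)
    is_head <- heads[as.logical(rbinom(length(heads), 1,
                                       cfg$fraction_convergent_pairs))]
    conv_pair <- rep(FALSE, n)
    if (length(is_head)) {
      conv_pair[is_head] <- TRUE
      conv_pair[is_head + 1L] <- TRUE
      strand[is_head] <- "+"
      strand[is_head + 1L] <- "-"
    }

    start0 <- integer(n)
    pos <- 1000L
    for (i in seq_len(n)) {
      start0[i] <- pos
      pos <- pos + len[i] + gap[i]
    }
    need <- pos + 1000L
    if (!is.null(cfg$chrom_length)) {
      .assert(cfg$chrom_length >= need,
              "genome too short for n_genes: need >= %d nt", need)
      chrom_length <- cfg$chrom_length
    } else chrom_length <- need

    cls <- sample(c("mRNA", "snoRNA", "CUT", "SUT"), n, replace = TRUE,
                  prob = c(0.85, 0.05, 0.05, 0.05))
    sno_class <- ifelse(cls == "snoRNA",
                        sample(c("monocistronic", "polycistronic"), n,
                               replace = TRUE, prob = c(0.85, 0.15)),
                        NA_character_)
    id <- sprintf("G%04d", seq_len(n))

    tx <- .gr_from_0based("chrSim", start0, start0 + len, strand,
                          id = id,
                          rna_class = factor(cls, levels = RNA_CLASSES),
                          sno_class = sno_class)
    tx$polyA <- .end3(tx)
    names(tx) <- id
    GenomeInfoDb::seqlengths(tx) <- c(chrSim = chrom_length)

    expr <- rnorm(n, cfg$expr_mean, cfg$expr_sd)
    rt <- rep(FALSE, n)
    n_rt <- round(cfg$fraction_readthrough_genes * n)
    if (n_rt > 0) rt[sample.int(n, n_rt)] <- TRUE
    delta <- ifelse(rt, cfg$readthrough_delta, 0)

    env <- .environment_labels(tx, horizon = 5000L)
    truth <- data.table::data.table(id = id, expr = expr, readthrough = rt,
                                    delta = delta, environment = env,
                                    conv_pair = conv_pair)
    list(transcripts = tx, truth = truth)
  })
}

# realized environment of each gene w.r.t. the nearest feature beyond its
# strand-aware 3' end (any strand) within `horizon`
.environment_labels <- function(tx, horizon = 5000L) {
  e3 <- .end3(tx)
  st <- as.character(GenomicRanges::strand(tx))
  s0 <- .gr_start0(tx); e0 <- .gr_end0(tx)
  vapply(seq_along(tx), function(i) {
    if (st[i] == "+") {
      ds <- which(s0 >= e3[i] & seq_along(tx) != i)
      if (!length(ds)) return("isolated")
      j <- ds[which.min(s0[ds])]
      if (s0[j] - e3[i] > horizon) return("isolated")
    } else {
      ds <- which(e0 <= e3[i] + 1L & seq_along(tx) != i)
      if (!length(ds)) return("isolated")
      j <- ds[which.max(e0[ds])]
      if (e3[i] + 1L - e0[j] > horizon) return("isolated")
    }
    if (st[j] == st[i]) "tandem" else "convergent"
  }, character(1))
}

#' Simulate tiling-array probe intensities
#'
#' Probes are laid every `probe_step` nt on both strands. The expected log2
#' intensity is `background_intensity` outside transcripts and the gene's
#' true expression inside it (same strand); mutant samples additionally gain
#' `delta * 2^(-d/halflength)` at distance `d` downstream of readthrough
#' genes' 3' ends. Each of the four samples gets independent `N(0, noise_sd^2)`
#' probe noise, so wild-type replicates differ only by noise.
#'
#' @param transcripts TranscriptSet from [simulate_genome()].
#' @param truth Ground-truth `data.table` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A `ProbeTrack` with samples `wt_1, wt_2, mut_1, mut_2`.
#' @export
simulate_probe_intensities <- function(transcripts, truth, config) {
  cfg <- config
  chrom_length <- GenomeInfoDb::seqlengths(transcripts)[["chrSim"]]
  pos <- seq.int(0L, chrom_length - 1L, by = cfg$probe_step)
  np <- length(pos)
  step <- cfg$probe_step

  mu <- list("+" = rep(cfg$background_intensity, np),
             "-" = rep(cfg$background_intensity, np))
  mu_rt <- list("+" = numeric(np), "-" = numeric(np))

  st <- as.character(GenomicRanges::strand(transcripts))
  s0 <- .gr_start0(transcripts); e0 <- .gr_end0(transcripts)
  e3 <- .end3(transcripts)
  span <- as.integer(10 * cfg$readthrough_decay_halflength)

  probe_idx <- function(a, b) { # probes with a <= pos < b
    lo <- ceiling(max(a, 0L) / step) + 1L
    hi <- floor((min(b, chrom_length) - 1L) / step) + 1L
    if (hi < lo) integer(0) else seq.int(lo, hi)
  }

  for (i in seq_along(transcripts)) {
    idx <- probe_idx(s0[i], e0[i])
    mu[[st[i]]][idx] <- truth$expr[i]
  }
  for (i in which(truth$readthrough)) {
    if (st[i] == "+") {
      idx <- probe_idx(e3[i], e3[i] + span)
      d <- pos[idx] - e3[i]
    } else {
      # first downstream base for a minus-strand gene is e3 - 1
      idx <- probe_idx(e3[i] - span, e3[i])
      d <- e3[i] - 1L - pos[idx]
    }
    mu_rt[[st[i]]][idx] <- mu_rt[[st[i]]][idx] +
      truth$delta[i] * 2^(-d / cfg$readthrough_decay_halflength)
  }

  .with_seed(cfg$seed + .SEED_OFFSETS[["probes"]], {
    make <- function(strand) {
      m <- sapply(SAMPLE_IDS, function(s) {
        base <- mu[[strand]] + rnorm(np, 0, cfg$noise_sd)
        if (startsWith(s, "mut")) base + mu_rt[[strand]] else base
      })
      data.table::data.table(chrom = "chrSim", position = pos, strand = strand,
                             m)
    }
    as_probe_track(rbind(make("+"), make("-")))
  })
}

#' Simulate CRAC-like stranded reads
#'
#' Reads are allocated to genes proportionally to linear-scale expression
#' (`2^expr`) and positioned within each gene under the configured bias
#' (5'-weighted Beta(1,3), 3'-weighted Beta(3,1), or uniform). A configured
#' fraction carries a non-templated 3' oligo(A) tail (`"AA"` plus a geometric
#' number of extra A). When `genome` is supplied, tails are extended past any
#' templated genomic A-run so the emitted fraction is genuinely
#' non-templated — the parameter states the truth the detector must recover.
#'
#' @param transcripts,truth,config As for [simulate_probe_intensities()].
#' @param genome Optional `DNAStringSet` used to guarantee non-templated tails.
#' @param n_reads Number of reads (default `config$reads_per_sample`).
#' @param seed_offset Added to the operation seed (lets callers draw
#'   independent samples, e.g. wt vs mutant).
#' @return A `ReadSet` with `oligoA` truth flag in the read metadata.
#' @export
simulate_crac_reads <- function(transcripts, truth, config, genome = NULL,
                                n_reads = NULL, seed_offset = 0L) {
  cfg <- config
  n_reads <- n_reads %||% cfg$reads_per_sample
  if (n_reads == 0)
    return(ReadSet(GenomicRanges::GRanges(tail3 = character(0)), 0L))
  chrom_length <- GenomeInfoDb::seqlengths(transcripts)[["chrSim"]]

  .with_seed(cfg$seed + .SEED_OFFSETS[["reads"]] + seed_offset, {
    w <- 2^truth$expr
    gi <- sample.int(length(transcripts), n_reads, replace = TRUE,
                     prob = w / sum(w))
    u <- switch(cfg$crac_bias,
                five_prime = stats::rbeta(n_reads, 1, 3),
                three_prime = stats::rbeta(n_reads, 3, 1),
                uniform = runif(n_reads))
    st <- as.character(GenomicRanges::strand(transcripts))[gi]
    s0 <- .gr_start0(transcripts)[gi]; e0 <- .gr_end0(transcripts)[gi]
    len <- e0 - s0
    off <- floor(u * pmax(1L, len - cfg$read_length))
    rstart <- ifelse(st == "+", s0 + off, e0 - off - cfg$read_length)
    rstart <- pmax(0L, pmin(rstart, chrom_length - cfg$read_length))
    gr <- .gr_from_0based("chrSim", as.integer(rstart),
                          as.integer(rstart + cfg$read_length), st)
    names(gr) <- sprintf("r%06d", seq_len(n_reads))

    has_tail <- as.logical(rbinom(n_reads, 1, cfg$oligoA_fraction))
    tail_len <- ifelse(has_tail, 2L + stats::rgeom(n_reads, 0.5), 0L)
    tails <- rep(NA_character_, n_reads)
    if (any(has_tail)) {
      if (!is.null(genome)) {
        tail_len[has_tail] <- vapply(which(has_tail), function(i) {
          .detemplate_tail_len(tail_len[i], gr[i], genome)
        }, integer(1))
      }
      tails[has_tail] <- strrep("A", tail_len[has_tail])
    }
    gr$tail3 <- tails
    gr$oligoA <- has_tail
    GenomeInfoDb::seqlengths(gr) <- c(chrSim = chrom_length)
    ReadSet(gr, n_reads)
  })
}

# extend an all-A tail until it mismatches the genomic template (or runs off
# the contig, which also counts as non-templated)
.detemplate_tail_len <- function(L, read, genome) {
  seqn <- as.character(GenomicRanges::seqnames(read))
  clen <- length(genome[[seqn]])
  st <- as.character(GenomicRanges::strand(read))
  repeat {
    tmpl <- .template_bases(read, genome, L)
    if (is.na(tmpl) || tmpl != strrep("A", L)) return(L)
    L <- L + 1L
    if (L > 50L) return(L) # pathological A-run; off-template by length
  }
}

# genomic bases the 3' tail would occupy, in read orientation; NA if off-contig
.template_bases <- function(read, genome, L) {
  seqn <- as.character(GenomicRanges::seqnames(read))
  clen <- length(genome[[seqn]])
  if (as.character(GenomicRanges::strand(read)) == "+") {
    a <- .gr_end0(read) # 0-based position just past the read
    if (a + L > clen) return(NA_character_)
    as.character(Biostrings::subseq(genome[[seqn]], a + 1L, a + L))
  } else {
    a <- .gr_start0(read) # tail extends leftward on the reference
    if (a - L < 0L) return(NA_character_)
    s <- Biostrings::subseq(genome[[seqn]], a - L + 1L, a)
    as.character(Biostrings::reverseComplement(s))
  }
}

#' Simulate a random genome sequence for the annotated chromosome
#' @param transcripts TranscriptSet carrying `seqlengths`.
#' @param config A [sim_config()] (seed source).
#' @return A `DNAStringSet` with one contig, `chrSim`.
#' @export
simulate_genome_sequence <- function(transcripts, config) {
  chrom_length <- GenomeInfoDb::seqlengths(transcripts)[["chrSim"]]
  .with_seed(config$seed + .SEED_OFFSETS[["sequence"]], {
    s <- paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
               collapse = "")
    g <- Biostrings::DNAStringSet(s)
    names(g) <- "chrSim"
    g
  })
}

#' Plant a motif upstream of polyA sites in a simulated genome
#'
#' Writes the DNA form of `motif` into the genome at a random sense-strand
#' offset within `at_range` (nt relative to the polyA site) for each selected
#' gene, strand-aware. Used to build motif-enrichment ground truth.
#'
#' @param genome `DNAStringSet`.
#' @param transcripts TranscriptSet with `polyA` coordinates.
#' @param gene_ids Genes to receive the motif.
#' @param motif RNA-alphabet motif (e.g. `"UAUAUA"`).
#' @param at_range Sense offsets (relative to polyA) within which the motif
#'   must fully fit; default the -80..-20 3' region.
#' @param seed Integer seed.
#' @return The modified genome.
#' @export
plant_motif <- function(genome, transcripts, gene_ids, motif = "UAUAUA",
                        at_range = c(-80, -20), seed = 1) {
  dna <- chartr("U", "T", motif)
  L <- nchar(dna)
  .with_seed(seed + .SEED_OFFSETS[["motif"]], {
    for (gid in gene_ids) {
      gx <- transcripts[gid]
      p <- gx$polyA
      o <- sample(seq(at_range[1], at_range[2] - L), 1L)
      seqn <- as.character(GenomicRanges::seqnames(gx))
      if (as.character(GenomicRanges::strand(gx)) == "+") {
        Biostrings::subseq(genome[[seqn]], p + o + 1L, p + o + L) <-
          Biostrings::DNAString(dna)
      } else {
        rc <- Biostrings::reverseComplement(Biostrings::DNAString(dna))
        Biostrings::subseq(genome[[seqn]], p - o - L + 1L, p - o) <- rc
      }
    }
    genome
  })
}

#' Write a self-contained simulated dataset to a directory
#'
#' Emits the same dialects the readers consume: `annotation.gff3`,
#' `probes.tsv`, `reads_wt.bed`/`reads_mut.bed`, `genome.fa` and
#' `truth.tsv`, plus the config as JSON.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  probes <- simulate_probe_intensities(sim$transcripts, sim$truth, config)
  genome <- simulate_genome_sequence(sim$transcripts, config)
  rd_wt <- simulate_crac_reads(sim$transcripts, sim$truth, config, genome,
                               seed_offset = 0L)
  rd_mut <- simulate_crac_reads(sim$transcripts, sim$truth, config, genome,
                                seed_offset = 1L)
  write_annotation(sim$transcripts, file.path(dir, "annotation.gff3"))
  write_probe_table(probes, file.path(dir, "probes.tsv"))
  write_genome(genome, file.path(dir, "genome.fa"))
  write_reads_bed(rd_wt, file.path(dir, "reads_wt.bed"))
  write_reads_bed(rd_mut, file.path(dir, "reads_mut.bed"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
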