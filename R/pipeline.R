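# End-to-end orchestration: a single config object carrying every analysis
# constant, staged execution with a machine-readable manifest, and a small
# subcommand-style CLI.

#' Build a run configuration
#'
#' Collects input paths and every tunable constant of the pipeline, with
#' defaults equal to the published analysis constants (window trims 100/200/
#' 50 nt, 8 probes/window, < 10 Cbc1 reads, -4.88 expression floor, 70%
#' median fractions, 500-nt snoRNA flank, 200/1200 Pol II group sizes,
#' -80..-20 motif region, k = 6, bottom-250 motif exclusion, FDR 0.05).
#'
#' @param annotation,probes,cbc1,reads_wt,reads_mut,genome,polyA_table,de_table
#'   Input paths (`NULL` = stage skipped; `cbc1` optional).
#' @param out_dir Output directory.
#' @param alpha FDR level.
#' @param min_length,clearance,min_probes Inclusion thresholds.
#' @param max_cbc1,expr_floor,frac,fraction_scale Expression-filter knobs.
#' @param flank_len snoRNA 3' flank (nt).
#' @param group_high,group_low Pol II profile group sizes.
#' @param motif_from,motif_to 3' motif region (nt relative to polyA).
#' @param k Motif length.
#' @param bottom_exclude Motif-set bottom exclusion count.
#' @param horizon Neighbor search distance (nt).
#' @param seed Integer seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(annotation = NULL, probes = NULL, cbc1 = NULL,
                       reads_wt = NULL, reads_mut = NULL, genome = NULL,
                       polyA_table = NULL, de_table = NULL,
                       out_dir = "readthrough_out", alpha = 0.05,
                       min_length = 200L, clearance = 400L, min_probes = 8L,
                       max_cbc1 = 10L, expr_floor = -4.88, frac = 0.7,
                       fraction_scale = "linear_on_log2", flank_len = 500L,
                       group_high = 200L, group_low = 1200L,
                       motif_from = -80L, motif_to = -20L, k = 6L,
                       bottom_exclude = 250L, horizon = 5000L, seed = 1L) {
  cfg <- as.list(environment())
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  .assert(min_probes >= 1 && min_length > 0 && clearance >= 0,
          "thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (JSON)
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `path` / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Run the full pipeline
#'
#' Stages (each skipped when its inputs are absent): genome-wide readthrough
#' analysis -> `readthrough.tsv`; CRAC profiles (class tally, oligo(A)
#' fraction, Pol II 3'-end group profiles) -> `profiles/`; motif enrichment
#' -> `motifs.tsv` + `motif_coverage.tsv`; environment classification ->
#' `environment.tsv`. A `manifest.json` records the config, package version
#' and input checksums; identical configs and inputs reproduce identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly.
#' @export
run_all <- function(config) {
  cfg <- config
  paths <- cfg[c("annotation", "probes", "cbc1", "reads_wt", "reads_mut",
                 "genome", "polyA_table", "de_table")]
  paths <- paths[!vapply(paths, is.null, logical(1))]
  for (nm in names(paths))
    .assert(file.exists(paths[[nm]]), "input '%s' not found: %s", nm,
            paths[[nm]])
  .assert(!is.null(cfg$annotation) && !is.null(cfg$probes),
          "annotation and probes are required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  tx <- read_annotation(cfg$annotation)
  probes <- read_probe_table(cfg$probes)
  cbc1 <- if (!is.null(cfg$cbc1)) read_reads(cfg$cbc1) else NULL

  res <- readthrough_analysis(tx, probes, cbc1 = cbc1, alpha = cfg$alpha,
                              min_length = cfg$min_length,
                              clearance = cfg$clearance,
                              min_probes = cfg$min_probes,
                              max_cbc1 = cfg$max_cbc1,
                              expr_floor = cfg$expr_floor, frac = cfg$frac,
                              fraction_scale = cfg$fraction_scale,
                              cbc1_missing = if (is.null(cbc1)) "pass" else
                                "fail")
  data.table::fwrite(res, file.path(cfg$out_dir, "readthrough.tsv"),
                     sep = "\t")
  message(sprintf("readthrough: %d transcripts, %d eligible, %d pass filters",
                  nrow(res), sum(res$eligible),
                  sum(res$pass_filters, na.rm = TRUE)))

  if (!is.null(cfg$reads_wt) && !is.null(cfg$reads_mut)) {
    pdir <- file.path(cfg$out_dir, "profiles")
    dir.create(pdir, showWarnings = FALSE)
    rd_wt <- read_reads(cfg$reads_wt)
    rd_mut <- read_reads(cfg$reads_mut)
    data.table::fwrite(class_tally(rd_wt, tx),
                       file.path(pdir, "class_tally_wt.tsv"), sep = "\t")
    data.table::fwrite(class_tally(rd_mut, tx),
                       file.path(pdir, "class_tally_mut.tsv"), sep = "\t")
    ranked <- res[!is.na(rank)][order(rank)]
    if (nrow(ranked) >= cfg$group_high + cfg$group_low) {
      hi <- ranked$id[seq_len(cfg$group_high)]
      lo <- tail(ranked$id, cfg$group_low)
      for (grp in list(list("high", hi), list("low", lo))) {
        for (strain in list(list("wt", rd_wt), list("mut", rd_mut))) {
          prof <- polii_3prime_group_profile(strain[[2]], tx, grp[[2]])
          data.table::fwrite(
            data.table::data.table(offset = prof$offsets,
                                   value = prof$values),
            file.path(pdir, sprintf("polii_3prime_%s_%s.tsv", grp[[1]],
                                    strain[[1]])), sep = "\t")
        }
      }
    }
  }

  if (!is.null(cfg$genome) && !is.null(cfg$polyA_table)) {
    genome <- read_genome(cfg$genome)
    pa <- data.table::fread(cfg$polyA_table, sep = "\t", header = TRUE)
    gs <- build_motif_gene_set(res, pa$id, cfg$bottom_exclude)
    txp <- tx[gs$id]
    seqs <- vapply(seq_along(txp), function(i)
      extract_3prime_region(txp[i], genome, cfg$motif_from, cfg$motif_to),
      character(1))
    low <- seqs[gs$quartile == 4L]
    high <- seqs[gs$quartile == 1L]
    mot <- motif_enrichment(low, high, k = cfg$k)
    data.table::fwrite(mot, file.path(cfg$out_dir, "motifs.tsv"), sep = "\t")
    top <- mot$motif[1L]
    covr <- rbind(
      cbind(group = "low",
            motif_positional_coverage(tx[gs$id[gs$quartile == 4L]], genome,
                                      top)),
      cbind(group = "high",
            motif_positional_coverage(tx[gs$id[gs$quartile == 1L]], genome,
                                      top)))
    data.table::fwrite(covr, file.path(cfg$out_dir, "motif_coverage.tsv"),
                       sep = "\t")
  }

  if (!is.null(cfg$de_table)) {
    de <- data.table::fread(cfg$de_table, sep = "\t", header = TRUE)
    calls <- data.table::data.table(
      id = res$id, readthrough = !is.na(res$significant_both) &
        res$significant_both)
    genes <- tx[tx$id %in% de$id]
    env <- annotate_environments(genes, tx, calls, de, cfg$horizon)
    data.table::fwrite(env, file.path(cfg$out_dir, "environment.tsv"),
                       sep = "\t")
  }

  manifest <- list(
    package = "readthroughr",
    version = as.character(utils::packageVersion("readthroughr")),
    config = unclass(cfg),
    input_md5 = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `readthrough`,
#' `run-all`. Example:
#' `Rscript -e 'readthroughr::rt_main()' readthrough --annotation a.gff3
#' --probes p.tsv --out out/`.
#'
#' @param args Command-line arguments (default `commandArgs(TRUE)`).
#' @return Exit status 0 on success (invisibly).
#' @export
rt_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  .assert(length(args) >= 1L,
          "usage: <simulate|readthrough|run-all> [options]")
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1L && i < length(rest)) rest[i + 1L] else default
  }
  switch(cmd,
    simulate = {
      cfg <- sim_config(n_genes = as.integer(opt("--n-genes", "500")),
                        seed = as.integer(opt("--seed", "1")))
      write_sim_dataset(cfg, opt("--out", "simdata"))
    },
    readthrough = {
      cfg <- run_config(annotation = opt("--annotation"),
                        probes = opt("--probes"), cbc1 = opt("--cbc1"),
                        alpha = as.numeric(opt("--alpha", "0.05")),
                        out_dir = opt("--out", "readthrough_out"))
      run_all(cfg)
    },
    `run-all` = {
      cfg <- read_run_config(opt("--config"))
      run_all(cfg)
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE))
  invisible(0L)
}
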