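test_that("read class assignment honors priority, antisense and intergenic", {
  tx <- make_tx(c(1000, 4000, "+", "mRNA", "m1"),
                c(2000, 2200, "+", "snoRNA", "s1"),   # nested in m1
                c(6000, 6500, "+", "CUT", "c1"),
                c(8000, 8400, "-", "mRNA", "m2"))
  rs <- make_reads(start = c(2050, 1500, 8100, 8100, 9500, 3990),
                   end = c(2080, 1530, 8130, 8130, 9530, 4020),
                   strand = c("+", "+", "-", "+", "+", "+"))
  got <- assign_read_class(rs, tx)
  expect_equal(got, c("snoRNA",     # nested snoRNA beats host mRNA
                      "mRNA",
                      "mRNA",       # sense on the minus-strand gene
                      "antisense",  # plus read over minus-strand mRNA
                      "intergenic",
                      "intergenic")) # only 10/30 nt inside m1: < 50%

  # tallies match a brute-force per-read loop on a random fixture
  set.seed(61)
  starts <- sample.int(9000, 200)
  rs2 <- make_reads(starts, starts + 30,
                    strand = sample(c("+", "-"), 200, TRUE))
  got2 <- assign_read_class(rs2, tx)
  prio <- readthroughr:::CLASS_PRIORITY
  oracle <- vapply(seq_len(200), function(i) {
    r <- rs2$reads[i]
    ov <- function(g) {
      max(0, min(GenomicRanges::end(r), GenomicRanges::end(g)) -
            max(GenomicRanges::start(r), GenomicRanges::start(g)) + 1)
    }
    best <- "intergenic"
    anti <- FALSE
    for (j in seq_along(tx)) {
      if (ov(tx[j]) < 15) next
      same <- as.character(GenomicRanges::strand(tx[j])) ==
        as.character(GenomicRanges::strand(r))
      cl <- as.character(tx$rna_class[j])
      if (same) {
        if (best == "intergenic" || match(cl, prio) < match(best, prio))
          best <- cl
      } else anti <- TRUE
    }
    if (best == "intergenic" && anti) "antisense" else best
  }, character(1))
  expect_equal(got2, oracle)
  ct <- class_tally(rs2, tx)
  expect_equal(sum(ct$fraction), 1)
})

test_that("oligo(A) detection applies the A2+, non-templated rule", {
  genome <- make_genome(strrep("CT", 500)) # no A anywhere
  rs <- make_reads(start = c(100, 200, 300), end = c(130, 230, 330),
                   tail3 = c("AA", "A", NA))
  expect_equal(detect_oligoA(rs, genome), c(TRUE, FALSE, FALSE))

  # templated tail: genome continues with AA right after the read
  g2 <- make_genome(paste0(strrep("C", 130), "AA", strrep("C", 300)))
  rs2 <- make_reads(start = 100, end = 130, tail3 = "AA")
  expect_false(detect_oligoA(rs2, g2))
  # one mismatch within the would-be template is enough
  g3 <- make_genome(paste0(strrep("C", 130), "AG", strrep("C", 300)))
  expect_true(detect_oligoA(rs2, g3))

  # minus-strand read: template is upstream on the reference, revcomp'd
  g4 <- make_genome(paste0(strrep("C", 98), "TT", strrep("C", 300)))
  rs4 <- make_reads(start = 100, end = 130, strand = "-", tail3 = "AA")
  expect_false(detect_oligoA(rs4, g4)) # TT revcomp = AA: templated
  g5 <- make_genome(strrep("C", 400))
  expect_true(detect_oligoA(rs4, g5))

  # tail running off the contig counts as non-templated
  g6 <- make_genome(strrep("A", 131))
  expect_true(detect_oligoA(rs2, g6))

  # non-A tails never flag
  rs7 <- make_reads(start = 100, end = 130, tail3 = "AG")
  expect_false(detect_oligoA(rs7, genome))
})

test_that("oligo(A) fraction aggregates and decomposes by class", {
  genome <- make_genome(strrep("CT", 2000))
  tx <- make_tx(c(0, 2000, "+", "mRNA", "m"),
                c(2500, 3000, "+", "snoRNA", "s"), chrom_length = 4000)
  rs <- make_reads(start = c(10, 50, 2600, 2700), end = c(40, 80, 2630, 2730),
                   tail3 = c("AA", NA, "AAA", NA))
  got <- oligoA_fraction(rs, genome, tx)
  expect_equal(got$fraction, 0.5)
  by <- got$by_class
  # overall fraction is the read-count weighted mean of per-class fractions
  expect_equal(sum(by$fraction * by$n) / sum(by$n), got$fraction)

  empty <- make_reads(integer(0), integer(0))
  expect_message(g0 <- oligoA_fraction(empty, genome), "undefined")
  expect_true(is.na(g0$fraction))

  noTails <- make_reads(10, 40)
  expect_equal(oligoA_fraction(noTails, genome)$fraction, 0)
})

test_that("metagene endpoint profiles anchor and normalize correctly", {
  tx <- make_tx(c(1000, 2000, "+", "mRNA", "g1"))
  # one read covering TSS +/- 2 (0-based 998..1002)
  rs <- make_reads(998, 1003)
  prof <- metagene_endpoint_profile(rs, tx, "TSS", flank_out = 10,
                                    flank_in = 10, min_len = 100,
                                    normalization = "none")
  nz <- prof$offsets[prof$values > 0]
  expect_equal(nz, -2:2)

  s1 <- metagene_endpoint_profile(rs, tx, "TSS", 10, 10, 100, "sum_to_one")
  expect_equal(sum(s1$values), 1)

  pm <- metagene_endpoint_profile(rs, tx, "TSS", 10, 10, 100, "per_million",
                                  top_n = NULL)
  expect_equal(max(pm$values), 1e6 / rs$total_mapped)

  # minus-strand 3' anchor: offsets increase downstream (leftward)
  txm <- make_tx(c(1000, 2000, "-", "mRNA", "gm"))
  rsm <- make_reads(995, 1000, strand = "-") # bases 995..999, all downstream
  pm3 <- metagene_endpoint_profile(rsm, txm, "end3", flank_out = 10,
                                   flank_in = 5, min_len = 100,
                                   normalization = "none")
  expect_equal(pm3$offsets[pm3$values > 0], 1:5)

  expect_error(metagene_endpoint_profile(rs, tx[0], "TSS"), "empty")
})

test_that("metagene interior is flat under uniform coverage", {
  set.seed(71)
  tx <- make_tx(c(5000, 9000, "+", "mRNA", "u"))
  n <- 20000
  starts <- sample(3000:10800, n, replace = TRUE)
  rs <- make_reads(starts, starts + 30)
  prof <- metagene_endpoint_profile(rs, tx, "TSS", flank_out = 0,
                                    flank_in = 1000, min_len = 100,
                                    normalization = "none")
  lambda <- mean(prof$values)
  # per-position Poisson band; 4.5 sigma keeps the family-wise false-alarm
  # rate over 1000 positions well below 1%
  expect_true(all(abs(prof$values - lambda) < 4.5 * sqrt(lambda)))
})

test_that("length-normalized binning conserves mass", {
  tx <- make_tx(c(1000, 1999, "+", "mRNA", "g")) # 999 nt: not divisible by 10
  rs <- make_reads(c(1000, 1000), c(1999, 1500)) # full + first-half reads
  prof <- length_normalized_profile(rs, tx, n_bins = 10)
  # full-length read alone gives equal bins; second read loads the 5' half
  expect_equal(sum(prof), 999 + 500)
  expect_true(all(prof[1:5] > prof[6:10]))

  full <- length_normalized_profile(make_reads(1000, 1999, "+"), tx, 9)
  expect_equal(full, rep(111, 9))

  half <- length_normalized_profile(make_reads(1000, 1500, "+"), tx, 10)
  expect_equal(sum(half > 1e-9), 6) # 500 nt ends just inside bin 6
  expect_equal(sum(half), 500)
})

test_that("pileup matches a naive counting oracle", {
  rs <- make_reads(c(100, 110), c(130, 140), total_mapped = 1e6)
  v <- pileup(rs, "chr1", 90, 150, "+")
  expect_equal(unname(v[as.character(112)]), 2)
  expect_equal(unname(v[as.character(95)]), 0)
  expect_equal(unname(v[as.character(135)]), 1)

  expect_error(pileup(rs, "chr1", 0, 10, "+", total_mapped = 0), "0")
  expect_equal(unname(pileup(rs, "chr1", 5000, 5010, "+")), rep(0, 10))

  set.seed(83)
  starts <- sample.int(900, 120)
  rs2 <- make_reads(starts, starts + sample(10:40, 120, TRUE),
                    strand = sample(c("+", "-"), 120, TRUE),
                    total_mapped = 120)
  got <- pileup(rs2, "chr1", 0, 1000, "-")
  gr <- rs2$reads[GenomicRanges::strand(rs2$reads) == "-"]
  oracle <- vapply(0:999, function(p) {
    sum(readthroughr:::.gr_start0(gr) <= p & readthroughr:::.gr_end0(gr) > p)
  }, numeric(1)) * 1e6 / 120
  expect_equal(unname(got), oracle)
})

test_that("max-normalized group profiles are bounded and linear", {
  tx <- make_tx(c(1000, 2000, "+", "mRNA", "a"),
                c(5000, 6000, "+", "mRNA", "b"),
                c(8000, 9000, "+", "mRNA", "c"))
  # reads piled at each gene's 3' end
  rs <- make_reads(c(1990, 1990, 5990, 8995), c(2020, 2005, 6020, 9020))
  single <- polii_3prime_group_profile(rs, tx, "a", 50, 50)
  expect_equal(max(single$values), 1)

  pair <- polii_3prime_group_profile(rs, tx, c("a", "a"), 50, 50)
  expect_equal(pair$values, 2 * single$values)

  grp <- polii_3prime_group_profile(rs, tx, c("a", "b", "c"), 50, 50)
  expect_true(all(grp$values <= grp$gene_set_size + 1e-12))

  # gene without hits is dropped with a warning; empty group errors
  txd <- make_tx(c(1000, 2000, "+", "mRNA", "a"),
                 c(50000, 51000, "+", "mRNA", "nohit"))
  expect_warning(p2 <- polii_3prime_group_profile(rs, txd, c("a", "nohit"),
                                                  50, 50), "dropped")
  expect_equal(p2$gene_set_size, 1L)
  expect_error(polii_3prime_group_profile(rs, tx, character(0)), "empty")
})

test_that("snoRNA flank ratios compare strains", {
  sno <- make_tx(c(1000, 1200, "+", "snoRNA", "s"))[1]
  mk <- function(body, flank) {
    make_reads(c(rep(1050, body), rep(1300, flank)),
               c(rep(1080, body), rep(1330, flank)))
  }
  same <- snoRNA_flank_ratio(mk(100, 10), mk(100, 10), sno)
  expect_equal(same$fold, 1.0)
  dbl <- snoRNA_flank_ratio(mk(100, 10), mk(100, 20), sno)
  expect_equal(dbl$fold, 2.0)
  # symmetry under strain swap
  expect_equal(snoRNA_flank_ratio(mk(100, 20), mk(100, 10), sno)$fold,
               1 / dbl$fold)
  expect_message(und <- snoRNA_flank_ratio(mk(0, 10), mk(100, 10), sno),
                 "undefined")
  expect_true(is.na(und$fold))
})

test_that("snoRNA readthrough tallies exclude intronic transcripts", {
  tx <- make_tx(c(1000, 1200, "+", "snoRNA", "s1", "monocistronic"),
                c(2000, 2200, "+", "snoRNA", "s2", "monocistronic"),
                c(3000, 3200, "+", "snoRNA", "s3", "monocistronic"),
                c(4000, 4200, "+", "snoRNA", "s4", "polycistronic"),
                c(5000, 5200, "+", "snoRNA", "s5", "intronic"),
                c(6000, 7000, "+", "mRNA", "m1"))
  calls <- data.frame(id = c("s1", "s2", "s3", "s4", "s5", "m1"),
                      readthrough = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  tal <- tally_snoRNA_readthrough(calls, tx)
  expect_equal(tal[tal$sno_class == "monocistronic"]$n_rt, 2L)
  expect_equal(tal[tal$sno_class == "monocistronic"]$n_total, 3L)
  expect_equal(tal[tal$sno_class == "all"]$n_total, 4L) # intronic excluded
  expect_equal(tal[tal$sno_class == "all"]$n_rt, 3L)

  # brute-force oracle over random flag draws
  set.seed(5)
  for (i in 1:10) {
    calls$readthrough <- sample(c(TRUE, FALSE), 6, TRUE)
    tal <- tally_snoRNA_readthrough(calls, tx)
    keep <- tx$sno_class %in% c("monocistronic", "polycistronic")
    want <- sum(calls$readthrough[match(tx$id[keep], calls$id)])
    expect_equal(tal[tal$sno_class == "all"]$n_rt, want)
  }
})

test_that("profile smoothing preserves vector length and flat signals", {
  x <- c(rep(1, 10), 5, rep(1, 10))
  s <- smooth_profile(x, k = 5)
  expect_length(s, length(x))
  expect_lt(max(s), 5)
  expect_equal(smooth_profile(rep(2, 8), k = 3), rep(2, 8))
})
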