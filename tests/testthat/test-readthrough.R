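test_that("windows obey the strand-aware definition", {
  plus <- make_tx(c(1000, 2000, "+"))
  w <- define_windows(plus)
  expect_equal(unlist(w$dn100[c("start", "end")]), c(start = 2000, end = 2100))
  expect_equal(unlist(w$dn200[c("start", "end")]), c(start = 2100, end = 2300))
  expect_equal(unlist(w$tran[c("start", "end")]), c(start = 1050, end = 1950))

  minus <- make_tx(c(1000, 2000, "-"))
  w <- define_windows(minus)
  expect_equal(unlist(w$dn100[c("start", "end")]), c(start = 900, end = 1000))
  expect_equal(unlist(w$dn200[c("start", "end")]), c(start = 700, end = 900))
  expect_equal(unlist(w$tran[c("start", "end")]), c(start = 1050, end = 1950))

  expect_error(define_windows(make_tx(c(0, 90, "+"))), "100")
})

test_that("inclusion filter applies length, spacing and probe rules", {
  tx <- make_tx(c(1000, 1150, "+", "mRNA", "short"),    # 150 nt
                c(3000, 4000, "+", "mRNA", "crowded"),
                c(4050, 5000, "+", "mRNA", "neighbor"), # 50 nt downstream
                c(8000, 9000, "+", "mRNA", "cutup"),
                c(9050, 9400, "+", "CUT", "thecut"),    # CUT 50 nt down
                c(20000, 21000, "+", "mRNA", "clear"),
                c(30000, 31000, "-", "mRNA", "minus_ok"),
                c(25000, 26000, "-", "mRNA", "minus_crowded"),
                c(24000, 24800, "-", "mRNA", "mc_neighbor"))
  probes <- probe_track_of(make_probes(0, 40000, "+", step = 8),
                           make_probes(0, 40000, "-", step = 8))
  res <- inclusion_filter(tx, probes)
  flag <- function(id, col) res[[col]][res$id == id]
  expect_false(flag("short", "incl_length"))
  expect_false(flag("crowded", "incl_spacing"))   # mRNA 50 nt downstream
  expect_true(flag("cutup", "incl_spacing"))      # CUT exception
  expect_true(flag("clear", "eligible"))
  expect_true(flag("minus_ok", "eligible"))
  expect_false(flag("minus_crowded", "incl_spacing")) # 200 nt to mc_neighbor
  # the CUT itself is also scored for eligibility (class included), but the
  # spacing exception does not apply to it
  expect_true(flag("thecut", "incl_length"))
})

test_that("too few probes in a downstream window fails incl_probes", {
  tx <- make_tx(c(1000, 2000, "+", "mRNA", "g"))
  # probes only inside the transcript: DN100/DN200 empty
  probes <- as_probe_track(make_probes(1000, 2000, "+", step = 8))
  res <- inclusion_filter(tx, probes)
  expect_false(res$incl_probes)
  expect_false(res$eligible)
  expect_gte(res$n_tran, 8)
  expect_equal(res$n_dn100, 0)
})

test_that("readthrough score is the DN200 - TRAN median difference", {
  tx <- make_tx(c(1000, 2000, "+"))
  w <- define_windows(tx)
  # constant track: score 0
  flat <- as_probe_track(make_probes(900, 2400, "+", step = 8, wt_1 = 1.7))
  expect_equal(readthrough_score(w, flat, "wt_1"), 0)

  # hand-computed medians: DN200 {-3,-2,-4}, TRAN {1,2,3,0,1,2,1,3}
  dn200 <- make_probes(2100, 2300, "+", step = 67)[1:3][
    , `:=`(wt_1 = c(-3, -2, -4))]
  tran <- make_probes(1050, 1950, "+", step = 112)[1:8][
    , `:=`(wt_1 = c(1, 2, 3, 0, 1, 2, 1, 3))]
  dn100 <- make_probes(2000, 2100, "+", step = 12)
  track <- probe_track_of(dn100, dn200, tran)
  expect_equal(readthrough_score(w, track, "wt_1", min_probes = 3),
               -3 - 1.5) # even-n median = mean of central pair
  expect_error(readthrough_score(w, track, "wt_1", min_probes = 8),
               "invalid window")

  # translation invariance
  shifted <- data.table::as.data.table(track)
  shifted[, wt_1 := wt_1 + 2.0]
  expect_equal(readthrough_score(w, as_probe_track(shifted), "wt_1",
                                 min_probes = 3),
               readthrough_score(w, track, "wt_1", min_probes = 3))
})

test_that("ratio arithmetic and antisymmetry", {
  expect_equal(readthrough_ratio(-1.0, -1.0), 0)
  expect_equal(readthrough_ratio(-1.0, -4.5), 3.5)
  set.seed(13)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(readthrough_ratio(a, b), -readthrough_ratio(b, a))
})

test_that("empirical null: identical tracks give exactly zero, n matches", {
  scores <- data.frame(wt_1 = c(0.3, -1, 2), wt_2 = c(0.3, -1, 2))
  expect_equal(empirical_null(scores), c(0, 0, 0))
  scores2 <- data.frame(wt_1 = rnorm(40), wt_2 = rnorm(40))
  expect_length(empirical_null(scores2), 40)
  expect_error(empirical_null(scores2[0, ]), "empty")
})

test_that("empirical p-values match the counting definition", {
  null <- c(-1, 0, 1)
  expect_equal(empirical_pvalue(2, null), 0.25)
  expect_equal(empirical_pvalue(-5, null), 1.0)
  expect_equal(empirical_pvalue(1, null), 0.5) # tie counts against
  expect_error(empirical_pvalue(Inf, null), "finite")

  # counting oracle on random data
  set.seed(5)
  null <- rnorm(200)
  ratios <- rnorm(50)
  oracle <- sapply(ratios, function(r) (1 + sum(null >= r)) / 201)
  expect_equal(empirical_pvalue(ratios, null), oracle)
  expect_true(all(empirical_pvalue(ratios, null) > 0))
})

test_that("BH step-up matches the reference implementation", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.04, 0.9), 0.05),
               c(TRUE, TRUE, FALSE, FALSE)) # 0.04 > 3 * 0.05 / 4
  expect_equal(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bh_fdr(numeric(0)), logical(0))

  set.seed(17)
  for (i in 1:200) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(1:3, 1)
    p[p == 0] <- 1e-12
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(bh_fdr(p, alpha), p.adjust(p, "BH") <= alpha)
  }
})

test_that("expression filters implement thresholds (i)-(iv)", {
  base <- data.frame(dn100_wt_1 = 0, dn100_wt_2 = 0,
                     dn100_mut_1 = 0.8, dn100_mut_2 = 0.8,
                     dn200_wt_1 = 0, dn200_wt_2 = 0,
                     dn200_mut_1 = 0, dn200_mut_2 = 0,
                     tran_wt_1 = 1, tran_wt_2 = 1,
                     tran_mut_1 = 1, tran_mut_2 = 1)
  # (iii): 0.8 > 0.7 * 1.0 under the linear-on-log2 reading
  f <- expression_filters(base, cbc1_dn100 = 0L)
  expect_true(f$f_dn100_frac)
  expect_true(f$pass)

  # (i): 12 Cbc1 reads in DN100 fails the < 10 rule
  expect_false(expression_filters(base, cbc1_dn100 = 12L)$f_cbc1)
  expect_true(expression_filters(base, cbc1_dn100 = 9L)$f_cbc1)

  # (ii): mean WT TRAN median of -5.0 fails the > -4.88 floor
  low <- transform(base, tran_wt_1 = -5, tran_wt_2 = -5)
  expect_false(expression_filters(low, cbc1_dn100 = 0L)$f_expr_floor)

  # (iv): mutant TRAN below 70% of WT TRAN
  drop <- transform(base, tran_mut_1 = 0.6, tran_mut_2 = 0.6)
  expect_false(expression_filters(drop, cbc1_dn100 = 0L)$f_tran_frac)

  # missing Cbc1 data fails closed by default, passes when configured
  expect_false(expression_filters(base)$f_cbc1)
  expect_true(expression_filters(base, cbc1_missing = "pass")$f_cbc1)

  # intensity-scale variant: (iii) becomes dn100 > tran + log2(0.7)
  fi <- expression_filters(base, cbc1_dn100 = 0L,
                           fraction_scale = "linear_on_intensity")
  expect_true(fi$f_dn100_frac) # 0.8 > 1 - 0.515
})

test_that("ranking: ties average, permutation invariant", {
  expect_equal(rank_genes(c(3, 1, 2)), c(1, 3, 2))
  expect_equal(rank_genes(c(2, 2, 1)), c(1.5, 1.5, 3))
  set.seed(23)
  x <- rnorm(100)
  perm <- sample.int(100)
  expect_equal(rank_genes(x)[perm], rank_genes(x[perm]))
})

test_that("length correlation equals rank-then-Pearson and is null-calibrated", {
  r <- length_correlation(1:10, (1:10)^2)
  expect_equal(r$rho, 1)

  set.seed(31)
  ratio <- rnorm(300); len <- rlnorm(300)
  got <- length_correlation(ratio, len)
  oracle <- cor(rank(ratio), rank(len))
  expect_equal(got$rho, oracle, tolerance = 1e-12)

  expect_error(length_correlation(rep(1, 5), 1:5), "constant")

  # independent vectors: small |rho| in most seeds
  hits <- sum(sapply(1:20, function(s) {
    set.seed(s)
    abs(length_correlation(rnorm(1000), rnorm(1000))$rho) < 0.1
  }))
  expect_gte(hits, 19)
})

test_that("full analysis wires scores, null, calls and filters together", {
  # two genes with flat probes; one gets an injected mutant DN200 shift
  tx <- make_tx(c(1000, 2000, "+", "mRNA", "rt"),
                c(10000, 11000, "+", "mRNA", "flat"))
  pr <- make_probes(0, 15000, "+", step = 8, wt_1 = 0, wt_2 = 0,
                    mut_1 = 0, mut_2 = 0)
  pr[position >= 2100 & position < 2300, `:=`(mut_1 = 3, mut_2 = 3)]
  res <- readthrough_analysis(tx, as_probe_track(pr),
                              cbc1_missing = "pass")
  expect_true(all(res$eligible))
  expect_equal(res[res$id == "rt"]$ratio_1, 3)
  expect_equal(res[res$id == "flat"]$ratio_1, 0)
  expect_equal(res[res$id == "rt"]$null_ratio, 0)
  # two-gene null cannot reach significance: calls stay FALSE
  expect_false(any(res$significant_both))
})
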