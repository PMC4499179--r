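test_that("default window is 70 bp from the first CpG site, clipped to the region", {
  set.seed(41)
  seq200 <- paste0(strrep("AT", 5), "CG", rand_dna(50), "CG", strrep("TA", 69))
  reg <- make_region(seq200)  # first CpG at offset 10, length 200
  w <- select_window(reg)
  expect_equal(w$start, 10L)
  expect_equal(w$end, 80L)
  expect_true(all(w$sites >= 10 & w$sites + 1 < 80))

  # short region: end clips at the region length
  reg2 <- make_region(paste0(strrep("AT", 5), "CG", strrep("TA", 10)))
  w2 <- select_window(reg2)
  expect_equal(w2$end, reg2$length)
})

test_that("user windows are honoured and degenerate windows rejected", {
  reg <- make_region("TTCGTTACGTTT")
  w <- select_window(reg, window = c(0, 5))
  expect_equal(w$start, 0L)
  expect_equal(w$end, 5L)
  expect_equal(w$sites, 2L)  # CpG at 7 falls outside
  expect_error(select_window(make_region("ATATAT")), "no CpG")
  expect_error(select_window(reg, window = c(0, 2)), "no complete CpG")
  expect_error(select_window(reg, window = c(5, 5)), "empty window")
})

test_that("only reads covering all window sites with definite calls enter patterns", {
  reg <- make_region("TTCGTTTTCGTTTTCGTT")  # CpGs at 2, 8, 14
  w <- select_window(reg, window = c(0, 18))
  calls <- tibble::tibble(
    read_id = c("full", "partial", "ambig"),
    region_name = "r1", offset = 0L, strand_mode = "OT",
    read_seq = reg$sequence,
    status = c("MUM", "MU.", "MAU"),
    conversion_rate = 1, identity = 1
  )
  kept <- reads_covering_window(calls, w)
  expect_equal(kept$read_id, "full")
  expect_equal(kept$signature, "MUM")
})

test_that("patterns group by signature with correct supports, fractions and p0", {
  ps <- pattern_set_from_signatures(c("MM", "MM", "UU", "MU"))
  expect_equal(ps$n, 4L)
  expect_equal(ps$p0, 1 / 3)
  pat <- ps$patterns[order(ps$patterns$signature), ]
  expect_equal(pat$signature, c("MM", "MU", "UU"))
  expect_equal(pat$support, c(2L, 1L, 1L))
  expect_equal(pat$fraction, c(0.5, 0.25, 0.25))
  expect_equal(sum(ps$patterns$support), ps$n)
  expect_equal(ps$p0 * nrow(ps$patterns), 1)

  # unanimity: single conceivable pattern is not significant against itself
  ps1 <- pattern_set_from_signatures(rep("MMM", 50))
  expect_equal(nrow(ps1$patterns), 1L)
  expect_equal(ps1$patterns$fraction, 1)
  expect_equal(ps1$p0, 1)
  expect_equal(ps1$patterns$p_value, 1)

  ps0 <- pattern_set_from_signatures(character(0))
  expect_equal(ps0$n, 0L)
  expect_equal(nrow(ps0$patterns), 0L)
})

test_that("the Z statistic matches direct evaluation and handles degeneracies", {
  # p_hat = 0.5, p0 = 0.25, n = 100: sqrt(0.5*0.5/100) = 0.05 -> z = 5
  r <- pattern_zscore(0.5, 0.25, 100)
  expect_equal(r$z, 5)
  expect_equal(r$p_value, pnorm(5, lower.tail = FALSE))
  # p_hat = p0 (< 1): z = 0, p = 0.5
  r <- pattern_zscore(0.3, 0.3, 17)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 0.5)
  # unanimity with alternatives possible: maximally significant
  r <- pattern_zscore(1, 0.5, 10)
  expect_equal(r$z, Inf)
  expect_equal(r$p_value, 0)
  # unanimity with p0 = 1: non-significant
  r <- pattern_zscore(1, 1, 10)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  expect_error(pattern_zscore(0.5, 0.5, 0), "n")
  expect_error(pattern_zscore(0, 0.5, 10), "p_hat")
})

test_that("z is monotone in p_hat and in n", {
  p <- seq(0.05, 0.95, by = 0.05)
  z <- pattern_zscore(p, 0.2, 50)$z
  expect_true(all(diff(z) > 0))
  ns <- c(5, 10, 50, 100, 1000)
  z2 <- pattern_zscore(0.4, 0.2, ns)$z
  expect_true(all(diff(z2) > 0))
})

test_that("significant patterns are ordered by z, support, then signature", {
  ps <- pattern_set_from_signatures(c(rep("MM", 60), rep("UU", 30), rep("MU", 10)))
  sig <- significant_patterns(ps, alpha = 0.05)
  expect_true(all(diff(sig$z) <= 0))
  expect_true(all(sig$p_value < 0.05))

  # equal z from equal (fraction, n): tie broken by signature (M before U)
  ps2 <- pattern_set_from_signatures(c(rep("MM", 40), rep("UU", 40), rep("MU", 20)))
  sig2 <- significant_patterns(ps2, alpha = 0.5)
  expect_equal(sig2$signature[1:2], c("MM", "UU"))

  # fraction threshold removes low-fraction patterns regardless of p-value:
  # 12 observed patterns (p0 = 1/12), "UUUU" at 190/2000 = 0.095 is
  # significant but sits below a 0.1 fraction floor
  fillers <- c("MUUU", "UMUU", "UUMU", "UUUM", "MMUU",
               "MUMU", "MUUM", "UMMU", "UMUM", "UUMM")
  ps3 <- pattern_set_from_signatures(
    c(rep("MMMM", 1000), rep("UUUU", 190), rep(fillers, each = 81)))
  expect_true("UUUU" %in% significant_patterns(ps3, alpha = 0.05)$signature)
  with_floor <- significant_patterns(ps3, alpha = 0.05, min_fraction = 0.1)
  expect_false("UUUU" %in% with_floor$signature)
  expect_true("MMMM" %in% with_floor$signature)

  # Bonferroni divides alpha by the number of observed patterns
  expect_lte(nrow(significant_patterns(ps3, alpha = 0.05, bonferroni = TRUE)),
             nrow(significant_patterns(ps3, alpha = 0.05)))
})

test_that("pattern grouping matches a brute-force signature tally on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(1:5, 1)
    n <- sample(1:500, 1)
    sigs <- apply(matrix(sample(c("M", "U"), n * k, replace = TRUE), n), 1,
                  paste, collapse = "")
    ps <- pattern_set_from_signatures(sigs)
    want <- brute_tally(sigs)
    got <- ps$patterns[order(ps$patterns$signature), ]
    expect_equal(got$signature, want$signature[order(want$signature)])
    expect_equal(got$support, want$support[order(want$signature)])
    expect_equal(ps$p0, 1 / nrow(want))
    expect_equal(sum(got$fraction), 1)
  }
})

test_that("pairwise CpG dependence reproduces hand-computed Pearson chi-square", {
  # perfect association: MM = UU = 50 -> chi2 = n = 100
  ps <- pattern_set_from_signatures(c(rep("MM", 50), rep("UU", 50)))
  d <- cpg_pair_dependency(ps, 1, 2)
  expect_equal(d$chi2, 100)
  expect_lt(d$p_value, 1e-20)
  expect_equal(as.vector(d$table), c(50, 0, 0, 50))

  # perfect balance: chi2 = 0, p = 1
  ps2 <- pattern_set_from_signatures(c(rep("MM", 25), rep("MU", 25),
                                       rep("UM", 25), rep("UU", 25)))
  d2 <- cpg_pair_dependency(ps2, 1, 2)
  expect_equal(d2$chi2, 0)
  expect_equal(d2$p_value, 1)

  # zero margin (site 1 always methylated): defined as no dependence
  ps3 <- pattern_set_from_signatures(c(rep("MM", 70), rep("MU", 30)))
  d3 <- cpg_pair_dependency(ps3, 1, 2)
  expect_equal(d3$chi2, 0)
  expect_equal(d3$p_value, 1)

  expect_error(cpg_pair_dependency(ps, 1, 3), "site")
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(43)
  for (i in 1:20) {
    counts <- sample(1:80, 4, replace = TRUE)
    sigs <- c(rep("MM", counts[1]), rep("MU", counts[2]),
              rep("UM", counts[3]), rep("UU", counts[4]))
    ps <- pattern_set_from_signatures(sigs)
    d <- cpg_pair_dependency(ps, 1, 2)
    ref <- suppressWarnings(stats::chisq.test(d$table, correct = FALSE))
    expect_equal(d$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(d$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the all-pairs dependence screen covers k choose 2 pairs", {
  set.seed(44)
  sigs <- apply(matrix(sample(c("M", "U"), 300 * 4, replace = TRUE), 300), 1,
                paste, collapse = "")
  ps <- pattern_set_from_signatures(sigs)
  dep <- cpg_dependency_all(ps)
  expect_equal(nrow(dep), choose(4, 2))
  expect_true(all(dep$chi2 >= 0))
  expect_true(all(dep$p_value >= 0 & dep$p_value <= 1))
})

test_that("tidy and glance summarise a pattern set", {
  ps <- pattern_set_from_signatures(c(rep("MM", 60), rep("UU", 30), rep("MU", 10)))
  td <- tidy(ps)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$support), 100L)
  expect_true(all(diff(td$z) <= 0))
  g <- glance(ps)
  expect_equal(g$n, 100L)
  expect_equal(g$n_patterns, 3L)
  expect_equal(g$p0, 1 / 3)
})
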