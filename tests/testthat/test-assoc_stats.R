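test_that("2x2 construction and the Haldane-Anscombe rule", {
  fx <- table_fixtures()
  t <- build_2x2(fx$B, "B*40:02:01")
  expect_equal(unclass(t)[c("a", "b", "c", "d")],
               c(a = 21, b = 161, c = 37, d = 663))
  expect_false(attr(t, "zero_cell_adjusted"))
  expect_equal(as.numeric(haldane_adjust(t)), as.numeric(t))  # no zero cell

  tz <- build_2x2(fx$DQA1, "DQA1*05:05:01")
  expect_equal(as.numeric(tz), c(28, 152, 0, 700))
  tz2 <- haldane_adjust(tz)
  expect_equal(as.numeric(tz2), c(28.5, 152.5, 0.5, 700.5))
  expect_true(attr(tz2, "zero_cell_adjusted"))

  expect_equal(as.numeric(haldane_adjust(tbl(0, 182, 10, 690))),
               c(0.5, 182.5, 10.5, 690.5))
  expect_error(build_2x2(fx$B, "B*99:99"), "not present")
})

test_that("Pearson chi-square matches an independent implementation", {
  # frozen published examples
  expect_equal(pearson_chi2(tbl(21, 161, 37, 663)), 9.192, tolerance = 5e-4)
  expect_equal(pearson_chi2(tbl(28.5, 152.5, 0.5, 700.5)), 111.149,
               tolerance = 5e-6)
  expect_equal(pearson_chi2(tbl(10, 172, 75, 625)), 4.519, tolerance = 5e-4)
  # identical proportions give exactly zero
  expect_equal(pearson_chi2(tbl(10, 90, 20, 180)), 0)
  # zero margin is undefined
  expect_error(pearson_chi2(tbl(0, 10, 0, 20)), "zero margin")

  # oracle equivalence on 1000 random integer tables
  set.seed(42)
  for (i in 1:1000) {
    a <- rpois(1, 10) + 1; b <- rpois(1, 50) + 1
    c_ <- rpois(1, 10) + 1; d <- rpois(1, 50) + 1
    expect_equal(pearson_chi2(tbl(a, b, c_, d)), oracle_chi2(a, b, c_, d),
                 tolerance = 1e-9)
  }

  # Yates correction shrinks |ad - bc| by N/2
  t <- tbl(3, 17, 9, 11)
  expect_lt(pearson_chi2(t, yates = TRUE), pearson_chi2(t))
  suppressWarnings(
    expect_equal(pearson_chi2(t, yates = TRUE),
                 unname(chisq.test(matrix(c(3, 17, 9, 11), 2, byrow = TRUE),
                                   correct = TRUE)$statistic),
                 tolerance = 1e-12))
})

test_that("Fisher's exact two-sided p equals hypergeometric enumeration", {
  expect_equal(fisher_two_sided(tbl(1, 1, 1, 1)), 1.0)
  expect_equal(fisher_two_sided(tbl(5, 0, 0, 5)), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_two_sided(tbl(2, 180, 0, 700)),
               oracle_fisher(2, 180, 0, 700), tolerance = 1e-9)

  set.seed(7)
  for (i in 1:200) {
    a <- rpois(1, 3); b <- rpois(1, 40) + 1
    c_ <- rpois(1, 3); d <- rpois(1, 40) + 1
    expect_equal(fisher_two_sided(tbl(a, b, c_, d)),
                 oracle_fisher(a, b, c_, d), tolerance = 1e-7)
  }
  # proportional tables are the independence case
  expect_equal(fisher_two_sided(tbl(10, 90, 30, 270)), 1.0, tolerance = 1e-9)
  expect_error(fisher_two_sided(tbl(0.5, 1, 1, 1)), "integer")
})

test_that("Woolf odds ratio and confidence interval", {
  expect_equal(odds_ratio_woolf(tbl(21, 161, 37, 663)),
               c(or = 2.337, ci_low = 1.332, ci_high = 4.102),
               tolerance = 3e-4)
  expect_equal(odds_ratio_woolf(tbl(28.5, 152.5, 0.5, 700.5)),
               c(or = 261.826, ci_low = 15.897, ci_high = 4312.308),
               tolerance = 2e-5)
  expect_equal(odds_ratio_woolf(tbl(33, 147, 6, 694))[["or"]], 25.966,
               tolerance = 2e-5)
  for (k in c(1, 5, 20)) {
    expect_equal(odds_ratio_woolf(tbl(k, k, k, k))[["or"]], 1.0)
  }
  expect_error(odds_ratio_woolf(tbl(0, 1, 1, 1)), "positive cells")

  # group swap inverts the OR and leaves the chi-square unchanged
  set.seed(11)
  for (i in 1:50) {
    t <- tbl(rpois(1, 8) + 1, rpois(1, 60) + 1,
             rpois(1, 8) + 1, rpois(1, 60) + 1)
    s <- tbl(t[["c"]], t[["d"]], t[["a"]], t[["b"]])
    expect_equal(odds_ratio_woolf(s)[["or"]],
                 1 / odds_ratio_woolf(t)[["or"]], tolerance = 1e-12)
    expect_equal(pearson_chi2(s), pearson_chi2(t), tolerance = 1e-12)
    expect_equal(odds_ratio_woolf(s)[["ci_low"]],
                 1 / odds_ratio_woolf(t)[["ci_high"]], tolerance = 1e-12)
  }
})

test_that("locus-wise correction is Sidak-type and numerically safe", {
  expect_equal(locus_correct(0.002, 31), 0.060, tolerance = 5e-3)
  expect_equal(locus_correct(0.25, 1), 0.25)
  expect_equal(locus_correct(0.001, 14), 1 - 0.999^14, tolerance = 1e-12)
  # monotone in p and in n; bounded by [p, 1]
  ps <- c(0, 1e-300, 1e-12, 0.001, 0.05, 0.5, 1)
  for (n in c(1, 5, 31)) {
    pc <- locus_correct(ps, n)
    expect_true(all(diff(pc) >= 0))
    expect_true(all(pc >= ps & pc <= 1))
  }
  expect_true(all(diff(sapply(c(1, 2, 10, 50),
                              function(n) locus_correct(0.01, n))) >= 0))
  # no underflow to zero for extreme p
  expect_gt(locus_correct(1e-300, 31), 0)
  expect_equal(locus_correct(1e-300, 31), 31e-300, tolerance = 1e-10)
})

test_that("Haberman adjusted standardized residuals follow the formula", {
  ct <- allele_counts("A", c("A*01:01", "A*02:01"), c(30, 70), c(10, 90),
                      case_total = 100, control_total = 100)
  r <- haberman_asr(ct)
  # hand evaluation: E = 20, row prop 40/200, col prop 100/200
  expect_equal(r$asr["A*01:01", "case"],
               (30 - 20) / sqrt(20 * (1 - 0.2) * (1 - 0.5)), tolerance = 1e-12)
  expect_equal(r$asr["A*01:01", "case"], 3.536, tolerance = 2e-4)
  expect_true(r$significant[["A*01:01"]])

  # O = E everywhere gives all-zero residuals
  ct0 <- allele_counts("A", c("A*01:01", "A*02:01"), c(30, 70), c(30, 70),
                       case_total = 100, control_total = 100)
  expect_equal(max(abs(haberman_asr(ct0)$asr)), 0)

  # case and control residuals of one allele are antisymmetric, and
  # observed-minus-expected sums vanish over rows and columns
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    ca <- rmultinom(1, 120, prob = runif(k))[, 1]
    co <- rmultinom(1, 300, prob = runif(k))[, 1]
    al <- sprintf("A*%02d:01", seq_len(k))
    r <- haberman_asr(allele_counts("A", al, ca, co, 120, 300))
    expect_equal(r$asr[, "case"], -r$asr[, "control"], tolerance = 1e-9)
    d <- r$observed - r$expected
    expect_lt(max(abs(rowSums(d))), 1e-9)
    expect_lt(max(abs(colSums(d))), 1e-9)
  }
})

test_that("per-locus analysis assembles, orders and flags correctly", {
  fx <- table_fixtures()
  r <- run_locus(fx$B)
  expect_s3_class(r, "assoc_table")
  expect_equal(nrow(r), 31L)
  expect_equal(attr(r, "n_alleles"), 31L)
  expect_equal(nrow(run_locus(fx$A)), 18L)
  # descending chi-square, stable name tie-break
  expect_true(all(diff(r$chi2) <= 1e-12))
  expect_equal(r$allele[1], "B*40:02:01")
  # zero-cell rows are flagged and all finite
  expect_true(all(r$zero_cell_adjusted[r$freq_case == 0 | r$freq_control == 0]))
  expect_true(all(is.finite(r$or)))
  expect_true(all(r$ci_low <= r$or & r$or <= r$ci_high))
  expect_true(all(r$p_corrected >= r$p_chi2 - 1e-15))

  single <- allele_counts("A", "A*01:01", 5, 5, 10, 10)
  expect_error(run_locus(single), "single-allele")
})

test_that("the full published chi-square, OR and CI surface reproduces", {
  fx <- table_fixtures()
  for (loc in names(fx)) {
    r <- run_locus(fx[[loc]])
    g <- golden_chi2[[loc]]
    expect_equal(length(setdiff(names(g), r$allele)), 0L)
    got <- r$chi2[match(names(g), r$allele)]
    expect_lt(max(abs(got - g)), 1e-3)
    # corrected p from the chi-square p reproduces the flagship value
    if (loc == "B") {
      i <- match("B*40:02:01", r$allele)
      expect_equal(r$p_corrected[i],
                   locus_correct(r$p_chi2[i], 31), tolerance = 1e-12)
    }
    for (al in intersect(names(golden_or), r$allele)) {
      i <- match(al, r$allele)
      expect_lt(max(abs(c(r$or[i], r$ci_low[i], r$ci_high[i]) -
                        golden_or[[al]])), 1e-3, label = al)
    }
  }
})
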