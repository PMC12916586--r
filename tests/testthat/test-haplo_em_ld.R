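test_that("EM with known phase equals direct haplotype counting", {
  # fully homozygous individuals: phase is certain
  pairs <- list(c("A*01:01", "A*01:01"), c("A*01:01", "A*01:01"),
                c("A*02:01", "A*02:01"))
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   A_1 = c("A*01:01", "A*01:01", "A*02:01"),
                   A_2 = c("A*01:01", "A*01:01", "A*02:01"),
                   B_1 = c("B*07:02", "B*08:01", "B*07:02"),
                   B_2 = c("B*07:02", "B*08:01", "B*07:02"))
  co <- hla_cohort(df, "case", c("A", "B"))
  hf <- em_haplotypes(co, c("A", "B"))
  got <- setNames(hf$freq, paste(hf$A, hf$B, sep = "~"))
  expect_equal(got[["A*01:01~B*07:02"]], 2 / 6, tolerance = 1e-9)
  expect_equal(got[["A*01:01~B*08:01"]], 2 / 6, tolerance = 1e-9)
  expect_equal(got[["A*02:01~B*07:02"]], 2 / 6, tolerance = 1e-9)
  expect_true(attr(hf, "converged"))

  # single heterozygous locus: still no phase ambiguity, equals counting
  df2 <- data.frame(sample_id = c("s1", "s2"),
                    A_1 = c("A*01:01", "A*01:01"),
                    A_2 = c("A*02:01", "A*01:01"),
                    B_1 = c("B*07:02", "B*07:02"),
                    B_2 = c("B*07:02", "B*07:02"))
  co2 <- hla_cohort(df2, "case", c("A", "B"))
  hf2 <- em_haplotypes(co2, c("A", "B"))
  got2 <- setNames(hf2$freq, paste(hf2$A, hf2$B, sep = "~"))
  expect_equal(got2[["A*01:01~B*07:02"]], 3 / 4, tolerance = 1e-9)
  expect_equal(got2[["A*02:01~B*07:02"]], 1 / 4, tolerance = 1e-9)
})

test_that("a lone double-heterozygote resolves to a symmetric optimum", {
  df <- data.frame(sample_id = "s1", A_1 = "A*01:01", A_2 = "A*02:01",
                   B_1 = "B*07:02", B_2 = "B*08:01")
  co <- hla_cohort(df, "case", c("A", "B"))
  hf <- em_haplotypes(co, c("A", "B"))
  # one of the two equivalent phase resolutions at 0.5/0.5, deterministically
  expect_equal(nrow(hf), 2L)
  expect_equal(sort(hf$freq), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(attr(hf, "loglik"), log(0.5), tolerance = 1e-6)
  # deterministic: same result on re-run
  hf2 <- em_haplotypes(co, c("A", "B"))
  expect_identical(as.data.frame(hf), as.data.frame(hf2))
})

test_that("EM recovers simulated haplotype frequencies", {
  truth <- c("A*01:01~B*07:02" = 0.4, "A*02:01~B*08:01" = 0.3,
             "A*01:01~B*08:01" = 0.2, "A*03:01~B*07:02" = 0.1)
  sim <- simulate_cohorts(synth_config(
    n_cases = 2, n_controls = 500,
    haplotype_freqs = list(loci = c("A", "B"), case = truth, control = truth),
    seed = 202))
  hf <- em_haplotypes(sim$controls, c("A", "B"))
  got <- setNames(hf$freq, paste(hf$A, hf$B, sep = "~"))
  for (h in names(truth)) {
    se <- sqrt(truth[[h]] * (1 - truth[[h]]) / 1000)
    expect_lt(abs(got[[h]] - truth[[h]]), 3 * se, label = h)
  }
  # frequencies sum to one; log-likelihood is monotone over the trace
  expect_equal(sum(hf$freq), 1, tolerance = 1e-8)
  expect_true(all(diff(attr(hf, "trace")) >= -1e-8))

  # excluding records missing a requested locus
  miss <- simulate_cohorts(synth_config(
    n_cases = 2, n_controls = 50,
    haplotype_freqs = list(loci = c("A", "B"), case = truth, control = truth),
    missing_rate = c(A = 0.3, B = 0), seed = 7))
  hfm <- em_haplotypes(miss$controls, c("A", "B"))
  expect_lt(attr(hfm, "n_records"), 50L)
  expect_error(em_haplotypes(miss$controls, c("A", "DPB1")), "not typed")
})

test_that("pairwise LD normalization hits its closed-form anchors", {
  # complete association of two biallelic loci
  truth <- c("A*01:01~B*07:02" = 0.5, "A*02:01~B*08:01" = 0.5)
  sim <- simulate_cohorts(synth_config(
    n_cases = 2, n_controls = 300,
    haplotype_freqs = list(loci = c("A", "B"), case = truth, control = truth),
    seed = 11))
  hf <- em_haplotypes(sim$controls, c("A", "B"))
  v <- ld_pair(hf)
  expect_equal(v[["dprime"]], 1, tolerance = 1e-9)
  expect_equal(v[["rsq"]], 1, tolerance = 1e-9)

  # independence: product frequencies give D' = r2 = 0 exactly
  ind <- structure(
    data.frame(A = rep(c("A*01:01", "A*02:01"), each = 2),
               B = rep(c("B*07:02", "B*08:01"), 2),
               freq = c(0.6 * 0.7, 0.6 * 0.3, 0.4 * 0.7, 0.4 * 0.3)),
    loci = c("A", "B"), class = c("haplo_freqs", "data.frame"))
  v0 <- ld_pair(ind)
  expect_equal(v0[["dprime"]], 0)
  expect_equal(v0[["rsq"]], 0)
  expect_equal(ld_pair(ind, weighting = "uniform")[["dprime"]], 0)

  # biallelic case agrees with the classical closed forms
  p <- 0.6; q <- 0.7; D <- 0.08
  ht <- structure(
    data.frame(A = rep(c("A*01:01", "A*02:01"), each = 2),
               B = rep(c("B*07:02", "B*08:01"), 2),
               freq = c(p * q + D, p * (1 - q) - D,
                        (1 - p) * q - D, (1 - p) * (1 - q) + D)),
    loci = c("A", "B"), class = c("haplo_freqs", "data.frame"))
  v1 <- ld_pair(ht, weighting = "uniform")
  dmax <- min(p * (1 - q), (1 - p) * q)
  expect_equal(v1[["dprime"]], D / dmax, tolerance = 1e-12)
  expect_equal(v1[["rsq"]], D^2 / (p * (1 - p) * q * (1 - q)),
               tolerance = 1e-12)
  # frequency weighting changes the average, not the per-pair values;
  # for biallelic loci all four pairs share |D| so D' stays put
  expect_equal(ld_pair(ht)[["dprime"]], D / dmax, tolerance = 1e-12)

  # monomorphic locus has no defined LD
  mono <- structure(
    data.frame(A = "A*01:01", B = c("B*07:02", "B*08:01"),
               freq = c(0.5, 0.5)),
    loci = c("A", "B"), class = c("haplo_freqs", "data.frame"))
  expect_true(all(is.na(ld_pair(mono))))
})

test_that("LD matrices are symmetric, bounded, and ordered chromosomally", {
  # duplicated locus content: every haplotype x~x, perfect LD
  df <- data.frame(sample_id = sprintf("s%d", 1:40))
  set.seed(5)
  a <- sample(c("01:01", "02:01", "03:01"), 40, TRUE)
  b <- sample(c("01:01", "02:01", "03:01"), 40, TRUE)
  df$A_1 <- paste0("A*", a); df$A_2 <- paste0("A*", b)
  df$B_1 <- paste0("B*", a); df$B_2 <- paste0("B*", b)
  co <- hla_cohort(df, "control", c("A", "B"))
  m <- ld_matrix(co, c("B", "A"))  # order given reversed on purpose
  expect_equal(m$loci, c("A", "B"))
  expect_equal(m$dprime["A", "B"], 1, tolerance = 1e-9)
  # mean r-squared stays below 1 for multi-allelic perfect coupling (the
  # off-diagonal allele pairs have r2 = p q / ((1-p)(1-q)) < 1)
  expect_lt(m$rsq["A", "B"], 1)
  expect_gt(m$rsq["A", "B"], 0.3)
  expect_equal(diag(m$dprime), c(A = 1, B = 1))
  expect_true(all(m$dprime >= 0 & m$dprime <= 1))
  expect_true(all(m$rsq >= 0 & m$rsq <= 1))
  expect_equal(m$dprime, t(m$dprime))

  # tight Class II block vs independent Class I: the block shows more LD
  class2 <- c("DRB1*03:01~DQA1*05:01~DQB1*02:01~DPB1*04:01" = 0.4,
              "DRB1*15:01~DQA1*01:02~DQB1*06:02~DPB1*04:02" = 0.3,
              "DRB1*07:01~DQA1*02:01~DQB1*02:02~DPB1*02:01" = 0.2,
              "DRB1*01:01~DQA1*01:01~DQB1*05:01~DPB1*04:01" = 0.1)
  sim2 <- simulate_cohorts(synth_config(
    n_cases = 2, n_controls = 150,
    haplotype_freqs = list(loci = c("DRB1", "DQA1", "DQB1", "DPB1"),
                           case = class2, control = class2),
    seed = 31))
  af <- list(
    A = list(case = c("A*01:01" = 0.5, "A*02:01" = 0.5),
             control = c("A*01:01" = 0.5, "A*02:01" = 0.5)),
    DPB1 = list(case = c("DPB1*04:01" = 0.6, "DPB1*02:01" = 0.4),
                control = c("DPB1*04:01" = 0.6, "DPB1*02:01" = 0.4)))
  simI <- simulate_cohorts(synth_config(n_cases = 2, n_controls = 150,
                                        allele_freqs = af, seed = 32))
  m2 <- ld_matrix(sim2$controls, c("DRB1", "DQA1"))
  mI <- ld_matrix(simI$controls, c("A", "DPB1"))
  expect_gt(m2$dprime["DRB1", "DQA1"], mI$dprime["A", "DPB1"])

  # identical cohorts give identical matrices
  mA <- ld_matrix(sim2$controls, c("DRB1", "DQB1"))
  mB <- ld_matrix(sim2$controls, c("DRB1", "DQB1"))
  expect_identical(mA$dprime, mB$dprime)
})

test_that("haplotype association mirrors the allele-level machinery", {
  mk <- function(freqs, loci = c("DRB1", "DQB1")) {
    parts <- strsplit(names(freqs), "~", fixed = TRUE)
    structure(
      cbind(as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
            |> setNames(loci),
            data.frame(freq = unname(freqs))),
      loci = loci, class = c("haplo_freqs", "data.frame"))
  }
  f <- c("DRB1*03:01~DQB1*02:01" = 0.6, "DRB1*15:01~DQB1*06:02" = 0.4)
  same <- haplotype_assoc(mk(f), mk(f), 200, 700)
  expect_true(all(abs(same$chi2) < 1e-9))
  expect_true(all(abs(same$or - 1) < 1e-9))

  # a case-only haplotype at 0.10 vs absent in controls reproduces the
  # allele-level Haldane statistics for the same fractional table
  fc <- c("DRB1*03:01~DQB1*02:01" = 0.9, "DRB1*05:05~DQB1*03:01" = 0.1)
  fk <- c("DRB1*03:01~DQB1*02:01" = 1.0)
  ha <- haplotype_assoc(mk(fc), mk(fk), 182, 700)
  i <- which(ha$DRB1 == "DRB1*05:05")
  t <- hlacc:::two_by_two(0.1 * 182, 182 - 0.1 * 182, 0, 700)
  t <- haldane_adjust(t)
  expect_equal(ha$chi2[i], pearson_chi2(t), tolerance = 1e-12)
  expect_equal(ha$or[i], odds_ratio_woolf(t)[["or"]], tolerance = 1e-12)
  expect_true(ha$zero_cell_adjusted[i])
  expect_true(ha$em_unstable[i])  # expected control count 0 < 5

  # group swap: reciprocal odds ratios
  swap <- haplotype_assoc(mk(fk), mk(fc), 700, 182)
  j <- which(swap$DRB1 == "DRB1*05:05")
  expect_equal(swap$or[j], 1 / ha$or[i], tolerance = 1e-12)

  # correction uses the number of haplotypes tested
  expect_equal(ha$p_corrected,
               locus_correct(ha$p_chi2, nrow(ha)), tolerance = 1e-15)
  expect_error(haplotype_assoc(mk(f), mk(f, loci = c("DRB1", "DPB1")),
                               100, 100), "different loci")
})
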