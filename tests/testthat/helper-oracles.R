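# Independent oracles and small fixture builders shared across tests.

# textbook Pearson chi-square via observed/expected sums (no closed form)
oracle_chi2 <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# two-sided Fisher p by full hypergeometric enumeration over the support,
# minimum-likelihood convention
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  pr <- dhyper(support, m1, m2, k)
  sum(pr[pr <= dhyper(a, m1, m2, k) * (1 + 1e-7)])
}

# exact biallelic Hardy-Weinberg test: enumerate the conditional
# distribution of the heterozygote count given allele counts
oracle_hwe_biallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  m1 <- 2 * nAA + nAB
  hs <- seq(m1 %% 2, min(m1, 2 * n - m1), by = 2)
  lp <- vapply(hs, function(h) {
    n1 <- (m1 - h) / 2; n2 <- (2 * n - m1 - h) / 2
    lfactorial(n) - lfactorial(n1) - lfactorial(h) - lfactorial(n2) +
      h * log(2) + lfactorial(m1) + lfactorial(2 * n - m1) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp)
  min(sum(pr[pr <= pr[hs == nAB] * (1 + 1e-9)]), 1)
}

# cohort of one locus from explicit genotype pairs
cohort_from_pairs <- function(pairs, locus = "A", group = "control") {
  df <- data.frame(sample_id = sprintf("s%03d", seq_along(pairs)),
                   stringsAsFactors = FALSE)
  df[[paste0(locus, "_1")]] <- vapply(pairs, `[`, "", 1L)
  df[[paste0(locus, "_2")]] <- vapply(pairs, `[`, "", 2L)
  hla_cohort(df, group = group, loci = locus)
}

# biallelic genotype-count table from genotype totals
geno_table <- function(nAA, nAB, nBB, locus = "A") {
  pairs <- c(rep(list(c("A*01:01", "A*01:01")), nAA),
             rep(list(c("A*01:01", "A*02:01")), nAB),
             rep(list(c("A*02:01", "A*02:01")), nBB))
  genotype_counts(cohort_from_pairs(pairs, locus = "A"), "A")
}

tbl <- function(a, b, c, d) hlacc:::two_by_two(a, b, c, d)
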