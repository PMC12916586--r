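#' Monte-Carlo exact Hardy-Weinberg test for a multi-allelic locus
#'
#' Exact-test criterion conditional on the observed allele counts: the
#' statistic is the log conditional probability of the genotype
#' configuration given the allele counts,
#' `log P = log(n!) + sum(log(m_k!)) + h log 2 - log((2n)!) - sum(log(g_ij!))`
#' with `m_k` the allele counts, `g_ij` the genotype counts and `h` the
#' number of heterozygous individuals.  The null distribution is sampled by
#' randomly permuting the pooled vector of `2n` allele copies and pairing
#' adjacent entries, which draws genotype configurations from exactly this
#' conditional distribution.  The p-value counts replicate configurations
#' at least as improbable as the observed one, with the observed table
#' included so that p is never zero:
#' `p = (1 + #\{replicate stat <= observed\}) / (n_replicates + 1)`.
#'
#' Deviation from Hardy-Weinberg proportions at a control locus can signal
#' genotyping error, allele dropout, or cryptic population stratification
#' (the Wahlund heterozygote deficit from mixing subpopulations with
#' divergent allele frequencies).
#'
#' @param g a [genotype_counts()] table.
#' @param n_replicates Monte-Carlo replicates (default 10000).
#' @param seed integer seed; recorded in the result.  The caller's RNG
#'   state is preserved.
#' @return an `hwe_result`: list with `locus`, `p_value`, `observed_stat`
#'   (log conditional probability), `n_replicates`, `seed`, `n_individuals`,
#'   `n_alleles`.
#' @examples
#' sim <- simulate_cohorts(synth_config(
#'   n_cases = 5, n_controls = 100,
#'   allele_freqs = list(A = list(
#'     case = c("A*01:01" = 0.3, "A*02:01" = 0.7),
#'     control = c("A*01:01" = 0.3, "A*02:01" = 0.7))),
#'   seed = 7))
#' hwe_exact_mc(genotype_counts(sim$controls, "A"), n_replicates = 2000, seed = 7)
#' @export
hwe_exact_mc <- function(g, n_replicates = 10000L, seed = 1L) {
  stopifnot(inherits(g, "genotype_counts"), n_replicates >= 1)
  n <- attr(g, "n_individuals")
  alleles <- sort(unique(c(g$allele1, g$allele2)))
  k <- length(alleles)
  if (k < 2) {
    warning("monomorphic locus: Hardy-Weinberg test not possible, p = 1")
    return(structure(list(locus = attr(g, "locus"), p_value = 1,
                          observed_stat = 0, n_replicates = 0L,
                          seed = seed, n_individuals = n, n_alleles = k),
                     class = "hwe_result"))
  }
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)

  i1 <- match(g$allele1, alleles)
  i2 <- match(g$allele2, alleles)
  # pooled allele-copy vector, length 2n
  pool <- rep(c(i1, i2), times = c(g$count, g$count))
  m <- tabulate(pool, nbins = k)          # allele counts, fixed margin
  const <- lfactorial(n) + sum(lfactorial(m)) - lfactorial(2L * n)

  # relative statistic: h log 2 - sum(lfactorial(genotype counts));
  # the constant term cancels in comparisons
  rel_stat <- function(g1, g2) {
    key <- pmin(g1, g2) * (k + 1L) + pmax(g1, g2)
    cnt <- rle(sort.int(key, method = "radix"))$lengths
    sum(g1 != g2) * log(2) - sum(lfactorial(cnt))
  }
  obs_rel <- sum(g$count[i1 != i2]) * log(2) - sum(lfactorial(g$count))

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(seed)
  odd <- seq.int(1L, 2L * n, by = 2L)
  hits <- 0L
  for (r in seq_len(n_replicates)) {
    perm <- sample(pool)
    if (rel_stat(perm[odd], perm[odd + 1L]) <= obs_rel + 1e-9) hits <- hits + 1L
  }
  structure(
    list(locus = attr(g, "locus"),
         p_value = (1 + hits) / (n_replicates + 1),
         observed_stat = const + obs_rel,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed),
         n_individuals = n,
         n_alleles = k),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> locus %s: p = %.4g (%d alleles, n = %d, %d replicates, seed %d)\n",
              x$locus, x$p_value, x$n_alleles, x$n_individuals,
              x$n_replicates, x$seed))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
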