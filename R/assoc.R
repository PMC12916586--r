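#' Build the 2x2 carrier table for one allele
#'
#' Rows are groups (case, control), columns carrier / non-carrier
#' chromosomes: `a` = case carriers, `b` = case non-carriers, `c` = control
#' carriers, `d` = control non-carriers.
#'
#' @param counts an [allele_counts()] table.
#' @param allele allele name present in `counts`.
#' @return a `two_by_two` object: named numeric vector `(a, b, c, d)` with
#'   attribute `zero_cell_adjusted = FALSE`.
#' @export
build_2x2 <- function(counts, allele) {
  stopifnot(inherits(counts, "allele_counts"))
  i <- match(allele, counts$allele)
  if (is.na(i)) {
    stop(sprintf("allele '%s' not present at locus %s", allele,
                 attr(counts, "locus")), call. = FALSE)
  }
  two_by_two(a = counts$case_count[i],
             b = attr(counts, "case_total") - counts$case_count[i],
             c = counts$control_count[i],
             d = attr(counts, "control_total") - counts$control_count[i])
}

two_by_two <- function(a, b, c, d, adjusted = FALSE) {
  t <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  stopifnot(all(t >= 0))
  structure(t, zero_cell_adjusted = adjusted, class = "two_by_two")
}

#' Haldane-Anscombe zero-cell correction
#'
#' If any cell of the 2x2 table is exactly zero, add 0.5 to all four cells;
#' otherwise return the table unchanged.  This is what makes odds ratios
#' and chi-square statistics finite for alleles observed in only one group,
#' and it is applied before the Pearson statistic and the Woolf interval
#' throughout the pipeline.
#'
#' @param t a `two_by_two` table.
#' @return the (possibly adjusted) table; attribute `zero_cell_adjusted`
#'   records whether the correction fired.
#' @export
haldane_adjust <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (any(t == 0)) {
    two_by_two(t[["a"]] + 0.5, t[["b"]] + 0.5, t[["c"]] + 0.5, t[["d"]] + 0.5,
               adjusted = TRUE)
  } else t
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' Closed form `N (|ad - bc| - delta)^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' `delta = N/2` under Yates' continuity correction, else 0.  Accepts
#' non-integer cells so it can be applied to Haldane-adjusted tables.
#' The pipeline default is `yates = FALSE`.
#'
#' @param t a `two_by_two` table (Haldane-adjusted where relevant).
#' @param yates apply Yates' continuity correction.
#' @return the chi-square statistic (1 degree of freedom).
#' @export
pearson_chi2 <- function(t, yates = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t[["a"]]; b <- t[["b"]]; c <- t[["c"]]; d <- t[["d"]]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("chi-square undefined: zero margin (allele fixed in both groups)",
         call. = FALSE)
  }
  delta <- if (yates) n / 2 else 0
  num <- max(abs(a * d - b * c) - delta, 0)
  n * num^2 / prod(margins)
}

#' Two-sided p-value from the chi-square statistic
#'
#' @param chi2 chi-square statistic, 1 df.
#' @return upper-tail probability.
#' @export
chi2_p <- function(chi2) stats::pchisq(chi2, df = 1L, lower.tail = FALSE)

#' Fisher's exact test, two-sided, for a 2x2 table
#'
#' Minimum-likelihood convention: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table.  Requires the
#' raw integer table (apply before any Haldane adjustment).
#'
#' @param t a `two_by_two` table with integer cells.
#' @return two-sided p-value.
#' @export
fisher_two_sided <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (any(abs(t - round(t)) > 1e-9)) {
    stop("Fisher's exact test requires integer cell counts (unadjusted table)",
         call. = FALSE)
  }
  m <- matrix(round(t), nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Woolf odds ratio and 95% confidence interval
#'
#' `OR = ad / bc`; the interval is `exp(log OR +/- 1.96 sqrt(1/a + 1/b +
#' 1/c + 1/d))` (normal approximation to the log odds ratio).  All cells
#' must be positive, so apply [haldane_adjust()] first for sparse tables.
#'
#' @param t a `two_by_two` table with strictly positive cells.
#' @return named numeric vector `(or, ci_low, ci_high)`.
#' @export
odds_ratio_woolf <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  if (any(t == 0)) {
    stop("Woolf OR requires positive cells; apply haldane_adjust() first",
         call. = FALSE)
  }
  or <- t[["a"]] * t[["d"]] / (t[["b"]] * t[["c"]])
  se <- sqrt(sum(1 / t))
  c(or = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se))
}

#' Sidak-type locus-wise multiplicity correction
#'
#' `pc = 1 - (1 - p)^n` over the `n` alleles tested at a locus, evaluated
#' in log space (`-expm1(n * log1p(-p))`) so that corrected values remain
#' accurate for p far below 1e-12.
#'
#' @param p per-allele p-value(s) in `[0, 1]`.
#' @param n_alleles number of alleles tested at the locus.
#' @return corrected p-value(s), clamped to `[0, 1]`.
#' @export
locus_correct <- function(p, n_alleles) {
  stopifnot(all(p >= 0 & p <= 1), n_alleles >= 1)
  pc <- -expm1(n_alleles * log1p(-p))
  pmin(pmax(pc, p), 1)
}

#' Haberman adjusted standardized residuals for an alleles-by-groups table
#'
#' For each cell, `ASR = (O - E) / sqrt(E (1 - row prop)(1 - col prop))`
#' where `E` is the usual independence expectation and the proportions are
#' the marginal totals over the grand total.  Under independence the ASR is
#' approximately standard normal, so cells with `|ASR| >= crit` (default
#' 1.96) are flagged as significant contributors to the table-wide
#' chi-square signal.  Robust for sparse, multi-allelic HLA tables.
#'
#' @param counts an [allele_counts()] table with at least two alleles.
#' @param crit flagging threshold on `|ASR|` (default 1.96).
#' @return a `residual_table`: list with matrices `observed`, `expected`,
#'   `asr` (rows = alleles, columns = case/control) and logical vector
#'   `significant` (per allele, from the case column).
#' @export
haberman_asr <- function(counts, crit = 1.96) {
  stopifnot(inherits(counts, "allele_counts"), nrow(counts) >= 2)
  O <- cbind(case = counts$case_count, control = counts$control_count)
  rownames(O) <- counts$allele
  rowtot <- rowSums(O)
  coltot <- colSums(O)
  grand <- sum(O)
  if (grand == 0) stop("empty table", call. = FALSE)
  E <- outer(rowtot, coltot) / grand
  denom <- sqrt(E * outer(1 - rowtot / grand, 1 - coltot / grand))
  asr <- (O - E) / denom
  structure(
    list(observed = O, expected = E, asr = asr,
         significant = abs(asr[, "case"]) >= crit,
         crit = crit),
    class = "residual_table"
  )
}

#' @export
print.residual_table <- function(x, ...) {
  cat(sprintf("<residual_table> %d alleles; |ASR| >= %.2f flags %d\n",
              nrow(x$asr), x$crit, sum(x$significant)))
  print(round(x$asr, 3))
  invisible(x)
}

#' Full per-allele association analysis for one locus
#'
#' Assembles, for every allele in the count table: gene-counting
#' frequencies, Pearson chi-square (on the Haldane-adjusted table when a
#' zero cell is present) with its p-value, Fisher's exact two-sided p (on
#' the raw table), Woolf odds ratio with 95% CI (Haldane-adjusted table),
#' the Sidak-type locus-corrected p with `n` = number of alleles at the
#' locus, and the Haberman adjusted standardized residual (case column).
#' Rows are ordered by descending chi-square, ties broken by allele name.
#'
#' @param counts an [allele_counts()] table with at least two alleles.
#' @param yates apply Yates' continuity correction to the chi-square
#'   (default `FALSE`; every published sparse-table value this package
#'   reproduces uses the uncorrected statistic).
#' @param correct_from which p-value feeds the locus correction:
#'   `"chi2"` (default) or `"fisher"`.
#' @return an `assoc_table`: data frame with one row per allele and columns
#'   `allele`, `freq_case`, `freq_control`, `chi2`, `p_chi2`, `p_fisher`,
#'   `or`, `ci_low`, `ci_high`, `p_corrected`, `asr`, `zero_cell_adjusted`;
#'   attributes `locus` and `n_alleles`.
#' @examples
#' fx <- table_fixtures()
#' head(run_locus(fx$B), 3)
#' @export
run_locus <- function(counts, yates = FALSE,
                      correct_from = c("chi2", "fisher")) {
  stopifnot(inherits(counts, "allele_counts"))
  correct_from <- match.arg(correct_from)
  n <- nrow(counts)
  if (n < 2) {
    stop("association undefined for a single-allele locus", call. = FALSE)
  }
  res <- haberman_asr(counts)
  integer_counts <- all(abs(c(counts$case_count, counts$control_count) -
                            round(c(counts$case_count, counts$control_count))) < 1e-9)
  rows <- lapply(seq_len(n), function(i) {
    t0 <- build_2x2(counts, counts$allele[i])
    t1 <- haldane_adjust(t0)
    chi2 <- pearson_chi2(t1, yates = yates)
    orci <- odds_ratio_woolf(t1)
    data.frame(
      allele = counts$allele[i],
      freq_case = counts$case_count[i] / attr(counts, "case_total"),
      freq_control = counts$control_count[i] / attr(counts, "control_total"),
      chi2 = chi2,
      p_chi2 = chi2_p(chi2),
      p_fisher = if (integer_counts) fisher_two_sided(t0) else NA_real_,
      or = orci[["or"]],
      ci_low = orci[["ci_low"]],
      ci_high = orci[["ci_high"]],
      asr = res$asr[i, "case"],
      zero_cell_adjusted = attr(t1, "zero_cell_adjusted"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  p_base <- if (correct_from == "chi2") out$p_chi2 else out$p_fisher
  out$p_corrected <- locus_correct(p_base, n)
  out <- out[order(-out$chi2, out$allele), ]
  rownames(out) <- NULL
  out <- out[, c("allele", "freq_case", "freq_control", "chi2", "p_chi2",
                 "p_fisher", "or", "ci_low", "ci_high", "p_corrected",
                 "asr", "zero_cell_adjusted")]
  structure(out, locus = attr(counts, "locus"), n_alleles = n,
            class = c("assoc_table", "data.frame"))
}

#' @export
print.assoc_table <- function(x, digits = 3, ...) {
  cat(sprintf("<assoc_table> locus %s: %d alleles\n",
              attr(x, "locus"), attr(x, "n_alleles")))
  print.data.frame(format_assoc(x), row.names = FALSE)
  invisible(x)
}
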