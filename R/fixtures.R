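# Published per-allele frequencies for the aplastic-anemia case-control
# cohort (91 ethnic-Kazakh patients, 250 registry donors), as printed at
# six-digit resolution.  Chromosome totals are inferred from the frequency
# grids themselves: every control frequency is an integer multiple of 1/700
# and case DRB1/DQA1 frequencies are multiples of 1/180 (one case untyped at
# those loci), so the totals are {182 or 180} cases / 700 controls, not the
# 2x91/2x250 the headline sample sizes would suggest.  The reconstruction
# below multiplies each frequency by its total and requires the product to
# land within 0.02 of an integer, which validates both the totals and the
# transcription.
.fixture_freqs <- function() {
  f <- function(locus, txt) {
    con <- textConnection(txt)
    on.exit(close(con))
    df <- utils::read.table(con, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("allele", "freq_case", "freq_control"))
    df$locus <- locus
    df
  }
  rbind(
    f("A", "
      A*33:01:01 0.01648 0.00714
      A*26:01:01 0.06044 0.05000
      A*29:01:01 0.01099 0.01571
      A*32:01:01 0.02198 0.02714
      A*30:01:01 0.02198 0.01857
      A*01:01:01 0.07692 0.08571
      A*68:01:02 0.01648 0.03429
      A*31:01:02 0.04396 0.04714
      A*24:02:01 0.22527 0.18857
      A*02:01:01 0.20330 0.17714
      A*02:05:01 0.01648 0.01000
      A*02:06:01 0.06593 0.03429
      A*02:07:01 0.01099 0.02857
      A*33:03:01 0.03846 0.05286
      A*03:01:01 0.05495 0.06286
      A*03:02:01 0.01648 0.00429
      A*11:01:01 0.04945 0.08857
      A*23:01:01 0.01648 0.01857"),
    f("C", "
      C*07:06:01 0.01099 0.00000
      C*08:01:01 0.04396 0.01714
      C*04:01:01 0.05495 0.10714
      C*07:02:01 0.15385 0.10286
      C*03:04:01 0.12637 0.08286
      C*07:04:01 0.01099 0.03429
      C*15:02:01 0.02747 0.05714
      C*12:03:01 0.03846 0.07143
      C*16:04:01 0.01099 0.00286
      C*05:01:01 0.03846 0.02286
      C*02:02:02 0.01648 0.03143
      C*03:03:01 0.05495 0.03714
      C*12:02:02 0.01099 0.00429
      C*08:02:01 0.02747 0.01571
      C*06:02:01 0.10440 0.12429
      C*08:03:01 0.00549 0.01143
      C*14:02:01 0.02198 0.02571
      C*12:02:01 0.02747 0.03143
      C*01:02:01 0.07143 0.07286
      C*07:01:01 0.05495 0.05429
      C*03:02:02 0.05495 0.05429"),
    f("B", "
      B*40:02:01 0.11538 0.05286
      B*44:03:02 0.01099 0.00000
      B*67:01:01 0.01099 0.00000
      B*73:01:01 0.01099 0.00143
      B*07:02:01 0.09341 0.05857
      B*54:01:01 0.03297 0.01429
      B*49:01:01 0.03297 0.01429
      B*44:03:01 0.00549 0.02143
      B*44:02:01 0.04396 0.02429
      B*35:01:01 0.02747 0.05143
      B*40:01:01 0.00000 0.01429
      B*38:01:01 0.01099 0.02714
      B*27:05:02 0.01099 0.02714
      B*46:01:01 0.01099 0.02571
      B*18:01:01 0.01648 0.03143
      B*14:02:01 0.02747 0.01571
      B*15:18:01 0.01099 0.02143
      B*35:03:01 0.03297 0.04571
      B*37:01:01 0.01648 0.01000
      B*13:02:01 0.05495 0.07000
      B*48:01:01 0.03846 0.02857
      B*15:01:01 0.02198 0.03143
      B*52:01:01 0.02747 0.03571
      B*35:02:01 0.01099 0.00714
      B*57:01:01 0.01099 0.01571
      B*39:01:01L 0.01099 0.01571
      B*50:01:01 0.02198 0.02714
      B*51:01:01 0.07143 0.08000
      B*40:06:01 0.01099 0.01429
      B*08:01:01 0.03297 0.03714
      B*58:01:01 0.05495 0.06000"),
    f("DRB1", "
      DRB1*05:05:01 0.15556 0.00000
      DRB1*01:02:01 0.18333 0.00857
      DRB1*03:03:01 0.11111 0.00000
      DRB1*05:01:01 0.11111 0.00000
      DRB1*02:01:01 0.10556 0.00000
      DRB1*01:03:01 0.08333 0.00000
      DRB1*03:02:01 0.05556 0.00000
      DRB1*01:04:01 0.04444 0.00000
      DRB1*07:01:01 0.00000 0.12714
      DRB1*15:01:01 0.00000 0.09571
      DRB1*06:01:01 0.01667 0.00000
      DRB1*05:03:01 0.01667 0.00000
      DRB1*04:01:01 0.01667 0.08714
      DRB1*13:01:01 0.00000 0.05571
      DRB1*14:01:01 0.00000 0.04429
      DRB1*01:05:01 0.01111 0.00000
      DRB1*11:01:01 0.00000 0.04286
      DRB1*03:01:01 0.03889 0.10143
      DRB1*13:02:01 0.00000 0.03714
      DRB1*12:01:01 0.00000 0.03429
      DRB1*09:01:02 0.00000 0.03286
      DRB1*15:02:01 0.00000 0.03000
      DRB1*01:01:01 0.03333 0.07429"),
    f("DQA1", "
      DQA1*05:05:01 0.15556 0.00000
      DQA1*03:03:01 0.11111 0.00000
      DQA1*03:02:01 0.05556 0.00000
      DQA1*01:04:01 0.04444 0.00000
      DQA1*03:01:01 0.03889 0.20857
      DQA1*01:01:01 0.03333 0.15714
      DQA1*05:01:01 0.11111 0.22143
      DQA1*01:05:01 0.01111 0.00000
      DQA1*01:01:02 0.00556 0.00000
      DQA1*01:02:01 0.18333 0.13714
      DQA1*01:03:01 0.08333 0.11143
      DQA1*02:01:01 0.10556 0.12714
      DQA1*04:01:01 0.01667 0.01000
      DQA1*06:01:01 0.01667 0.02571"),
    f("DQB1", "
      DQB1*02:02:01 0.08791 0.00000
      DQB1*02:01:01 0.11538 0.21143
      DQB1*06:02:01 0.14835 0.08143
      DQB1*05:01:01 0.04396 0.09571
      DQB1*04:01:01 0.03297 0.01429
      DQB1*05:03:01 0.01648 0.04000
      DQB1*06:01:01 0.03297 0.06143
      DQB1*03:02:01 0.05495 0.08000
      DQB1*03:03:02 0.06593 0.04571
      DQB1*03:01:01 0.25275 0.21714
      DQB1*05:02:01 0.04396 0.03143
      DQB1*06:04:01 0.01648 0.02571
      DQB1*06:03:01 0.04945 0.05571
      DQB1*04:02:01 0.01648 0.01429
      DQB1*06:09:01 0.01099 0.01143"),
    f("DPB1", "
      DPB1*02:01:02 0.07143 0.00000
      DPB1*104:01:01 0.03297 0.00000
      DPB1*02:01:01 0.07692 0.17714
      DPB1*05:01:01 0.12637 0.07429
      DPB1*04:01:01 0.40110 0.32714
      DPB1*03:01:01 0.06044 0.09143
      DPB1*04:02:01 0.09341 0.12857
      DPB1*17:01:01 0.02198 0.04000
      DPB1*02:02:01 0.00549 0.01571
      DPB1*14:01:01 0.01099 0.01857
      DPB1*36:01:01 0.00000 0.00571
      DPB1*13:01:01 0.02198 0.03000
      DPB1*09:01:01 0.02198 0.02286
      DPB1*15:01:01 0.01099 0.01143"))
}

# case chromosome totals: 182 for loci where all 91 cases were typed, 180
# where one case was untyped (DRB1, DQA1); controls 700 at every locus
.fixture_totals <- function() {
  list(case = c(A = 182, C = 182, B = 182, DRB1 = 180, DQA1 = 180,
                DQB1 = 182, DPB1 = 182),
       control = c(A = 700, C = 700, B = 700, DRB1 = 700, DQA1 = 700,
                   DQB1 = 700, DPB1 = 700))
}

#' Reconstructed allele count tables for the published cohort
#'
#' Rebuilds the integer chromosome counts underlying the published
#' per-allele frequency tables by multiplying each frequency by the
#' locus-specific chromosome totals (cases: 182 for A/C/B/DQB1/DPB1, 180
#' for DRB1/DQA1; controls: 700) and rounding to the nearest integer.
#' Every product must land within `tol` of an integer; a larger residual
#' aborts, since it would mean either a transcription error or wrong
#' totals.  These tables are the regression surface for the association
#' statistics.
#'
#' @param tol maximum allowed distance from an integer (default 0.02).
#' @return named list of [allele_counts()] tables, one per locus in
#'   chromosomal order.
#' @examples
#' fx <- table_fixtures()
#' fx$B[fx$B$allele == "B*40:02:01", ]   # 21 of 182 vs 37 of 700
#' @export
table_fixtures <- function(tol = 0.02) {
  freqs <- .fixture_freqs()
  tots <- .fixture_totals()
  out <- list()
  for (loc in hla_loci()) {
    df <- freqs[freqs$locus == loc, ]
    ca_raw <- df$freq_case * tots$case[[loc]]
    co_raw <- df$freq_control * tots$control[[loc]]
    bad <- abs(ca_raw - round(ca_raw)) > tol | abs(co_raw - round(co_raw)) > tol
    if (any(bad)) {
      stop(sprintf("fixture integrity error at %s: %s does not reconstruct to integer counts",
                   loc, paste(df$allele[bad], collapse = ", ")),
           call. = FALSE)
    }
    out[[loc]] <- allele_counts(
      locus = loc, allele = df$allele,
      case_count = round(ca_raw), control_count = round(co_raw),
      case_total = tots$case[[loc]], control_total = tots$control[[loc]]
    )
  }
  out
}

#' Published per-allele frequencies used to build the fixtures
#'
#' @return data frame with columns `locus`, `allele`, `freq_case`,
#'   `freq_control` (frequencies as printed, five decimals).
#' @export
fixture_frequencies <- function() {
  .fixture_freqs()[, c("locus", "allele", "freq_case", "freq_control")]
}
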