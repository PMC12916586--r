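#' Format a p-value in 3-digit decimal notation
#'
#' Reporting convention for association tables: three decimals with no
#' leading zero, values below 0.001 shown as `"<.001"`.
#'
#' @param p numeric vector of probabilities.
#' @return character vector.
#' @examples
#' format_pvalue(c(0.0005, 0.06, 1))   # "<.001" ".060" "1.000"
#' @export
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<.001",
                sub("^0", "", sprintf("%.3f", p))))
  out
}

#' Format an odds ratio with its 95% confidence interval
#'
#' @param or,ci_low,ci_high numeric vectors.
#' @return character vector like `"2.337 (1.332, 4.102)"`.
#' @export
format_or_ci <- function(or, ci_low, ci_high) {
  sprintf("%.3f (%.3f, %.3f)", or, ci_low, ci_high)
}

#' Render an association table for reporting
#'
#' Applies the 3-digit p-value convention and the `"OR (low, high)"`
#' layout; frequencies keep five decimals.  Statistics are stored at full
#' precision in the underlying `assoc_table` -- formatting happens only
#' here.
#'
#' @param x an `assoc_table` from [run_locus()].
#' @return a character data frame ready for printing or TSV export.
#' @export
format_assoc <- function(x) {
  stopifnot(is.data.frame(x))
  data.frame(
    allele = x$allele,
    freq_case = sprintf("%.5f", x$freq_case),
    freq_control = sprintf("%.5f", x$freq_control),
    chi2 = sprintf("%.3f", x$chi2),
    p_chi2 = format_pvalue(x$p_chi2),
    p_fisher = format_pvalue(x$p_fisher),
    or_ci = format_or_ci(x$or, x$ci_low, x$ci_high),
    p_corrected = format_pvalue(x$p_corrected),
    asr = sprintf("%+.2f", x$asr),
    stringsAsFactors = FALSE
  )
}

#' Count-level association analysis over a set of loci
#'
#' Runs [run_locus()] for every count table and (optionally) writes one
#' TSV per locus plus a full-precision JSON.  This is the stage available
#' in "fixture mode", when only pre-tabulated counts -- not
#' individual-level genotypes -- are at hand; genotype-level stages
#' (Hardy-Weinberg, LD, haplotypes) need [run_hla_analysis()].
#'
#' @param count_tables named list of [allele_counts()] tables.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param yates passed to [run_locus()].
#' @return named list of `assoc_table`s, invisibly if writing.
#' @export
run_count_analysis <- function(count_tables, out_dir = NULL, yates = FALSE) {
  stopifnot(is.list(count_tables), length(count_tables) >= 1)
  res <- lapply(count_tables, run_locus, yates = yates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (loc in names(res)) {
      utils::write.table(as.data.frame(res[[loc]]),
                         file.path(out_dir, sprintf("assoc_%s.tsv", loc)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(res, function(r) as.data.frame(r)),
      file.path(out_dir, "assoc_full_precision.json"),
      digits = NA, auto_unbox = TRUE)
    writeLines(paste("Hardy-Weinberg, LD and haplotype stages skipped:",
                     "they require genotype-level input, not count tables"),
               file.path(out_dir, "SKIPPED_STAGES.txt"))
    return(invisible(res))
  }
  res
}

#' Full HLA case-control analysis from genotype-level cohorts
#'
#' Orchestrates every stage: per-locus gene counting and association
#' statistics, Monte-Carlo Hardy-Weinberg testing in the control group,
#' pairwise LD matrices per group, and (when all four Class II loci are
#' typed) DRB1~DQA1~DQB1~DPB1 haplotype estimation with case-control
#' haplotype association.  Writes per-stage TSVs and a JSON run manifest
#' recording settings, seed and output checksums; identical inputs,
#' settings and seed give identical manifests.
#'
#' @param cases,controls `hla_cohort` objects.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param loci loci to analyse (default: loci typed in both cohorts).
#' @param yates Yates' continuity correction for the chi-square
#'   (default `FALSE`).
#' @param ld_weighting `"frequency"` or `"uniform"` (see [ld_pair()]).
#' @param hwe_replicates Monte-Carlo replicates for the Hardy-Weinberg
#'   test.
#' @param seed seed for the Hardy-Weinberg permutations.
#' @param alpha significance level recorded in the manifest (default 0.05).
#' @param haplotype_loci loci for the haplotype stage (default: the Class
#'   II block DRB1, DQA1, DQB1, DPB1 when fully typed, else skipped).
#' @return list with components `assoc` (per-locus `assoc_table`s), `hwe`
#'   (data frame of control-group results), `ld` (per-group `ld_matrix`),
#'   `haplotypes` (list with `case`, `control`, `assoc` or `NULL`) and
#'   `manifest`.
#' @export
run_hla_analysis <- function(cases, controls, out_dir = NULL,
                             loci = NULL, yates = FALSE,
                             ld_weighting = c("frequency", "uniform"),
                             hwe_replicates = 10000L, seed = 1L,
                             alpha = 0.05, haplotype_loci = NULL) {
  stopifnot(inherits(cases, "hla_cohort"), inherits(controls, "hla_cohort"),
            alpha > 0, alpha < 1)
  ld_weighting <- match.arg(ld_weighting)
  if (is.null(loci)) {
    loci <- intersect(attr(cases, "loci"), attr(controls, "loci"))
  }
  if (length(loci) == 0L) stop("no shared loci", call. = FALSE)

  counts <- lapply(stats::setNames(loci, loci), function(loc) {
    count_alleles(cases, controls, loc)
  })
  assoc <- lapply(counts, function(ct) {
    if (nrow(ct) >= 2) run_locus(ct, yates = yates) else NULL
  })
  assoc <- Filter(Negate(is.null), assoc)

  hwe <- do.call(rbind, lapply(seq_along(loci), function(i) {
    g <- genotype_counts(controls, loci[i])
    r <- suppressWarnings(
      hwe_exact_mc(g, n_replicates = hwe_replicates, seed = seed + i))
    data.frame(locus = r$locus, n_individuals = r$n_individuals,
               n_alleles = r$n_alleles, p_value = r$p_value,
               n_replicates = r$n_replicates, seed = r$seed,
               stringsAsFactors = FALSE)
  }))

  ld <- NULL
  if (length(loci) >= 2) {
    ld <- list(case = ld_matrix(cases, loci, weighting = ld_weighting),
               control = ld_matrix(controls, loci, weighting = ld_weighting))
  }

  if (is.null(haplotype_loci)) {
    class2 <- c("DRB1", "DQA1", "DQB1", "DPB1")
    haplotype_loci <- if (all(class2 %in% loci)) class2 else NULL
  }
  haplotypes <- NULL
  if (!is.null(haplotype_loci) && length(haplotype_loci) >= 2) {
    hf_ca <- em_haplotypes(cases, haplotype_loci)
    hf_co <- em_haplotypes(controls, haplotype_loci)
    haplotypes <- list(
      case = hf_ca, control = hf_co,
      assoc = haplotype_assoc(hf_ca, hf_co,
                              case_2n = 2 * attr(hf_ca, "n_records"),
                              control_2n = 2 * attr(hf_co, "n_records")))
  }

  manifest <- list(
    package = "hlacc",
    package_version = as.character(utils::packageVersion("hlacc")),
    settings = list(loci = loci, yates = yates, ld_weighting = ld_weighting,
                    hwe_replicates = hwe_replicates, seed = seed,
                    alpha = alpha,
                    haplotype_loci = haplotype_loci),
    n_cases = nrow(cases), n_controls = nrow(controls)
  )

  out <- list(assoc = assoc, hwe = hwe, ld = ld, haplotypes = haplotypes,
              manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character(0)
  for (loc in names(run$assoc)) {
    files <- c(files, tsv(as.data.frame(run$assoc[[loc]]),
                          sprintf("assoc_%s.tsv", loc)))
  }
  files <- c(files, tsv(run$hwe, "hwe_controls.tsv"))
  if (!is.null(run$ld)) {
    for (grp in names(run$ld)) {
      m <- run$ld[[grp]]
      files <- c(files,
                 tsv(cbind(locus = m$loci, as.data.frame(m$dprime)),
                     sprintf("ld_dprime_%s.tsv", grp)),
                 tsv(cbind(locus = m$loci, as.data.frame(m$rsq)),
                     sprintf("ld_rsq_%s.tsv", grp)))
    }
  }
  if (!is.null(run$haplotypes)) {
    files <- c(files, tsv(as.data.frame(run$haplotypes$assoc),
                          "haplotype_assoc.tsv"))
  } else {
    writeLines(paste("haplotype stage skipped: needs >= 2 haplotype loci",
                     "typed in both groups (default: the full Class II",
                     "block DRB1/DQA1/DQB1/DPB1)"),
               file.path(out_dir, "SKIPPED_STAGES.txt"))
  }
  run$manifest$outputs <- as.list(tools::md5sum(sort(files)))
  names(run$manifest$outputs) <- basename(sort(files))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
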