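#' Construct a cohort of unphased HLA genotypes
#'
#' A cohort is a data frame with one row per individual: a `sample_id`
#' column plus two allele columns per locus named `<locus>_1` and
#' `<locus>_2` (e.g. `A_1`, `A_2`).  Genotypes are unphased and unordered;
#' homozygotes repeat the allele.  A locus is either fully typed (both
#' columns non-missing) or fully missing for an individual -- half-missing
#' genotypes are rejected, so chromosome denominators are always even.
#'
#' @param df data frame with `sample_id` and paired allele columns.
#' @param group group label for the whole cohort, `"case"` or `"control"`.
#' @param loci character vector of loci to keep; defaults to every locus
#'   with a complete column pair in `df`, in chromosomal order.
#' @return an object of class `hla_cohort`: the validated data frame with
#'   attributes `loci` and `group`.
#' @seealso [read_cohort()], [count_alleles()], [genotype_counts()]
#' @export
hla_cohort <- function(df, group = c("case", "control"), loci = NULL) {
  group <- match.arg(group)
  stopifnot(is.data.frame(df), "sample_id" %in% names(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(loci)) {
    have <- sub("_1$", "", grep("_1$", names(df), value = TRUE))
    loci <- intersect(hla_loci(), have)
    extra <- setdiff(have, hla_loci())
    loci <- c(loci, extra)  # non-standard loci kept, after the canonical ones
  }
  if (length(loci) == 0L) stop("no locus columns found", call. = FALSE)
  for (loc in loci) {
    c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
    if (!all(c(c1, c2) %in% names(df))) {
      stop(sprintf("missing column pair for locus %s", loc), call. = FALSE)
    }
    a1 <- blank_to_na(df[[c1]]); a2 <- blank_to_na(df[[c2]])
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) {
      stop(sprintf("half-missing genotype at locus %s for sample(s): %s",
                   loc, paste(df$sample_id[half], collapse = ", ")),
           call. = FALSE)
    }
    for (v in c(a1, a2)) {
      if (!is.na(v) && allele_locus(v) != loc) {
        stop(sprintf("allele '%s' does not belong to locus column %s", v, loc),
             call. = FALSE)
      }
    }
    df[[c1]] <- a1; df[[c2]] <- a2
  }
  keep <- c("sample_id",
            as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))
  df <- df[, keep, drop = FALSE]
  structure(df, loci = loci, group = group,
            class = c("hla_cohort", "data.frame"))
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  trimws(x)
}

#' @export
print.hla_cohort <- function(x, ...) {
  cat(sprintf("<hla_cohort> %d %s individuals; loci: %s\n",
              nrow(x), attr(x, "group"),
              paste(attr(x, "loci"), collapse = ", ")))
  for (loc in attr(x, "loci")) {
    cat(sprintf("  %-5s 2N = %d\n", loc, chromosomes(x, loc)))
  }
  invisible(x)
}

#' Number of typed chromosomes at a locus
#'
#' Twice the number of individuals non-missing at the locus; the
#' denominator of gene-counting allele frequencies.  Missingness is
#' locus-wise: an individual untyped at DRB1 still contributes two
#' chromosomes at HLA-A.
#'
#' @param cohort an `hla_cohort`.
#' @param locus locus name.
#' @return integer.
#' @export
chromosomes <- function(cohort, locus) {
  stopifnot(inherits(cohort, "hla_cohort"))
  if (!locus %in% attr(cohort, "loci")) {
    stop(sprintf("locus %s not typed in this cohort", locus), call. = FALSE)
  }
  2L * sum(!is.na(cohort[[paste0(locus, "_1")]]))
}

#' Read a genotype table from a TSV file
#'
#' Expected layout: a header row with `sample_id`, optionally `group`, and
#' two columns per locus (`A_1`, `A_2`, ...); empty cells denote missing
#' genotypes.  See [write_cohort()] for the inverse.
#'
#' @param path file path.
#' @param group group label to assign (overrides any `group` column).
#' @param loci optional locus subset.
#' @return an `hla_cohort`.
#' @export
read_cohort <- function(path, group = c("case", "control"), loci = NULL) {
  group <- match.arg(group)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  df$group <- NULL
  hla_cohort(df, group = group, loci = loci)
}

#' Write a genotype table to a TSV file
#'
#' @param cohort an `hla_cohort`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hla_cohort"))
  df <- as.data.frame(cohort)
  df <- cbind(sample_id = df$sample_id,
              group = attr(cohort, "group"),
              df[, setdiff(names(df), "sample_id"), drop = FALSE])
  df[is.na(df)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-locus allele counts by direct gene counting
#'
#' Counts, for each allele observed in either group, the number of case and
#' control chromosomes carrying it (homozygotes contribute two).  Alleles
#' present in only one group are retained with a zero count in the other --
#' zero-frequency cells carry the strongest association signals at HLA loci
#' and must not be dropped.
#'
#' @param cases,controls `hla_cohort` objects.
#' @param locus locus to count.
#' @return an object of class `allele_counts`: data frame with columns
#'   `allele`, `case_count`, `control_count`, plus attributes `locus`,
#'   `case_total` and `control_total` (typed chromosomes per group).
#' @examples
#' sim <- simulate_cohorts(synth_config(
#'   n_cases = 30, n_controls = 50,
#'   allele_freqs = list(A = list(case = c("A*01:01" = 0.5, "A*02:01" = 0.5),
#'                                control = c("A*01:01" = 0.2, "A*02:01" = 0.8))),
#'   seed = 1))
#' count_alleles(sim$cases, sim$controls, "A")
#' @export
count_alleles <- function(cases, controls, locus) {
  stopifnot(inherits(cases, "hla_cohort"), inherits(controls, "hla_cohort"))
  in_ca <- locus %in% attr(cases, "loci")
  in_co <- locus %in% attr(controls, "loci")
  if (!in_ca && !in_co) {
    stop(sprintf("locus %s typed in neither cohort", locus), call. = FALSE)
  }
  pool <- function(cohort) {
    if (!locus %in% attr(cohort, "loci")) return(character(0))
    a <- c(cohort[[paste0(locus, "_1")]], cohort[[paste0(locus, "_2")]])
    a[!is.na(a)]
  }
  ca <- pool(cases); co <- pool(controls)
  alleles <- sort(unique(c(ca, co)))
  allele_counts(
    locus = locus,
    allele = alleles,
    case_count = as.integer(table(factor(ca, levels = alleles))),
    control_count = as.integer(table(factor(co, levels = alleles))),
    case_total = length(ca),
    control_total = length(co)
  )
}

#' Construct an allele count table directly
#'
#' The unit of association testing: per-allele chromosome counts for two
#' groups with their chromosome totals.  Usually produced by
#' [count_alleles()] or [table_fixtures()]; this constructor is for
#' pre-tabulated counts.
#'
#' @param locus locus name.
#' @param allele character vector of allele names.
#' @param case_count,control_count non-negative integer vectors.
#' @param case_total,control_total positive chromosome totals (2N).
#' @return an `allele_counts` object.
#' @export
allele_counts <- function(locus, allele, case_count, control_count,
                          case_total, control_total) {
  stopifnot(length(allele) == length(case_count),
            length(allele) == length(control_count),
            all(case_count >= 0), all(control_count >= 0),
            case_total > 0, control_total > 0)
  if (sum(case_count) > case_total || sum(control_count) > control_total) {
    stop("allele counts exceed chromosome total", call. = FALSE)
  }
  if (anyDuplicated(allele)) stop("duplicate allele rows", call. = FALSE)
  for (a in allele) {
    if (allele_locus(a) != locus) {
      stop(sprintf("allele '%s' does not belong to locus %s", a, locus),
           call. = FALSE)
    }
  }
  structure(
    data.frame(allele = allele,
               case_count = as.numeric(case_count),
               control_count = as.numeric(control_count),
               stringsAsFactors = FALSE),
    locus = locus,
    case_total = as.numeric(case_total),
    control_total = as.numeric(control_total),
    class = c("allele_counts", "data.frame")
  )
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> locus %s: %d alleles; 2N = %g cases / %g controls\n",
              attr(x, "locus"), nrow(x),
              attr(x, "case_total"), attr(x, "control_total")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write an allele count table as TSV
#'
#' Format: a `#` comment line carrying the chromosome totals, then
#' `locus<TAB>allele<TAB>case_count<TAB>control_count`.
#'
#' @param counts an `allele_counts` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# locus=%s case_total=%g control_total=%g",
                     attr(counts, "locus"),
                     attr(counts, "case_total"), attr(counts, "control_total")),
             con)
  writeLines("locus\tallele\tcase_count\tcontrol_count", con)
  writeLines(sprintf("%s\t%s\t%g\t%g", attr(counts, "locus"),
                     counts$allele, counts$case_count, counts$control_count),
             con)
  invisible(path)
}

#' Read an allele count table written by [write_count_table()]
#'
#' @param path file path.
#' @return an `allele_counts` object.
#' @export
read_count_table <- function(path) {
  hdr <- readLines(path, n = 1L, encoding = "UTF-8")
  m <- regexec("^# locus=(\\S+) case_total=(\\S+) control_total=(\\S+)$", hdr)
  g <- regmatches(hdr, m)[[1]]
  if (length(g) == 0L) stop("missing totals header comment", call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, skip = 1L,
                          colClasses = c("character", "character",
                                         "numeric", "numeric"),
                          fileEncoding = "UTF-8")
  allele_counts(locus = g[2], allele = df$allele,
                case_count = df$case_count, control_count = df$control_count,
                case_total = as.numeric(g[3]), control_total = as.numeric(g[4]))
}

#' Unordered genotype counts at one locus
#'
#' Tabulates unordered allele pairs (genotypes) for one cohort at one
#' locus; the input to the Hardy-Weinberg exact test.  Pair keys are
#' `"a1/a2"` with the two names in sorted order.
#'
#' @param cohort an `hla_cohort`.
#' @param locus locus name.
#' @return an object of class `genotype_counts`: data frame with columns
#'   `allele1`, `allele2`, `count`, and attributes `locus` and
#'   `n_individuals`.
#' @export
genotype_counts <- function(cohort, locus) {
  stopifnot(inherits(cohort, "hla_cohort"))
  if (!locus %in% attr(cohort, "loci")) {
    stop(sprintf("locus %s not typed in this cohort", locus), call. = FALSE)
  }
  a1 <- cohort[[paste0(locus, "_1")]]
  a2 <- cohort[[paste0(locus, "_2")]]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(a1) == 0L) {
    stop(sprintf("no typed individuals at locus %s", locus), call. = FALSE)
  }
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  key <- paste(lo, hi, sep = "/")
  tab <- table(key)
  parts <- strsplit(names(tab), "/", fixed = TRUE)
  structure(
    data.frame(allele1 = vapply(parts, `[`, "", 1L),
               allele2 = vapply(parts, `[`, "", 2L),
               count = as.integer(tab),
               stringsAsFactors = FALSE),
    locus = locus,
    n_individuals = length(a1),
    class = c("genotype_counts", "data.frame")
  )
}
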