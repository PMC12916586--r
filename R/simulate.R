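#' Configuration for the synthetic-cohort simulator
#'
#' Defines a two-group cohort draw.  Exactly one of `allele_freqs`
#' (independent loci: per-group, per-locus allele frequency vectors) or
#' `haplotype_freqs` (per-group multi-locus haplotype frequency vectors,
#' which fixes the LD ground truth) must be given; the two modes are
#' mutually exclusive so the simulated LD structure is unambiguous.
#'
#' Under `hwe_mode = "random_mating"` each individual's two allele copies
#' (or haplotypes) are i.i.d. draws from the group frequency vector, so
#' genotypes follow Hardy-Weinberg proportions.  Under `"two_subpop_mix"`
#' each individual is drawn from one of two subpopulations whose allele
#' frequencies diverge from the nominal vector by a factor `1 +/-
#' divergence` (alternating sign across alleles, renormalized); mixing
#' proportion `mix_fraction`.  This produces the Wahlund heterozygote
#' deficit of cryptic population stratification.  For a two-allele locus at
#' (0.5, 0.5) with `divergence = 0.8`, the subpopulations sit at (0.9, 0.1)
#' and (0.1, 0.9).
#'
#' @param n_cases,n_controls individuals per group.
#' @param allele_freqs list `locus -> list(case = named vector, control =
#'   named vector)`; names are allele names of that locus, frequencies sum
#'   to 1.
#' @param haplotype_freqs list with `loci` (character vector) and `case` /
#'   `control` named vectors whose names are `"allele1~allele2~..."`
#'   haplotype labels.
#' @param hwe_mode `"random_mating"` or `"two_subpop_mix"`.
#' @param mix_fraction,divergence subpopulation mixing parameters (used
#'   only under `"two_subpop_mix"`).
#' @param missing_rate scalar or named-per-locus Bernoulli rate of
#'   whole-genotype missingness (never half-missing), applied per
#'   (individual, locus).
#' @param seed integer seed; the draw is fully deterministic given it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cases, n_controls,
                         allele_freqs = NULL, haplotype_freqs = NULL,
                         hwe_mode = c("random_mating", "two_subpop_mix"),
                         mix_fraction = 0.5, divergence = 0,
                         missing_rate = 0, seed = 1L) {
  hwe_mode <- match.arg(hwe_mode)
  stopifnot(n_cases >= 1, n_controls >= 1,
            xor(is.null(allele_freqs), is.null(haplotype_freqs)),
            mix_fraction >= 0, mix_fraction <= 1,
            divergence >= 0, divergence < 1,
            all(missing_rate >= 0), all(missing_rate < 1))
  check_fv <- function(v, what) {
    if (is.null(names(v)) || any(!nzchar(names(v)))) {
      stop(what, ": frequency vectors must be named", call. = FALSE)
    }
    if (abs(sum(v) - 1) > 1e-9) {
      stop(what, ": frequencies must sum to 1", call. = FALSE)
    }
    if (any(v < 0)) stop(what, ": negative frequency", call. = FALSE)
  }
  if (!is.null(allele_freqs)) {
    for (loc in names(allele_freqs)) {
      for (grp in c("case", "control")) {
        v <- allele_freqs[[loc]][[grp]]
        check_fv(v, paste(loc, grp))
        for (a in names(v)) {
          if (allele_locus(a) != loc) {
            stop(sprintf("allele '%s' does not belong to locus %s", a, loc),
                 call. = FALSE)
          }
        }
      }
    }
    loci <- names(allele_freqs)
  } else {
    loci <- haplotype_freqs$loci
    stopifnot(length(loci) >= 1)
    for (grp in c("case", "control")) check_fv(haplotype_freqs[[grp]], grp)
  }
  structure(list(n_cases = n_cases, n_controls = n_controls, loci = loci,
                 allele_freqs = allele_freqs,
                 haplotype_freqs = haplotype_freqs,
                 hwe_mode = hwe_mode, mix_fraction = mix_fraction,
                 divergence = divergence, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# split a frequency vector into two divergent subpopulation vectors:
# alternating +/- relative shifts of size `divergence`, renormalized
subpop_freqs <- function(v, divergence) {
  s <- rep_len(c(1, -1), length(v))
  f1 <- v * (1 + divergence * s); f1 <- f1 / sum(f1)
  f2 <- v * (1 - divergence * s); f2 <- f2 / sum(f2)
  list(f1, f2)
}

#' Simulate case and control cohorts
#'
#' Draws both groups per the configuration (see [synth_config()] for the
#' generative model) and returns them as standard genotype cohorts, so
#' every downstream stage -- gene counting, association, Hardy-Weinberg
#' testing, EM haplotype estimation -- can be validated against known
#' truth.  Byte-identical output for a fixed config and seed; the caller's
#' RNG state is untouched.
#'
#' @param config a `synth_config`.
#' @return list with elements `cases` and `controls`, each an `hla_cohort`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(config$seed)
  cases <- simulate_group(config, "case", config$n_cases)
  controls <- simulate_group(config, "control", config$n_controls)
  list(cases = hla_cohort(cases, group = "case", loci = config$loci),
       controls = hla_cohort(controls, group = "control", loci = config$loci))
}

simulate_group <- function(config, grp, n) {
  loci <- config$loci
  draw_pair <- function(v) {
    # two allele copies for n individuals from one frequency vector
    if (config$hwe_mode == "two_subpop_mix" && config$divergence > 0) {
      sub <- subpop_freqs(v, config$divergence)
      which_pop <- stats::rbinom(n, 1L, config$mix_fraction) + 1L
      a1 <- character(n); a2 <- character(n)
      for (p in 1:2) {
        idx <- which(which_pop == p)
        if (length(idx)) {
          a1[idx] <- sample(names(v), length(idx), TRUE, prob = sub[[p]])
          a2[idx] <- sample(names(v), length(idx), TRUE, prob = sub[[p]])
        }
      }
      cbind(a1, a2)
    } else {
      cbind(sample(names(v), n, TRUE, prob = v),
            sample(names(v), n, TRUE, prob = v))
    }
  }
  df <- data.frame(sample_id = sprintf("%s_%04d", grp, seq_len(n)),
                   stringsAsFactors = FALSE)
  if (!is.null(config$allele_freqs)) {
    for (loc in loci) {
      pr <- draw_pair(config$allele_freqs[[loc]][[grp]])
      df[[paste0(loc, "_1")]] <- pr[, 1]
      df[[paste0(loc, "_2")]] <- pr[, 2]
    }
  } else {
    v <- config$haplotype_freqs[[grp]]
    h1 <- sample(names(v), n, TRUE, prob = v)
    h2 <- sample(names(v), n, TRUE, prob = v)
    s1 <- strsplit(h1, "~", fixed = TRUE)
    s2 <- strsplit(h2, "~", fixed = TRUE)
    for (l in seq_along(loci)) {
      df[[paste0(loci[l], "_1")]] <- vapply(s1, `[`, "", l)
      df[[paste0(loci[l], "_2")]] <- vapply(s2, `[`, "", l)
    }
  }
  mr <- config$missing_rate
  if (any(mr > 0)) {
    mr <- if (length(mr) == 1L) stats::setNames(rep(mr, length(loci)), loci) else mr
    for (loc in loci) {
      drop <- stats::runif(n) < mr[[loc]]
      df[[paste0(loc, "_1")]][drop] <- NA_character_
      df[[paste0(loc, "_2")]][drop] <- NA_character_
    }
  }
  df
}

#' Simulate cohorts whose expected frequencies match a fixture locus
#'
#' Uses the reconstructed count-table frequencies of one locus as the
#' generative truth for a random-mating draw.  Group sizes default to the
#' chromosome totals behind the fixture (91 or 90 cases, 350 controls); the
#' unlisted remainder of each frequency vector (listed frequencies sum to
#' slightly below 1 at some loci) is carried by a synthetic filler allele
#' `<locus>*00:00` so that every listed allele's expected frequency equals
#' its fixture value exactly.
#'
#' @param locus fixture locus name.
#' @param seed integer seed.
#' @param n_cases,n_controls optional overrides of the group sizes.
#' @return list with `cases` and `controls` cohorts.
#' @export
simulate_from_fixture <- function(locus, seed = 1L,
                                  n_cases = NULL, n_controls = NULL) {
  fx <- table_fixtures()
  if (!locus %in% names(fx)) stop("no fixture for locus ", locus, call. = FALSE)
  t <- fx[[locus]]
  mk <- function(count, total) {
    v <- stats::setNames(count / total, t$allele)
    rem <- 1 - sum(v)
    if (rem > 1e-12) v <- c(v, stats::setNames(rem, paste0(locus, "*00:00")))
    v
  }
  cfg <- synth_config(
    n_cases = if (is.null(n_cases)) attr(t, "case_total") / 2 else n_cases,
    n_controls = if (is.null(n_controls)) attr(t, "control_total") / 2 else n_controls,
    allele_freqs = stats::setNames(list(list(
      case = mk(t$case_count, attr(t, "case_total")),
      control = mk(t$control_count, attr(t, "control_total")))), locus),
    seed = seed
  )
  simulate_cohorts(cfg)
}
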