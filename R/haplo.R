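#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies over a set of loci, obtained by
#' expectation-maximization over the phase-consistent resolutions of each
#' individual's unphased multi-locus genotype (the classical gene-counting
#' EM for multi-locus data).  The E-step distributes each individual's unit
#' mass over its compatible haplotype pairs in proportion to the current
#' pair probabilities (`2 f_i f_j` for distinct haplotypes, `f_i^2` for a
#' double dose); the M-step re-estimates frequencies from the expected
#' haplotype counts divided by `2n`.  Iteration stops when the relative
#' log-likelihood change drops below `tol`.
#'
#' Initialization is the product of observed single-locus allele
#' frequencies, which breaks the symmetry between equivalent phase
#' resolutions deterministically; a uniform initialization is available for
#' likelihood-surface checks.  The log-likelihood is non-decreasing at
#' every EM iteration; the full trace is returned.
#'
#' @param cohort an `hla_cohort`.
#' @param loci loci to phase (2 or more, at most 7); individuals missing
#'   any of them are excluded.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap; hitting it flags `converged = FALSE`
#'   rather than raising an error.
#' @param init `"product"` (default) or `"uniform"`.
#' @param prune haplotypes with final frequency below this are dropped
#'   (default 1e-10).
#' @return a `haplo_freqs` object: data frame with one column per locus
#'   plus `freq`, sorted by decreasing frequency; attributes `loci`,
#'   `loglik`, `trace`, `n_iter`, `converged`, `n_records`.
#' @export
em_haplotypes <- function(cohort, loci, tol = 1e-8, max_iter = 1000L,
                          init = c("product", "uniform"), prune = 1e-10) {
  stopifnot(inherits(cohort, "hla_cohort"), length(loci) >= 2, length(loci) <= 7)
  init <- match.arg(init)
  missing_loci <- setdiff(loci, attr(cohort, "loci"))
  if (length(missing_loci)) {
    stop("loci not typed in cohort: ", paste(missing_loci, collapse = ", "),
         call. = FALSE)
  }
  geno <- lapply(loci, function(loc) {
    cbind(cohort[[paste0(loc, "_1")]], cohort[[paste0(loc, "_2")]])
  })
  complete <- Reduce(`&`, lapply(geno, function(g) !is.na(g[, 1])))
  n <- sum(complete)
  if (n == 0L) stop("no records typed at all requested loci", call. = FALSE)
  geno <- lapply(geno, function(g) g[complete, , drop = FALSE])

  # per-individual phase expansions; identical genotypes share one entry
  key <- do.call(paste, c(lapply(geno, function(g) {
    paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]), sep = "|")
  }), sep = "||"))
  uniq <- !duplicated(key)
  weight <- as.vector(table(key)[key[uniq]])
  expansions <- lapply(which(uniq), function(i) {
    phase_expand(lapply(geno, function(g) g[i, ]))
  })

  haps <- sort(unique(unlist(expansions)))
  H <- length(haps)
  exp_idx <- lapply(expansions, function(e) {
    matrix(match(e, haps), ncol = 2)
  })

  f <- switch(init,
    uniform = rep(1 / H, H),
    product = {
      margins <- lapply(seq_along(loci), function(l) {
        a <- as.vector(geno[[l]])
        tab <- table(a) / length(a)
        tab
      })
      parts <- strsplit(haps, "~", fixed = TRUE)
      v <- vapply(parts, function(p) {
        prod(vapply(seq_along(loci), function(l) {
          as.numeric(margins[[l]][p[l]])
        }, numeric(1)))
      }, numeric(1))
      v / sum(v)
    })
  # deterministic symmetry-breaking: exactly tied phase resolutions (e.g. a
  # single double-heterozygote) make the all-equal point an EM fixed point;
  # a small ordered perturbation pushes the iteration off the saddle toward
  # a maximum, reproducibly and without randomness.  The ramp is quadratic
  # in the haplotype index because a linear ramp cancels to first order
  # between complementary phase pairs (their index sums coincide).
  f <- f * (1 + 1e-3 * (seq_len(H) / H)^2)
  f <- f / sum(f)

  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(H)
    ll <- 0
    for (u in seq_along(exp_idx)) {
      idx <- exp_idx[[u]]
      w <- f[idx[, 1]] * f[idx[, 2]] * ifelse(idx[, 1] == idx[, 2], 1, 2)
      s <- sum(w)
      if (s <= 0) {                       # degenerate start: fall back flat
        w <- rep(1, nrow(idx)); s <- sum(w)
        ll <- ll + weight[u] * log(.Machine$double.xmin)
      } else {
        ll <- ll + weight[u] * log(s)
      }
      post <- weight[u] * w / s
      for (r in seq_len(nrow(idx))) {
        counts[idx[r, 1]] <- counts[idx[r, 1]] + post[r]
        counts[idx[r, 2]] <- counts[idx[r, 2]] + post[r]
      }
    }
    f <- counts / (2 * n)
    trace <- c(trace, ll)
    if (is.finite(loglik) &&
        abs(ll - loglik) < tol * max(1, abs(loglik))) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
    if (iter >= max_iter) break
  }

  keep <- f > prune
  parts <- strsplit(haps[keep], "~", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- loci
  out$freq <- f[keep] / sum(f[keep])
  out <- out[order(-out$freq, do.call(paste, out[loci])), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, loci = loci, loglik = loglik, trace = trace,
            n_iter = iter, converged = converged, n_records = n,
            class = c("haplo_freqs", "data.frame"))
}

# all phase-consistent haplotype pairs for one multi-locus genotype;
# genotype = list of length-2 allele vectors, one per locus.
# 2^(h-1) unordered pairs for h heterozygous loci (1 pair if h == 0).
phase_expand <- function(genotype) {
  het <- vapply(genotype, function(g) g[1] != g[2], logical(1))
  h <- sum(het)
  if (h > 20) stop("phase expansion too large (> 20 heterozygous loci)",
                   call. = FALSE)
  L <- length(genotype)
  if (h <= 1) {
    h1 <- vapply(genotype, `[`, "", 1L)
    h2 <- vapply(genotype, `[`, "", 2L)
    return(matrix(c(paste(h1, collapse = "~"), paste(h2, collapse = "~")),
                  ncol = 2))
  }
  free <- which(het)[-1]                  # first het locus pinned: unordered pairs
  combos <- as.matrix(expand.grid(rep(list(c(1L, 2L)), length(free))))
  pairs <- matrix("", nrow = nrow(combos), ncol = 2)
  for (r in seq_len(nrow(combos))) {
    pick <- rep(1L, L)
    pick[free] <- combos[r, ]
    h1 <- vapply(seq_len(L), function(l) genotype[[l]][pick[l]], "")
    h2 <- vapply(seq_len(L), function(l) genotype[[l]][3L - pick[l]], "")
    pairs[r, ] <- c(paste(h1, collapse = "~"), paste(h2, collapse = "~"))
  }
  pairs
}

#' @export
print.haplo_freqs <- function(x, ...) {
  cat(sprintf("<haplo_freqs> %s: %d haplotypes from %d records; loglik %.4f (%d iterations%s)\n",
              paste(attr(x, "loci"), collapse = "~"), nrow(x),
              attr(x, "n_records"), attr(x, "loglik"), attr(x, "n_iter"),
              if (attr(x, "converged")) "" else ", NOT converged"))
  print.data.frame(head(as.data.frame(x), 20), row.names = FALSE)
  if (nrow(x) > 20) cat("  ...", nrow(x) - 20, "more\n")
  invisible(x)
}

#' Pairwise multi-allelic linkage disequilibrium summaries
#'
#' From a two-locus haplotype frequency table, computes for every allele
#' pair `(i, j)`: `D_ij = p_ij - p_i q_j`; the normalized
#' `D'_ij = D_ij / D_max` with `D_max = min(p_i q_j, (1-p_i)(1-q_j))` when
#' `D_ij < 0` and `min(p_i (1-q_j), (1-p_i) q_j)` otherwise; and
#' `r2_ij = D_ij^2 / (p_i (1-p_i) q_j (1-q_j))`.  The locus-pair summary is
#' the frequency-weighted sum `sum(p_i q_j |D'_ij|)` (the standard
#' multi-allelic definition) or the unweighted mean over allele pairs, and
#' analogously for r-squared.
#'
#' @param freq2 a `haplo_freqs` over exactly two loci.
#' @param weighting `"frequency"` (default) or `"uniform"`.
#' @return named numeric vector `(dprime, rsq)`; `NA` if either locus is
#'   monomorphic.
#' @export
ld_pair <- function(freq2, weighting = c("frequency", "uniform")) {
  stopifnot(inherits(freq2, "haplo_freqs"), length(attr(freq2, "loci")) == 2)
  weighting <- match.arg(weighting)
  loci <- attr(freq2, "loci")
  a1 <- freq2[[loci[1]]]; a2 <- freq2[[loci[2]]]; fr <- freq2$freq
  al1 <- sort(unique(a1)); al2 <- sort(unique(a2))
  p <- vapply(al1, function(a) sum(fr[a1 == a]), numeric(1))
  q <- vapply(al2, function(a) sum(fr[a2 == a]), numeric(1))
  if (length(al1) < 2 || length(al2) < 2) {
    return(c(dprime = NA_real_, rsq = NA_real_))
  }
  dp_num <- dp_den <- r2_num <- r2_den <- 0
  for (i in seq_along(al1)) {
    for (j in seq_along(al2)) {
      pij <- sum(fr[a1 == al1[i] & a2 == al2[j]])
      D <- pij - p[i] * q[j]
      dmax <- if (D < 0) {
        min(p[i] * q[j], (1 - p[i]) * (1 - q[j]))
      } else {
        min(p[i] * (1 - q[j]), (1 - p[i]) * q[j])
      }
      dprime <- if (dmax > 0) abs(D) / dmax else 0
      r2 <- D^2 / (p[i] * (1 - p[i]) * q[j] * (1 - q[j]))
      w <- if (weighting == "frequency") p[i] * q[j] else 1
      dp_num <- dp_num + w * dprime
      dp_den <- dp_den + w
      r2_num <- r2_num + w * r2
      r2_den <- r2_den + w
    }
  }
  c(dprime = min(dp_num / dp_den, 1), rsq = min(r2_num / r2_den, 1))
}

#' Pairwise LD matrix across HLA loci
#'
#' Runs the two-locus EM for every locus pair and fills symmetric matrices
#' of mean |D'| and mean r-squared, with unit diagonal by convention.  Loci
#' are ordered chromosomally (A, C, B, DRB1, DQA1, DQB1, DPB1), matching
#' the physical gene order on 6p21.
#'
#' @param cohort an `hla_cohort`.
#' @param loci loci to include (at least two); reordered chromosomally.
#' @param weighting passed to [ld_pair()].
#' @param ... passed to [em_haplotypes()].
#' @return an `ld_matrix` object: list with symmetric matrices `dprime`
#'   and `rsq`, plus `loci` and the cohort `group` label.
#' @export
ld_matrix <- function(cohort, loci = attr(cohort, "loci"),
                      weighting = c("frequency", "uniform"), ...) {
  stopifnot(inherits(cohort, "hla_cohort"), length(loci) >= 2)
  weighting <- match.arg(weighting)
  loci <- c(intersect(hla_loci(), loci), setdiff(loci, hla_loci()))
  L <- length(loci)
  dp <- rs <- matrix(1, L, L, dimnames = list(loci, loci))
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      fr <- em_haplotypes(cohort, loci[c(i, j)], ...)
      v <- ld_pair(fr, weighting = weighting)
      dp[i, j] <- dp[j, i] <- v[["dprime"]]
      rs[i, j] <- rs[j, i] <- v[["rsq"]]
    }
  }
  structure(list(loci = loci, dprime = dp, rsq = rs,
                 group = attr(cohort, "group"), weighting = weighting),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %s group, %s-weighted mean |D'|:\n",
              x$group, x$weighting))
  print(round(x$dprime, 3))
  invisible(x)
}

#' Case-control association of EM-estimated haplotypes
#'
#' For every haplotype present in either group, forms the 2x2 table of
#' expected chromosome counts (`freq x 2n` per group, fractional counts
#' allowed) against all other haplotypes, then applies the same machinery
#' as the per-allele analysis: Haldane-Anscombe zero-cell correction,
#' Pearson chi-square, Woolf odds ratio with 95% CI, and the Sidak-type
#' correction with `n` = number of haplotypes tested.  Because phase
#' uncertainty is not propagated, results are approximate; haplotypes whose
#' expected count falls below 5 in either group are flagged
#' (`em_unstable`), since zero-frequency cells destabilize
#' maximum-likelihood haplotype estimation.
#'
#' @param case_freqs,control_freqs `haplo_freqs` over the same loci.
#' @param case_2n,control_2n chromosome counts behind each table.
#' @return data frame with the haplotype allele columns, `freq_case`,
#'   `freq_control`, `chi2`, `p_chi2`, `or`, `ci_low`, `ci_high`,
#'   `p_corrected`, `zero_cell_adjusted`, `em_unstable`; ordered by
#'   descending chi-square.
#' @export
haplotype_assoc <- function(case_freqs, control_freqs, case_2n, control_2n) {
  stopifnot(inherits(case_freqs, "haplo_freqs"),
            inherits(control_freqs, "haplo_freqs"))
  loci <- attr(case_freqs, "loci")
  if (!identical(loci, attr(control_freqs, "loci"))) {
    stop("case and control haplotype tables cover different loci",
         call. = FALSE)
  }
  key <- function(x) do.call(paste, c(x[loci], sep = "~"))
  kc <- key(case_freqs); kk <- key(control_freqs)
  all_h <- sort(unique(c(kc, kk)))
  fc <- stats::setNames(numeric(length(all_h)), all_h)
  fk <- fc
  fc[kc] <- case_freqs$freq
  fk[kk] <- control_freqs$freq
  n_h <- length(all_h)
  rows <- lapply(seq_len(n_h), function(i) {
    a <- fc[i] * case_2n; c_ <- fk[i] * control_2n
    t0 <- two_by_two(a, case_2n - a, c_, control_2n - c_)
    t1 <- haldane_adjust(t0)
    chi2 <- pearson_chi2(t1)
    orci <- odds_ratio_woolf(t1)
    data.frame(haplotype = all_h[i],
               freq_case = fc[i], freq_control = fk[i],
               chi2 = chi2, p_chi2 = chi2_p(chi2),
               or = orci[["or"]], ci_low = orci[["ci_low"]],
               ci_high = orci[["ci_high"]],
               zero_cell_adjusted = attr(t1, "zero_cell_adjusted"),
               em_unstable = a < 5 || c_ < 5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- locus_correct(out$p_chi2, n_h)
  parts <- strsplit(out$haplotype, "~", fixed = TRUE)
  hcols <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(hcols) <- loci
  out <- cbind(hcols, out[, setdiff(names(out), "haplotype")])
  out <- out[order(-out$chi2, do.call(paste, hcols)), ]
  rownames(out) <- NULL
  structure(out, loci = loci, n_haplotypes = n_h,
            class = c("haplo_assoc", "data.frame"))
}
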