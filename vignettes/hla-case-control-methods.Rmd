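---
title: "Statistical methods for sparse HLA case-control tables"
author: "hlacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for sparse HLA case-control tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacc)
```

## The setting

HLA loci are the most polymorphic genes in the human genome: a few hundred
individuals typed at three-field resolution routinely yield 15–30 distinct
alleles per locus. In a rare-disease case-control design — here, a small
patient cohort against a larger donor-registry control group — most
alleles are uncommon, and some are observed in only one group. These
*zero-frequency cells* are not noise to be discarded: alleles private to
the case group carry the strongest association signals, and the analysis
has to produce finite, interpretable statistics for them.

`hlacc` treats the chromosome, not the individual, as the sampling unit.
Each typed individual contributes two chromosomes per locus (gene
counting); allele frequencies are counts over the `2N` typed chromosomes.
Missingness is handled locus-wise, so per-locus denominators differ when
some individuals are untyped at some loci. This is why
`count_alleles()` always derives totals from the data rather than from a
headline sample size.

## Per-allele association

For each allele at a locus, the carrier/non-carrier chromosome counts form
a 2×2 table `(a, b, c, d)` (cases then controls). The pipeline computes:

* **Pearson chi-square**, closed form
  `N(|ad − bc| − δ)²/((a+b)(c+d)(a+c)(b+d))`, with `δ = N/2` under Yates'
  continuity correction and 0 otherwise. The pipeline default is **Yates
  off**: the statistic is then exactly the classical Pearson statistic, and
  it is the variant the package's regression surface of published sparse
  HLA tables reproduces. The flag exists for users who prefer the
  conservative small-sample convention.
* **Haldane–Anscombe correction**: when any cell is exactly zero, 0.5 is
  added to all four cells before the chi-square and the odds ratio. This is
  an explicit, flagged table transform (`haldane_adjust()`), not a hidden
  fix-up; rows so treated carry `zero_cell_adjusted = TRUE`.
* **Fisher's exact test** (two-sided, minimum-likelihood convention) on the
  *unadjusted* integer table, the appropriate exact complement for sparse
  cells. The chi-square p and Fisher p are reported side by side rather
  than silently switched between, because the two disagree noticeably for
  sparse tables and a reader should see which is which.
* **Woolf interval** for the odds ratio:
  `exp(ln OR ± 1.96 √(1/a + 1/b + 1/c + 1/d))` on the (possibly adjusted)
  table. With a Haldane-adjusted zero cell this yields the familiar very
  large OR with a CI spanning orders of magnitude — wide by construction,
  and honestly so.
* **Locus-wise multiplicity correction** `p_c = 1 − (1 − p)^n` with `n` the
  number of alleles tested at the locus. This is a Šidák-type bound (often
  loosely called Bonferroni in the applied literature); it is monotone in
  both arguments and satisfies `p ≤ p_c ≤ 1` but not `p_c ≤ np`. It is
  evaluated in log space as `-expm1(n log1p(-p))` so that corrected values
  remain accurate when `p` underflows toward 1e-300.
* **Haberman adjusted standardized residuals** over the full alleles ×
  groups table: `ASR = (O − E)/√(E(1 − row prop)(1 − col prop))`.
  Under independence each ASR is approximately standard normal, so
  `|ASR| ≥ 1.96` flags the cells driving a significant table-wide
  chi-square; for a two-column table the case and control residuals of an
  allele are exact negatives. The package follows this formula verbatim;
  its null calibration is checked by simulation (fraction of `|ASR| ≥
  1.96` close to 0.05 under multinomial sampling with all expected counts
  above 50).

Rows are ordered by descending chi-square with a stable tie-break on the
allele name. P-values are stored at full precision; the three-decimal
rendering with a `"<.001"` floor is applied only in `format_assoc()`.

The pipeline reports only these crude (unadjusted) statistics. It does not
fit covariate-adjusted logistic models: individual-level covariates are
outside the package's data model, and in the small-cohort HLA setting an
age/sex-adjusted OR from a near-orthogonal covariate set is numerically
indistinguishable from the crude Woolf estimate. Output columns are
labelled accordingly ("unadjusted (Woolf)").

## Reconstructed count fixtures

`table_fixtures()` rebuilds integer count tables from a published
seven-locus frequency surface (five-decimal allele frequencies for an
aplastic-anemia case group and registry controls). The chromosome totals
are *inferred from the frequency grids*: every control frequency is an
integer multiple of 1/700, and case frequencies at DRB1/DQA1 are multiples
of 1/180 versus 1/182 elsewhere — so the totals are 700 control and 182
(or 180) case chromosomes, and one case was evidently untyped at the two
affected loci. Each frequency times its total must land within 0.02 of an
integer or the builder aborts; the observed worst residual is 0.003. This
integer-reconstruction gate is what justifies using the fixtures as an
exact regression surface for the association statistics.

Two quirks of the source tables are deliberately not chased: a duplicated
pair of rows at the DRB1 locus (the fixture keeps the 23 unique alleles),
and one confidence bound whose printed value is inconsistent with its own
point estimate and lower bound (a digit-level typo; the row is excluded
from the regression surface). Printed crude p-values and ASR magnitudes
from the source tables are likewise not regression targets, as they are
not reproducible from the counts under any standard convention; the
package reports what its formulas give.

## Monte-Carlo exact Hardy–Weinberg test

For a multi-allelic locus with genotype counts `g_ij`, allele counts `m_k`
and `h` heterozygous individuals among `n`, the conditional probability of
the genotype configuration given the allele counts is

    P = n! ∏_k m_k! 2^h / ( (2n)! ∏_{i≤j} g_ij! )

The test orders configurations by this probability (the standard exact-test
criterion) and estimates the p-value by Monte Carlo: the pooled vector of
`2n` allele copies is randomly permuted and adjacent entries paired, which
samples genotype configurations from exactly this conditional
distribution. The estimator includes the observed table,
`p = (1 + #{stat ≤ observed})/(R + 1)`, so `p` is never zero and the test
is valid at any replicate count. Replicates default to 10,000; the seed is
a required, recorded input and the caller's RNG state is preserved. An
alternative reading of "based on observed allele frequencies" — parametric
resampling of genotypes from the frequency estimates — was considered and
rejected: the conditional permutation scheme is the exact-test convention,
needs no plug-in estimate, and is the one with a clean finite-sample
guarantee. Comparisons use a 1e-9 slack on the log-probability ordering so
that mathematically equal configurations are not split by floating-point
rounding.

On two-allele loci the Monte-Carlo p converges to the closed conditional
distribution over heterozygote counts of the correct parity, which the
test suite uses as an independent enumeration oracle. Calibration under
random mating (type-I error near 0.05) and power under a two-subpopulation
Wahlund mixture are checked by simulation, with cohorts of 100 control
genotypes and four alleles at frequencies (0.4, 0.3, 0.2, 0.1) — a size
and allele spectrum chosen to resemble a registry control arm while
keeping the conditional distribution rich enough for the exact test's
discreteness to be negligible.

## EM haplotype estimation and LD

`em_haplotypes()` is the classical gene-counting EM for unphased
multi-locus genotypes: each individual's genotype is expanded into its
`2^(h−1)` phase-consistent haplotype pairs (`h` = heterozygous loci), the
E-step distributes unit mass over those pairs proportionally to `2 f_i f_j`
(or `f_i²`), and the M-step re-estimates frequencies from expected counts
over `2n` chromosomes. The log-likelihood is non-decreasing at every
iteration (asserted in the tests over every fitted case) and iteration
stops when its relative change drops below `tol = 1e-8`, with
`max_iter = 1000` flagging — not throwing — non-convergence.

Initialization is the product of observed single-locus allele frequencies,
plus a tiny deterministic perturbation (relative size 1e-3, quadratic in
the haplotype index). The perturbation matters only for degenerate
symmetric inputs: a lone double-heterozygote gives two phase resolutions
with identical likelihood, and the unperturbed symmetric point is an EM
fixed point (a saddle). The quadratic ramp — a linear one cancels between
complementary phase pairs — pushes the iteration off the saddle toward one
of the equivalent maxima, chosen reproducibly by haplotype sort order
rather than by randomness. For regular data the perturbation is far below
sampling noise and does not move the optimum. Final frequencies below
1e-10 are pruned and the remainder renormalized.

Pairwise LD between two loci is summarized from the two-locus EM fit: for
each allele pair, `D_ij = p_ij − p_i q_j`, normalized to `D'_ij` by the
sign-appropriate bound, and `r²_ij = D_ij²/(p_i(1−p_i)q_j(1−q_j))`. The
locus-pair summary is the frequency-weighted mean `Σ p_i q_j |D'_ij|` —
the standard multi-allelic definition — with an unweighted mode available,
since plain "average absolute D′" is ambiguous and the two can differ
materially when rare alleles are in strong LD. The weighting used is
recorded in the `ld_matrix` object. Loci in LD matrices are always ordered
chromosomally (A, C, B, DRB1, DQA1, DQB1, DPB1). Note one multi-allelic
subtlety the tests pin down: duplicated locus content gives mean |D′| = 1,
but mean r² stays below 1 because off-diagonal allele pairs have
`r² = p q/((1−p)(1−q)) < 1` even under perfect coupling.

Haplotype case-control association reuses the allele-level machinery on
expected chromosome counts (`freq × 2n`, fractional values allowed, the
Haldane rule applied to exact zeros). Because phase uncertainty is not
propagated into these counts, every such row is approximate; rows whose
expected count falls below 5 in either group are additionally flagged
`em_unstable`, the regime where zero cells destabilize maximum-likelihood
haplotype estimation.

## The synthetic-cohort simulator

`simulate_cohorts()` draws the two groups from explicit generative truth,
in one of two mutually exclusive modes so the LD ground truth is never
ambiguous: independent loci (per-locus allele frequency vectors; all
cross-locus LD is exactly zero) or haplotype mode (multi-locus haplotype
frequency vectors; LD is whatever the haplotype table implies). Under
random mating the two chromosomes of an individual are i.i.d. draws, so
Hardy–Weinberg proportions hold by construction; under
`two_subpop_mix` each individual comes from one of two subpopulations
whose frequencies diverge from the nominal vector by `1 ± divergence`
(alternating sign, renormalized) — with `divergence = 0.8` a symmetric
biallelic locus splits into (0.9, 0.1) vs (0.1, 0.9) subpopulations,
producing the Wahlund heterozygote deficit the HWE test must detect.
Missingness is whole-genotype per (individual, locus), mirroring how real
typing failures produce the uneven per-locus denominators described above.
Draws are byte-reproducible given the config seed.

What the simulator does *not* emulate: genotyping error, allele-calling
ambiguity, linkage between "independent" loci, covariate structure, or
the long rare-allele tail of real HLA spectra (simulated loci have the
handful of alleles the config names). Passing calibration tests on
simulated cohorts therefore validates the statistical machinery, not the
upstream typing pipeline.

`simulate_from_fixture()` bridges the two worlds: it uses a fixture
locus's reconstructed frequencies as generative truth (default group
sizes: the 91/90 cases and 350 controls behind the fixture totals). Where
listed frequencies sum below 1, the remainder is carried by a synthetic
filler allele named `<locus>*00:00`, clearly outside real HLA nomenclature,
so listed alleles keep their exact expected frequencies.

## Problem sizes and tolerances used in validation

The test and acceptance runs use: 1,000 random-mating cohorts (100 control
genotypes, 4 alleles, 400 Monte-Carlo replicates) for HWE type-I
calibration and 200 cohorts for Wahlund power; 100 cohorts of n = 500 for
EM recovery against a 6-haplotype, 4-locus truth (observed mean absolute
error ≈ 0.009 against a 0.02 bound); 10,000 multinomial tables for ASR
null calibration; and a 50,000-per-group draw for the estimator-consistency
check against fixture odds ratios. These sizes make the binomial noise of
each calibration estimate several times smaller than the width of its
acceptance band. Golden regression values are asserted to ±0.001, the
rounding precision of the published three-decimal statistics.

## Known limitations

* No covariate adjustment (see above); no exact conditional logistic
  regression and no shrinkage estimators for sparse ORs.
* Haplotype association ignores phase uncertainty; its p-values should be
  read as descriptive when `em_unstable` is set.
* The Monte-Carlo HWE test is the plain conditional permutation sampler;
  for loci with very many alleles and large n a Markov-chain sampler would
  be faster per effective replicate, but 10,000 independent permutations
  are ample at registry-cohort sizes.
* Allele names are compared as exact strings at their given resolution.
  Rollup to two-field names is available (`allele_rollup()`) but off
  everywhere by default, because three-field siblings (e.g.
  DPB1\*02:01:01 vs DPB1\*02:01:02) can carry opposite association
  signals and silent truncation would merge them.
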