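---
title: "Methods: case-control association and gene-gene interaction analysis of TP53-axis variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control association and gene-gene interaction analysis of TP53-axis variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tp53axis)
```

## The problem

Acute myeloid leukemia (AML) susceptibility has been linked to common
germline variants in the p53 regulatory axis: *TP53* rs1042522 (Arg72Pro),
the two *MDM2* promoter/indel variants rs2279744 (309T>G) and rs3730485
(del1518), and *MDM4* rs4245739 (34091 C>A). Because MDM2 and MDM4 are
negative regulators of p53, the interesting questions are not only the
marginal genotype effects but whether the variants interact — whether, for
example, the risk carried by the Pro/Pro genotype of *TP53* is modified by
the GG genotype of *MDM2* 309T>G.

`tp53axis` implements the complete statistical side of such a candidate-gene
case-control study: genotype bookkeeping, Hardy-Weinberg and linkage-
disequilibrium diagnostics, single-locus logistic association under four
inheritance codings, pairwise epistasis likelihood-ratio matrices, a
from-scratch model-based multifactor dimensionality reduction (MB-MDR) with
max-Wald permutation correction, and categorical clinical-feature testing.
Because individual-level genotype data for such studies are typically not
deposited, the package also ships a synthetic cohort generator that
reproduces the statistical structure the analysis assumes, so every stage is
testable end to end.

## Data model and genotype coding

A cohort is a subject-level table (`status`, `sex`, `age_ge60`, one genotype
column per locus) plus a locus configuration fixing, for each biallelic
locus, which allele counts as *variant*. Orientation is deliberately a
configuration fact and never inferred from allele frequency: the reference/
ancestral annotation of *MDM4* rs4245739 has flipped between genome-browser
releases, so a frequency heuristic could silently reverse every odds ratio
at that locus. The shipped panel encodes variant = Pro, G, D, A. Genotypes
are stored as variant-allele dosage 0/1/2; heterozygote strings are
order-insensitive on input and written back in canonical wildtype-first
form, which makes write-read-write round-trips byte-identical.

Missing genotypes are excluded per analysis (complete-case); exclusion
counts are carried in the tabulations. The four inheritance codings map
dosage to design columns: codominant (two dummies against dosage 0),
dominant (`d >= 1`), recessive (`d == 2`), overdominant (`d == 1`).

## Single-locus association

For each locus and coding, `fit_locus()` fits a binomial GLM (logit link)
by IRLS. Per-level odds ratios and 95% intervals are Wald
(`exp(beta +/- 1.959964 se)`); the single model p-value is a
likelihood-ratio test against the nested null (2 df for codominant, 1 df
otherwise). In the adjusted analysis both models contain the `age_ge60` and
`sex` covariates, so the LRT isolates the genetic term. LRT rather than a
per-coefficient Wald test is used for the model p-value because it gives
one coherent p per coding, including a 2-df omnibus for codominant — the
convention of the standard SNP-association toolchain this package mirrors.

For any single-column coding the GLM is a saturated 2x2 model, so the
fitted OR must equal the cross-product ratio `ad/bc` and the Wald SE must
equal `sqrt(1/a + 1/b + 1/c + 1/d)`; the test suite asserts this closed-form
equivalence to 1e-6, and `crude_or_from_counts()` exposes the closed form
directly (with the Haldane-Anscombe +0.5 correction, flagged, when a cell
is zero). Multiplicity is handled exactly as declared in the study design:
Benjamini-Hochberg within the family of the four codings of one locus,
crude and adjusted families separate (`bh_adjust()` delegates to
`stats::p.adjust`).

The joint interaction model (`fit_interaction_model()`) is a single
logistic model with recessive-coded main effects of all four loci, product
terms for the two biologically motivated pairs (rs2279744 x rs1042522,
rs4245739 x rs3730485), and the covariates. Stratum odds ratios are derived
as `exp(beta_main + beta_interaction)`.

## Hardy-Weinberg and linkage disequilibrium

`hwe_test()` is the Pearson 1-df chi-square against `p^2, 2pq, q^2` at the
estimated allele frequency, without continuity correction; a monomorphic
sample is in equilibrium by convention. The chi-square (not an exact test)
is the default because the study values this package reproduces are
consistent with it; an exact test was considered and rejected as the
default since nothing in the reproduced material distinguishes them.

`em_haplotypes()` estimates the four two-locus haplotype frequencies from
unphased genotypes by EM. In the 3x3 genotype table only the
double-heterozygote cell is phase-ambiguous; the E-step splits it between
the cis and trans resolutions in proportion to the current haplotype
frequencies, and the M-step is gamete counting. The EM is initialized at
linkage equilibrium, converges when the largest frequency change is below
1e-8 (cap 1000 iterations), and is deterministic. The log-likelihood is
asserted non-decreasing at every iteration, and when the
double-heterozygote count is zero the estimate equals direct phased
counting exactly. From the converged frequencies: signed
`D = f(var,var) - pA pB`, standardized `|D'| = |D| / Dmax` with the usual
frequency-dependent bound, `r^2`, and a 1-df LRT against the
independence model. `|D'|` is reported unsigned, the convention in which a
value such as 0.89 is quoted; which locus pair such a single quoted value
refers to is not identifiable from a publication, so `ld_table()` computes
all six pairs and leaves the biologically expected same-gene MDM2 pair to
the reader's attention.

## Pairwise epistasis matrices

`epistasis_matrix()` produces, per coding, the conventional three-zone
matrix: upper triangle = LRT of the two-locus model with genotype product
term(s) against the additive two-locus model; diagonal = each locus against
the covariate-only model; lower triangle = the additive two-locus model
against the better (higher log-likelihood) of the two single-locus models,
ties broken deterministically by row-locus order. All models include the
covariates and are fitted on the pair's complete cases so each comparison is
strictly nested. Degrees of freedom come from fitted-rank differences:
constant design columns (empty genotype classes) are dropped and reduce the
df of the affected cell; a cell with no remaining df is NA.

## MB-MDR

The MB-MDR implementation is written from first principles for binary
outcomes:

1. **Cell enumeration.** For a combination of k loci (k = 2-4), each
   observed multi-locus genotype is a cell (up to 3^k); cells partition the
   complete-case subjects.
2. **Step 1 — categorization.** Each cell is tested by logistic regression
   of status on the cell-membership indicator versus all other subjects.
   Cells with `beta > 0` and `p < 0.10` are high-risk (H), `beta < 0` and
   `p < 0.10` low-risk (L), all others no-evidence (O). The default step-1
   model is unadjusted — the classical choice, with covariates entering at
   step 2 — and because that model is a saturated 2x2 its MLE and Wald test
   are computed in closed form, identical to the GLM to numerical precision
   (asserted in the tests). `step1_adjust = TRUE` switches to per-cell GLMs
   with covariates. Cells with fewer than 5 subjects, or degenerate cells
   (all-case or all-control, infinite log-odds), are forced to O and
   flagged; the size floor is a package choice where the procedure's
   description is silent.
3. **Step 2 — merged-group testing.** The H group is tested against the
   remaining subjects by logistic regression of status on the H indicator
   plus additive-coded main effects of the combination's loci and the
   covariates; likewise L. Additive main-effect adjustment is the standard
   MB-MDR choice — full codominant dummies for all loci would be nearly
   rank-deficient against the merged indicator. `W = (beta/se)^2` is
   referred to the 1-df chi-square upper tail; an empty category reports NA.
   The combination's statistic is `min(p_H, p_L)`.
4. **Permutation correction.** Case/control labels are permuted (genotypes
   and covariates stay with subjects), the full two-step procedure re-run,
   and `max(W_H, W_L)` recorded (0 when both sides are NA). The corrected
   p-value uses the add-one convention
   `(1 + #{perm >= obs}) / (n_perm + 1)`, so it is never 0 and never below
   `1/(n_perm + 1)`. The asymptotic step-2 p-values are reported
   uncorrected (their published counterparts match the plain chi-square(1)
   tail), with the permutation p carrying the multiplicity control; a
   Bonferroni-style per-category correction was considered and left out of
   the default for exactly that reason.

`scan_combinations()` runs all combinations of orders 2-4 (6 + 4 + 1 = 11
for four loci); each combination gets a deterministically derived child
seed so any row can be reproduced in isolation.

## The synthetic cohort generator

The generator's defaults encode the study conditions the analysis assumes:

* **Group sizes** 403 cases / 406 controls.
* **Allele frequencies and Hardy-Weinberg departure** are derived
  programmatically from the published control genotype counts. Each locus
  gets a variant frequency `p` and an inbreeding coefficient
  `F = 1 - h_obs/h_exp` (TP53 ~0.068, rs2279744 ~0 after clamping a
  slightly negative heterozygote excess, rs3730485 ~0.086, MDM4 ~0.379);
  genotypes follow `P(hom var) = F p + (1-F) p^2`,
  `P(het) = (1-F) 2 p (1-p)`. The one-parameter F model is the minimal
  emulator of the observed departures, for which no mechanism is
  established.
* **Linkage disequilibrium.** The two MDM2 loci are generated from a pair
  of two-locus haplotypes whose frequencies are solved to give `|D'| = 0.89`
  at the control allele frequencies, with the variant alleles positively
  associated (the direction is not identifiable from a quoted |D'|; it was
  fixed once). Per-locus inbreeding is imposed by copying the first
  gamete's allele onto the second with probability F at that locus, which
  reproduces the single-locus F-model marginals while retaining the
  haplotype structure. A known consequence: under nonzero F the EM
  estimator, which assumes random union of gametes, is mildly attenuated
  (about 0.83 observed against the closed-form 0.89 for the control-derived
  F values), so the LD-accuracy checks are run at F = 0 where the EM is
  unbiased; the F > 0 presets are validated on their genotype margins
  instead.
* **Disease model.** Status is Bernoulli with logit
  `beta0 + sum(betas * design)`; design terms are products of covariates
  and per-locus coding indicators, so the published joint interaction model
  is exactly recoverable by construction. The `paper_replica` preset plants
  the published recessive-model coefficients (-0.41, 0.51, 0.10, 0.26,
  interactions +1.22 and -0.92) plus covariate log-odds implied by the
  reported demographic margins (male +0.35, age >= 60 -0.23);
  `beta0 = -1` keeps the case quota cheap to fill.
* **Ascertainment** is rejection sampling from the population model until
  both quotas are met — exact under the logistic model and simple, instead
  of inverting the retrospective likelihood. The attempt cap turns an
  unreachable quota into a clear error.

Identical configuration and seed reproduce a cohort byte-for-byte.

What the generator does **not** emulate: clinical features (blood counts,
risk-stratification scores), survival, genotyping error, or population
stratification. Passing tests therefore demonstrate that the estimators are
correct and calibrated under the assumed generative model, not that any
particular biological finding replicates in new data.

## Numerical choices

* IRLS convergence: deviance tolerance 1e-12, max 100 iterations; this is
  tight enough that the GLM agrees with closed-form 2x2 quantities and
  independent Newton refits to 1e-6.
* Separation / non-convergence: flagged (absolute coefficient above 15 or
  non-converged IRLS) and reported as NA p-values, never silently dropped.
* CI level fixed at 95%, `z = 1.959964`.
* EM: tolerance 1e-8 on frequencies, cap 1000 iterations, likelihood floors
  at 1e-300 to avoid log(0) in empty cells.
* Fisher's exact test is selected automatically when any expected count is
  below 5 (2x2 exact; larger tables fall back to seeded Monte-Carlo
  simulation if the network algorithm fails). Pearson 2x2 tests use no
  continuity correction.
* Permutation p-values use the add-one convention; master seed plus
  deterministic child seeds (`(1009 s + 7919 i) mod 2^31 - 1`) keep every
  row independently reproducible.

## Validation strategy and problem sizes

The suite validates each estimator against an independent oracle: phased
haplotype counts for the EM, hypergeometric enumeration for Fisher,
damped-Newton refits from a different start for the GLMs, independent
log-likelihood evaluation for the LRTs, per-cell GLMs for the MB-MDR
closed form, and brute-force recounting for every tabulation. Statistical
behaviour is checked by simulation at sizes chosen to balance Monte-Carlo
error against a desk-scale run: type-I calibration with 100 seeds of
n = 800 cohorts at 200 permutations (empirical alpha required inside
[0.01, 0.11] at the 0.05 level), parameter recovery with 100 cohorts of
n = 809 (planted coefficients required inside their fitted 95% CIs at least
90 times), and detection power for the implicated two-locus combination in
a majority of 50 seeds. The full suite runs in about a minute.

## Known limitations

* Quantities that require the undeposited individual-level data — adjusted
  ORs, the observed epistasis p-values, the observed MB-MDR betas — cannot
  be reproduced numerically; they are validated by the property-based
  substitutes above.
* The epistasis matrix targets a handful of candidate loci; it is not a
  genome-scale pair scanner.
* MB-MDR here is binary-outcome only; no quantitative-trait or survival
  variant, and permutations run on one core.
* The post-hoc machinery for clinical features implements the generic
  level-vs-rest and pairwise contrast families; thresholds for
  dichotomizing laboratory values are configuration, not fixed science.
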