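# tp53axis

Case-control association and gene-gene interaction analysis of candidate
variants in the p53 regulatory axis: *TP53* rs1042522 (Arg72Pro), *MDM2*
rs2279744 (309T>G) and rs3730485 (del1518), and *MDM4* rs4245739 (34091
C>A), with acute myeloid leukemia (AML) as the case phenotype. The package
is for biostatisticians and genetic epidemiologists running candidate-gene
case-control studies who need the whole analysis chain — not just the
marginal tests — reproducible and testable.

## What it computes

* **Single-locus association** under the four inheritance codings
  (codominant, dominant, recessive, overdominant): binomial GLM (logit
  link), Wald 95% CIs per genotype level, likelihood-ratio model p-values,
  crude and age/sex-adjusted, with Benjamini–Hochberg FDR across the four
  codings of each locus. For a single-column coding the GLM odds ratio
  equals the 2×2 cross-product ratio *ad/bc* with
  `CI = exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d))`.
* **Population-genetic diagnostics**: Hardy–Weinberg χ²(1) per locus and
  group; two-locus linkage disequilibrium from unphased genotypes via an EM
  haplotype-frequency estimator, reporting D, |D′| = |D|/D\_max, r², and a
  1-df LRT for D = 0.
* **Pairwise epistasis matrices**: per coding, covariate-adjusted LRT
  p-values — interaction vs additive (upper triangle), locus vs covariates
  (diagonal), additive vs best single locus (lower triangle).
* **MB-MDR** (model-based multifactor dimensionality reduction), written
  from scratch for binary outcomes: per-cell logistic categorization into
  high-risk/low-risk/no-evidence (H if β > 0 and p < 0.10, L if β < 0 and
  p < 0.10, else O), merged-group Wald tests W = (β/se)² adjusted for
  main effects and covariates, and max(W_H, W_L) permutation correction
  with `perm_p = (1 + #{perm ≥ obs})/(n_perm + 1)`.
* **Clinical categorical testing**: Pearson/Fisher with automatic
  expected-count selection and BH-adjusted post-hoc contrasts.
* **A synthetic cohort generator** whose defaults encode the study
  conditions (403 cases / 406 controls, control-table allele frequencies,
  inbreeding-coefficient HWE departures, MDM2 haplotype LD at |D′| = 0.89,
  and the published joint logistic disease model), so every stage runs and
  is validated without individual-level patient data.

## Worked example

```r
library(tp53axis)

ch <- simulate_cohort(sim_preset("paper_replica", seed = 42))
ch
#> <cohort> 809 subjects (403 cases / 406 controls), 4 loci: TP53_rs1042522,
#>   MDM2_rs2279744, MDM2_rs3730485, MDM4_rs4245739

fit_locus(ch, "TP53_rs1042522", "recessive")
#> <assoc_result> TP53_rs1042522, recessive: LRT p = 1.348e-05 (df = 1)
#>     level   or ci_lo ci_hi
#> 1 Pro/Pro 3.05 1.792 5.192

permutation_correct(ch, c("MDM2_rs2279744", "TP53_rs1042522"),
                    n_perm = 1000, seed = 42)
#> <mbmdr_result> MDM2_rs2279744 + TP53_rs1042522
#>   H: N=3 beta=0.834 W=24.7 p=6.68e-07 | L: N=3 beta=-0.639 W=14.6 p=0.000136
#>   permutation-corrected p = 0.000999 (1000 permutations)
```

The simulated cohort carries a planted Pro/Pro recessive effect and a
GG × Pro/Pro interaction, so the recessive odds ratio is elevated (3.05
here; the planted marginal-plus-interaction structure makes the realized
value vary by seed), and the MB-MDR two-locus scan flags the interacting
pair with a permutation-corrected p at the resolution floor of 1000
permutations. `run_pipeline(list(preset = "paper_replica", seed = 42))`
executes every stage and writes the four report tables, a Markdown summary,
and a JSON manifest.

On real data, replace the simulated cohort with
`read_cohort("cohort.tsv", "loci.yaml")` — one row per subject, one
genotype column per configured locus.

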