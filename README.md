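# mendeviate

Detection of Mendelian deviations in parent–offspring trio SNP-array
genotypes and estimation of the germline mutation frequency, for studies
that use the burden of de novo point mutations in children as a biomarker
of parental exposure to mutagens such as ionizing radiation.

## The problem and the method

A *Mendelian deviation* (MD) is a child genotype at a biallelic marker
that no pair of parental gametes can produce — at an autosomal SNP it is
read as a candidate de novo germline mutation. Given high-density
SNP-array genotypes (AA/AB/BB calls with per-call confidence values) for
father, mother, and child, the package:

1. **Filters** to markers with valid, confidence-passing calls in all
   three members; the count of retained markers is the trio's valid-SNP
   number *nvp*.
2. **Detects** deviations by exhaustive gamete logic, and infers the
   **parent of origin** wherever one parent alone can explain one of the
   child's alleles (e.g. AA × AB → BB must come from the father's
   gamete). Combinations like AA × AA → AB remain ambiguous.
3. **Deduces** the origin of ambiguous deviations with two heuristics
   that must agree: the parent with the lowest call-confidence value at
   the marker, and the origin of the nearest Mendelian-resolved
   deviation on the same chromosome (a proxy for which parent
   transmitted the segment). Disagreement leaves the deviation in the
   "unknown" column.
4. **Classifies** each deviation into the six pyrimidine-standardized
   substitution classes (C>A, C>G, C>T, T>A, T>C, T>G; purine changes
   are strand-collapsed), flagging C>T sites inside CpG islands.
5. **Estimates** the per-trio germline mutation frequency

   MF_MD = Σ T_MD / (2 · nvp)

   (deviations per transmitted allele), and computes the group-level
   statistics used to compare exposed and control families: group means
   and SDs, percent increase, pooled-variance t-test, variance-ratio
   F-test on per-trio MD counts, Shapiro–Wilk normality checks,
   dose–response OLS regression, exposed-father/mother subgroup
   comparison, and paternal-fraction/parental-age regressions.

A Hardy–Weinberg trio **simulator** with injected de novo mutations
(per-gamete rate μ), genotyping errors (ε), and no-calls provides ground
truth for end-to-end validation, including an exact enumeration of the
probability that an injected allele flip is detectable as a deviation.

## Worked example

The package ships the published per-trio results of a cohort of 15
families exposed to Cs-137 during the Goiânia radiological accident
(parental absorbed doses 0.1–0.5 Gy) and 15 unexposed control families:

```r
library(mendeviate)
d <- goiania_cohort()
head(d[, c("family_id", "group", "dose_gy", "md_total", "n_valid", "mf_md")], 3)
#>   family_id   group dose_gy md_total n_valid        mf_md
#> 1     Ct001 control       0     1487  702304 0.0010586584
#> 2      Ct25 control       0     1179  683381 0.0008626228
#> 3      Ct27 control       0     1332  692311 0.0009619954

group_comparison(d)
#> Group comparison of germline mutation frequencies
#>   exposed: n = 15, mean MF_MD = 0.00126 (SD 0.0004)
#>   control: n = 15, mean MF_MD = 0.000877 (SD 0.00019)
#>   increase: 43.9%
#>   pooled t = 3.349 (df 28), p = 0.002
#>   variance ratio F = 4.477 (df 14, 14; on counts), p = 0.008
#>   Shapiro-Wilk p (counts): exposed 0.559, control 0.678

dose_regression(d)
#> MF_MD = 0.0009143 + 0.001256 * dose (Gy); R^2 = 0.257, p(slope) = 0.004, n = 30
```

Exposed children carry on average a ~44% higher burden of de novo SNP
mutations than controls (1.26×10⁻³ vs 0.88×10⁻³ per transmitted allele),
and the frequency rises with the parental absorbed dose by about 10⁻³
per gray.

Marker-level analysis on simulated data with known truth:

```r
cfg <- sim_config(n_markers = 20000, mu = 1e-3, seed = 1)
sc  <- simulate_trios(cfg, n_trios = 1)
tr  <- sc$trios[[1]]
res <- analyze_trio(tr$father, tr$mother, tr$child, family_id = "Sim01")
nrow(res$mds)                                        # 18 deviations
evaluate_detection(sc$truth, res$mds, res$n_valid)   # sensitivity 1, 0 false
```

Only flips landing in informative parental-genotype contexts surface as
deviations — `detectability_probability(maf)` gives the exact fraction
(≈0.53 averaged over common allele frequencies), so detected counts
undercount true events by a known factor, an ascertainment shared by any
array-based MD count.

A command-line front end over the same functions lives in
`inst/cli/mendeviate.R` (subcommands `simulate`, `run`, `detect`,
`summarize`, `compare`).

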