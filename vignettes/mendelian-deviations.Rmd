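---
title: "Mendelian deviations as a germline mutation assay: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian deviations as a germline mutation assay: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendeviate)
```

## The assay

High-density SNP arrays genotype several hundred thousand autosomal
biallelic markers per sample. In a father–mother–child trio, a child
genotype that cannot be assembled from one paternal and one maternal
gamete — a *Mendelian deviation* (MD) — indicates that a transmitted
allele changed in a parental germ line (or that a genotyping error
occurred; see *Limitations*). Counting MDs across a trio's valid markers
yields a per-child estimate of the germline point-mutation burden,

$$MF_{MD} = \frac{\sum T_{MD}}{2\, n_{vp}},$$

deviations per transmitted allele: each of the $n_{vp}$ valid markers
contributes two transmitted alleles (one per gamete). Comparing $MF_{MD}$
between children of exposed and unexposed parents turns the burden into
a biomarker of parental mutagen exposure.

## Transmission logic and parent of origin

In a marker's A/B allele space there are $3^3 = 27$ (father, mother,
child) genotype combinations. Exhaustive gamete enumeration shows 12 are
deviations. For a deviation, a *single-mutation explanation* for parent
$P$ is: $P$'s transmitted allele mutated while the other parent
contributed one of the child's alleles unchanged. The origin is assigned
to $P$ exactly when the explanation works for $P$ alone:

* 8 combinations resolve to one parent (e.g. AA × AB → BB: the mother
  can pass B, the father cannot — his gamete mutated A→B);
* 4 are ambiguous: AA × AA → {AB, BB} and BB × BB → {AB, AA}. In
  AA × AA → AB either parent's gamete may have mutated; in AA × AA → BB
  no single mutation suffices.

Double inconsistencies (AA × BB → AA, AA × AA → BB) are counted as **one**
MD event with origin resolved only when unique: per-marker tallies have
no two-event category, and a two-hit interpretation is indistinguishable
from a genotyping artifact at the level of array calls. For
origin-unknown deviations with both parents homozygous for the same
allele the ancestral base is still defined (the shared parental allele),
so these MDs enter the substitution spectrum.

The same logic is exposed in base space
(`classify_transmission_bases()`), where third-base child calls — which a
biallelic probe cannot actually produce — are handled for completeness.

## Origin deductions for ambiguous MDs

Two heuristics attempt to rescue ambiguous origins; both must agree
(conjunction), otherwise the MD stays in the "unknown" column:

1. **Confidence**: the parent with the *lowest* call-confidence value at
   the marker. On this platform lower confidence values denote better
   calls; we read the published procedure as comparing the per-call
   confidence directly, since "confidence interval" is not otherwise
   defined for a single genotype call. Exact ties are uninformative.
2. **Nearest resolved neighbor**: the origin of the closest
   Mendelian-resolved MD on the same chromosome, by absolute base-pair
   distance (1-D Euclidean distance; chromosomal segments make
   cross-chromosome neighbors meaningless). Equidistant neighbors break
   deterministically toward the lower position. The search window is
   unlimited by default (`window_bp`), configurable.

Only Mendelian-resolved MDs serve as neighbors, in a single pass:
allowing deduced MDs to seed further deductions would let one ambiguous
assignment propagate down a chromosome. The conjunction rule is why a
residual unknown count remains even after deduction — matching the
nonzero "unknown" columns of published per-trio tables. This neighbor
heuristic is *not* haplotype phasing; it is a coarse proxy for segment
transmission.

## QC model

Calls are kept when the genotype is not a no-call and the confidence
value passes the threshold (default 0.05). The published filtering
sentence can be read two ways; because the platform convention is that
lower confidence values are better, the default `keep_rule = "leq"`
keeps calls with confidence ≤ 0.05, and `"geq"` implements the opposite
reading. A missing confidence value is treated as the worst possible
(1.0), so such calls never pass.

Complete-case filtering is applied **per trio** by default: each family
keeps its own valid-SNP count $n_{vp}$, which is how per-family valid-SNP
totals can differ. A `completeness = "global"` mode (markers valid in
every sample of every family) is available for sensitivity analyses.
Sex chromosomes are excluded at read time: X-linked calls are noisy and
Y coverage is sparse, and transmission logic differs there anyway.

## Substitution spectrum and CpG sites

Array genotypes cannot tell which strand mutated, so substitutions are
collapsed into six pyrimidine-ancestral classes (C>A, C>G, C>T, T>A,
T>C, T>G); the mapping is an involution under complementation. C>T MDs
falling inside CpG islands (user-supplied BED track, 0-based half-open;
a marker at 1-based position $p$ is inside $[s, e)$ iff $s < p \le e$)
are flagged as likely deamination-driven. The flag is always computed
but flagged sites are **kept** in tallies by default, matching the
published analysis in which all C>T sites fell outside islands and were
retained; `exclude_cpg = TRUE` removes them from the class table only.

## Group statistics

* Group means of $MF_{MD}$ are unweighted arithmetic means of per-trio
  frequencies, not pooled counts over pooled $n_{vp}$ — each child is one
  observation of the germline process.
* The two-sample t-test uses pooled variance with $n_1 + n_2 - 2$ df.
* The variance-ratio F-test compares per-trio MD **counts**
  (exposed/control) by default: recomputing both variants from the
  published per-trio table shows counts reproduce the reported statistic
  (4.477 ≈ 4.47) while frequencies give ≈4.58. Frequencies remain
  available via `f_test_on = "mf_md"`.
* Shapiro–Wilk normality is computed per group on the MD counts (the
  exposed group's p = 0.559 is the published value; the pooled-30 value
  is also reported). It is informational and never gates a test.
* The dose regression is OLS of $MF_{MD}$ on absorbed dose in Gy over
  all trios, controls entering at dose 0.
* Sample SDs use the $n-1$ denominator throughout; p-values are carried
  at full precision and only rounded for display.

The published intragroup comparison of exposed-father vs exposed-mother
children (p = 0.195) is not reproducible from the printed per-trio
values (a pooled t-test gives p ≈ 0.79); the package reports its own
p-value.

## The simulator

`simulate_trios()` draws markers with minor-allele frequencies uniform
on [0.05, 0.5] (common polymorphic array content), parents under
Hardy–Weinberg equilibrium, and one transmitted allele per parent. A
transmitted allele flips to the other probe allele with probability μ
per gamete per marker; genotyping errors (probability ε per call,
uniformly to a wrong genotype) and no-calls are applied afterwards, and
every injected event is logged with whether it is *detectable* — i.e.
whether the realized trio genotypes form a deviation.
`detectability_probability()` computes that probability exactly by
enumeration over HWE parental genotype pairs and transmission choices:
it tends to 1 as MAF → 0 and falls to 0.375 at MAF 0.5, averaging ≈0.53
over the default MAF band. Mutations are constrained to the two probe
alleles, mirroring the assay's own ascertainment: like the real assay,
the simulator's detected counts undercount the true de novo rate by the
non-detectable fraction.

Defaults emulate the study conditions: the `cohort_design()` preset
reuses the published 15 + 15 family design (doses, ages, sexes) and
calibrates each family's μ so the expected frequency follows the
published dose response ($MF = 0.9\times10^{-3} + 1.0\times10^{-3}
\cdot d$), dividing by mean detectability. Simulations in tests and
examples use 20–50k markers rather than the platform's ~700k — the
detection logic is per-marker, so scale only affects counting noise, and
these sizes keep examples quick while leaving expected MD counts in the
tens. One global seed drives the run; each family uses a deterministic
substream so any single family is reproducible in isolation.

What the simulator does **not** model: linkage disequilibrium between
markers (so the nearest-neighbor deduction cannot be validated for
biological fidelity, only for its stated mechanics), cluster-intensity
artifacts, population structure, and mosaicism. Passing simulation tests
therefore demonstrate the pipeline's logic and calibration, not the
biological accuracy of the deduction heuristics on real chromosomes.

## Numerical and degenerate-input choices

* Genotype tables: duplicate probe ids and missing mandatory columns are
  hard errors; malformed rows are skipped and counted.
* Empty probe intersection across a trio is a hard error (QC upstream of
  assembly went wrong).
* `mf_md()` requires $n_{vp} > 0$; a zero-variance predictor makes the
  dose regression a hard error; a subgroup below two trios reports an
  undefined SD and skips the comparison; a zero-variance control group
  makes the F statistic undefined (reported as `NA`).
* All tie-breaks (equidistant neighbors, equal confidences) are
  deterministic; the pipeline contains no randomness outside the
  simulator, so identical inputs give byte-identical outputs.

## Limitations

Genotyping errors masquerade as MDs: the estimated $MF_{MD}$ is inflated
monotonically with the error rate ε (a property verified in the test
suite), and an array-based MD count is therefore an upper bound on
detectable de novo events, not a calibrated mutation rate. Somatic
variants arising in early embryonic divisions are counted as germline.
Recurrence tabulation across families (`tabulate_recurrence()`) helps
flag problem probes but cannot remove within-family artifacts. Finally,
the published control-group class-table totals are internally
inconsistent with their own means; the package reports totals consistent
with per-trio counts and does not attempt to reproduce those printed
totals.
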