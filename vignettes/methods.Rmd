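---
title: "Methods: two-phase germline pharmacogenomic variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase germline pharmacogenomic variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pgxprio` implements a two-phase design for finding germline variants in a
pharmacogene panel that predict how breast-cancer patients respond to
cytotoxic chemotherapy and how long they stay disease-free. A *testing*
cohort is screened broadly: genotypes pass a QC cascade, each surviving
variant is tested against two clinical endpoints with a permutation-based
multiplicity adjustment, survivors are screened for a plausible gene-dosage
relationship, and database plus in-silico evidence sorts them into priority
levels from which a compact *validation* panel is drawn. The panel is then
re-genotyped in an independent, larger cohort and re-tested with the same
statistics plus multivariate adjustment.

This vignette records the model, the tunable parameters, the numerical
choices, and the places where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## Data model

A `genotype_matrix` codes each call as the number of copies of the *rare*
allele in the analyzed cohort: 0 = common homozygote, 1 = heterozygote,
2 = rare homozygote, `NA` = missing. `orient_genotypes()` flips any row
whose non-reference allele frequency exceeds 0.5, because panel variants
are often oriented so the reference genome carries the minor allele
(non-reference frequencies up to ~0.9 occur), while every downstream test
groups patients as common-homozygote / heterozygote / rare-homozygote.
Orientation is fixed on the full cohort before any subsetting so testing
and validation subsets share group labels.

The clinical table carries therapy arm (neoadjuvant, adjuvant,
hormonal-only, none), the dichotomized radiological response (complete or
partial response = responder; stable or progressive disease =
non-responder; defined only for neoadjuvant patients), disease-free
survival in months with an event flag (absent exactly for patients lost to
follow-up), and the covariates stage, grade, ER, PR, HER2 and molecular
subtype.

## QC cascade

A variant is analyzed when all three hold:

* MAF > 0.05 — below that, group sizes in a cohort of a few hundred give no
  power;
* exact Hardy-Weinberg p > 0.01 — departures flag genotyping artifacts;
* missing calls < 50% of the cohort (denominator: all samples, not just
  genotyped ones).

The HWE test is the exact conditional test: given the observed allele
counts, the probability of each admissible heterozygote count is computed
by the standard ratio recurrence, and the p-value sums all outcomes no more
probable than the observed one. The exact flavor was chosen (the source
analysis names only the tool it used) because panel variants include
low-MAF sites where the chi-square approximation is unreliable; the mid-p
variant is not used. Monomorphic sites return p = 1.

The report records the first failing rule in the order MAF → HWE →
missingness; the pass/fail *set* is order-independent.

Before association testing, a homozygote group observed in fewer than
5 patients is collapsed into the heterozygotes, giving a two-group
common-homozygote vs rare-allele comparison. Exactly 5 keeps three groups
("fewer than five" is strict).

## Association testing

**Response.** Pearson chi-square on the genotype-group × responder table,
no continuity correction (validated against the published 3×2 tables, which
reproduce only without correction). Restricted to neoadjuvant patients.

**DFS.** K-group log-rank with hypergeometric variance; follow-up is
administratively truncated at 120 months (values strictly above 120 are set
to 120 and censored). Kaplan-Meier curves use the standard convention that
subjects censored at an event time remain at risk at that time. Patients
lost to follow-up are excluded from survival analyses but retained for
response.

**Permutation adjustment.** For each variant the outcome vector is permuted
B times (B = 1000 for response, 100 for survival), the raw p is recomputed
each time, and the adjusted p is `(1 + #{permuted p <= observed p})/(B+1)`.
Two deliberate choices:

* *Direction.* The source text, read literally, counts permutations with
  p *higher or equal* than observed, which would drive genuinely associated
  variants toward 1. The conventional direction (permuted p ≤ observed) is
  implemented; this is flagged as a documented divergence from the letter
  of the text, not silently resolved.
* *Add-one smoothing.* `(1+k)/(B+1)` keeps the Monte-Carlo p away from an
  impossible 0 and puts adjusted p on the grid `k/(B+1)`.

Survival permutations are generated within therapy-arm strata, since the
testing cohort mixes neoadjuvant and adjuvant patients whose follow-up
differs structurally. At the pipeline level one shared set of outcome
permutations is evaluated against every variant (the permuted object is the
original data, not per-variant relabelings); the per-variant `perm_adjust()`
operation uses the same generator, so both paths agree exactly under a
common seed. Significance is adjusted p < 0.05.

**Multivariate adjustment.** Logistic regression for response (adjusted to
disease stage) and Cox proportional hazards for DFS (Efron tie handling —
month-resolution data guarantees ties; adjusted to grade, stage, ER, PR).
Both report the likelihood-ratio test of the variant term against the
nested covariate-only model, plus Wald 95% intervals. These covariate sets
are the ones found prognostic in the source cohorts and are configurable.
Non-convergence, separation and monotone likelihood are flagged, never
silently reported. Post-hoc multiplicity corrections (Bonferroni, Holm,
Hochberg, Hommel, Benjamini-Hochberg) are available for the Cox p-values.

## Gene-dosage gate

Variants whose *heterozygote* shows the most extreme outcome relative to
both homozygotes contradict a dose-response interpretation and are
excluded. "Most extreme" needs a scalar per genotype group; the source
shows only KM plots, so this package uses the restricted mean survival
time over [0, 120] months — the area under the KM step curve, which matches
the visual ordering of curves over the fixed window. A variant is
*consistent* when the heterozygote RMST lies weakly between the homozygote
RMSTs (ties pass, so null variants are not excluded by measure-zero
events). With fewer than three genotype groups the verdict is
not-evaluable and treated as a pass.

Two scope decisions:

* The gate is evaluated on the *collapsed* grouping. Collapsing precedes
  the gate in the analysis order, and every variant the source excluded by
  this rule retained three groups of ≥ 5 patients. Evaluating uncollapsed
  1–2-patient homozygote curves would let pure noise veto genuinely
  additive effects.
* Only the survival verdict excludes. The source applies the rule to
  DFS-associated variants; the analogous responder-proportion check for the
  response endpoint is provided and reported as a diagnostic column, but
  does not gate, because with a ~10-patient rare-homozygote group its
  betweenness rule rejects planted additive effects at a rate we measured
  near 20% — an exclusion that would be noise, not biology.

## Evidence integration and the priority matrix

Per-variant evidence arrives as a pre-built table (no live database
queries; the artifact stays hermetic and version-stable): PharmGKB
association status, ClinVar status, a cancer-related-functionality flag,
and per-tool in-silico outputs.

`insilico_consensus()` reduces the tools to one call:

* *missense*: strict four-tool consensus — Mutation Assessor H/M, SIFT
  ≤ 0.05, LRT = D, PROVEAN = D; any missing tool makes the call `unknown`
  (consensus with listwise exclusion, avoiding training-set circularity);
* *splice-site*: MaxEntScan alternative score below reference, or dbscSNV
  ada ≥ 0.6 (the conventional threshold; the source reports scores without
  a cutoff);
* *noncoding/synonymous*: RegulomeDB category 1, PINES p ≤ 0.05, IW score
  < 0.01, or a conserved miRNA target site;
* any class: CADD PHRED ≥ 19 upgrades a non-deleterious call to
  deleterious (supplementary ensemble evidence).

`assign_priority()` is a pure function over {significant} × {PharmGKB} ×
{ClinVar} × {in-silico} × {cancer-related}. Significance is mandatory;
columns are evaluated left to right, first match wins (the matrix defines
no conflict rule; left-to-right preserves its ordering). ClinVar "other
disease" maps to no-data — only drug-response and cancer/neoplasm records
count as pathognomonic here, following the matrix over the looser prose
elsewhere in the source. An `unknown` in-silico call satisfies the High
column's deleterious-or-neutral slot but never a strict deleterious
requirement. The panel is ordered by level, then smaller adjusted p, then
variant id (a deterministic tie-break), and truncated at the configured
size (default 58).

## Synthetic cohorts

`simulation_config()` + `simulate_cohort()` generate cohorts with exactly
the structure the analysis assumes, so every stage is testable without
patient-level data (none is deposited):

* genotypes i.i.d. per variant with P(het) = 2pq(1−f), homozygotes
  p² + pqf and q² + pqf; f = 0 is exact HWE, and f's admissible range
  [−min(p,q)/max(p,q), 1] is validated;
* response via a logistic model: logit P = logit(baseline) + Σ log(OR) ×
  dose, dose ∈ {0,1,2} (additive), {0,1,1} (dominant), {0,0,1} (recessive);
* DFS via exponential event times with hazard `baseline_hazard × HR^dose`,
  independent exponential censoring, and administrative censoring at the
  horizon — the simplest generative model consistent with proportional
  hazards (the source states none);
* missingness completely at random (the source reports only counts);
* covariates drawn independently of genotype from the validation-cohort
  marginals (an optional hook lets one variant shift the stage distribution
  to exercise confounding adjustment);
* one global seed; each stage draws from a substream derived
  deterministically from it, so a run is a pure function of the seed.

Defaults state the world the pipeline targets: 805 samples, 55 variants
with MAFs spread over 0.05–0.48, 75% baseline responder rate (127/170
responders among neoadjuvant patients), baseline hazard 0.003
events/month (~30% cumulative recurrence over the 120-month horizon),
censoring 0.005/month (mean follow-up near the reported ~76 months),
0.6% missing calls (257/44,275), and arm/stage/grade/receptor/subtype
marginals matching the validation cohort's published composition.

What the generator does *not* emulate: linkage disequilibrium between
variants, population structure, competing risks, informative censoring,
genotype-dependent missingness. A green test therefore establishes that
the statistics and plumbing behave correctly under the stated model — not
that the model captures every feature of real cohort data.

One power-related choice in the *test fixtures*: planted-effect cohorts
use a baseline responder rate of 0.5 rather than the cohort-like 0.75,
because at 0.75 a planted OR of 3–6 saturates (response probabilities
0.9+) and detection measures the ceiling, not the code. The generator
default remains 0.75.

## Known limitations

* The QC cascade implements the three stated filters only; the source's
  own arithmetic (7539 MAF-passing − 842 HWE − 432 missing) does not reach
  its final 5875-variant set, and the extra, unenumerated filters are out
  of scope. Whether HWE exclusions were computed before or after the MAF
  cut is also unstated; this package computes them after (the verdict
  precedence records MAF first).
* The pooled log-rank across molecular-subtype strata is implemented as
  per-subtype log-rank tests plus the arm-stratified permutation test; the
  exact pooling used at the source is unstated.
* Cohort-level findings (e.g. a specific variant's HR of 2.58, per-subtype
  p-values, the 18,245-variant discovery) require the undeposited
  patient-level data and are covered only by printed-table anchors and
  property suites.
* One published genotype-count row (rs2032583) is internally inconsistent:
  its printed counts give a MAF that rounds to 0.11, not the printed 0.10.
  The recomputed value is what the test suite asserts.
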