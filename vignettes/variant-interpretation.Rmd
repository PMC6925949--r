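---
title: "Interpreting gene-panel variants in non-familial epilepsy cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting gene-panel variants in non-familial epilepsy cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivar)
```

## The problem

Exome screens of adult, non-familial epilepsy patients produce hundreds of
thousands of variant calls, almost all of which are common polymorphisms,
technical artifacts, or changes in genes with no established link to
epilepsy. epivar implements the interpretation layer that sits between an
annotated variant table and a clinical-style cohort summary: which calls
are credible candidates, which of those are Pathogenic or Likely pathogenic
(P/LP) under the ACMG/AMP framework, and what fraction of patients carry at
least one retained P/LP (the *diagnostic yield*), overall and by seizure
onset age and drug-response group.

The package assumes variant calling and functional annotation have already
happened (BWA/GATK/SnpEff-style pipelines are out of scope); its inputs are
tabular annotations — consequence class, read depth, genotype, population
allele frequencies, calls from eleven in-silico deleteriousness predictors,
ClinVar/HGMD assertions, and a small set of curated knowledge flags.

## The filter cascade

Candidate reduction is a conjunction of five stateless predicates, applied
in a fixed order only so that failures are attributed to a single step:

1. **Depth**: read depth ≥ 30× (`min_depth`, inclusive). Calls without a
   depth fail with reason `no-depth`.
2. **Consequence**: frameshift, nonsense, missense, in-frame indel, or
   canonical splice site. Synonymous and other classes fail.
3. **Panel**: the gene is one of the 178 panel symbols (105 epilepsy genes,
   73 neurodevelopment-associated genes). Matching is exact and
   case-sensitive; the historical symbol GPR98 carries the alias ADGRV1 for
   metadata lookups only.
4. **Frequency**: any reference-panel minor-allele frequency *strictly*
   above 1% (`maf_threshold`) excludes the variant; a frequency exactly at
   the threshold, or absence from every panel, passes. The strict
   inequality mirrors the "greater than 1% excluded" convention.
5. **Deleteriousness vote**: at least 2 of 9 voting units
   (`min_deleterious_votes`) call the variant deleterious.

Because each predicate is pure, the survivor set is invariant under
permutations of the cascade order; the test suite asserts this by
evaluating the five predicates independently and in shuffled sequential
order on randomly generated cohorts, along with idempotence and
distribution over cohort union.

### The 9-unit ensemble vote

Eleven predictors are consulted: PolyPhen-2 HDIV and HVAR, SIFT,
MutationTaster, MutationAssessor, LRT, FATHMM, PROVEAN, MetaSVM, MetaLR,
and GERP++. The two PolyPhen-2 scores and the two meta scores are each
strongly correlated within their pair, so each pair is collapsed into a
single voting unit, leaving 9 units. Design choices here were genuinely
open:

* **Within-pair combination.** A pair votes deleterious when *either*
  member does (`pair_rule = "either"`). The OR-combination cannot silently
  discard a damaging signal from one member of the pair; the
  AND-combination is available as `pair_rule = "both"` for sensitivity
  analyses.
* **GERP++ threshold.** GERP++ is a conservation score without a
  categorical call; the unit votes deleterious at RS ≥ 4.4
  (`gerp_deleterious_cutoff`), a widespread dbNSFP convention. The cutoff
  is configurable because no single value is canonical.
* **Missing calls never vote**, in either direction. Imputing a
  deleterious call would manufacture evidence; imputing a tolerated call
  would destroy it.

### Database reconciliation

ClinVar and HGMD assertions are reconciled to one of
`consistent_pathogenic`, `consistent_benign`, or `uncertain` (any
disagreement, or no record at all, is uncertain). Reconciliation
*annotates* rather than filters: its output drives the reputable-source
evidence codes (PP5/BP6) downstream, because classified-variant sets in
practice retain discordant variants rather than dropping them.

## Case-control association and PS4

Control populations are represented by a local frequency table emulating
KRGDB/ExAC lookups. For each surviving variant:

* case alternate alleles are counted over carriers (heterozygote 1,
  homozygote 2) against a case allele number of twice the patient count
  (486 for a 243-patient cohort);
* control counts are reconstructed as
  `control_alt = round(af × allele_number)` (round half to even), with a
  default control allele number of 121,412 when the table does not state
  one;
* the odds ratio is the cross-product ratio, with the Haldane–Anscombe
  +0.5 correction applied to all four cells whenever any cell is zero. A
  variant *absent* from the control panel has a missing OR rather than an
  inflated corrected one — absence of lookup data is not evidence of
  absence in controls;
* the confidence interval is Woolf's log-normal interval,
  `exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d))`. The published table names no
  CI method; Woolf is the standard for allele-count odds ratios and
  reproduces the characteristic asymmetric intervals. The simulation test
  checks its type-I behaviour: at a true OR of 1 with 486 case and 121,412
  control alleles at frequency 0.001, the 95% interval excludes 1 in about
  5% of 10,000 replicates (5.7% at the frozen seed, within the ±1.5
  percentage-point band).

**PS4** (case-control prevalence evidence) fires when the OR exceeds 5.0
(`or_threshold`) *and* the CI excludes 1.0. A missing OR never fires PS4.

The individual published ORs are not reproducible from printed data (the
exact control counts behind each "adjusted" ExAC frequency were not
published), so the printed values serve as goldens for the PS4 decision
logic only, never for the arithmetic.

## ACMG evidence assignment and combination

Evidence codes divide into computed and curated:

* computed — PVS1 (null variant in a loss-of-function-mechanism gene),
  PS4, PM2 (absent from all frequency panels), PP3 (vote ≥ threshold),
  PP5/BP6 (reconciled database assertions), BA1 (any panel frequency
  > 5%), BP4 (no deleterious and ≥ 2 tolerated votes);
* curated, input via knowledge flags and never inferred — PS1, PS3, PM5,
  PM6. PS2 (confirmed de novo) is never auto-assigned: cohorts without
  parental samples can at most *assume* de novo status (PM6), driven by
  the `assumed_de_novo` flag.

PP5/BP6 are retained (behind `use_pp5`) because published classification
tables of this era use them, despite their later deprecation in the field.

`combine_evidence()` transcribes the ACMG/AMP combining rules over
strength counts and returns one of the five classes. Conflicting evidence
(a pathogenic-side and a benign-side rule firing together) yields
uncertain significance with a `conflict` flag — the guideline's prose on
conflicts is ambiguous, and the conservative collapse to VUS never
promotes a variant. The engine is verified three ways: the 26 published
criteria sets reproduce their printed verdicts (3 Pathogenic, 23 Likely
pathogenic); an independently coded literal transcription of the rules
agrees over every enumerable small evidence set; and adding
pathogenic-side evidence never demotes a verdict.

## Cohort analytics

* **Onset strata**: infantile ≤ 1 year, childhood 2–18, adulthood ≥ 19.
  The boundary at 19 is forced by recounting the published cohort table:
  a patient with onset at 19 must fall in adulthood for the printed 16/109
  stratum to hold.
* **Recessive-heterozygote exclusion**: a lone heterozygous P/LP in a
  recessive-inheritance gene does not satisfy the inheritance model and is
  excluded from yield (not re-classified). Two or more distinct
  heterozygous P/LPs in the same recessive gene in one patient are flagged
  as a candidate compound-heterozygote pair and retained; copy-number
  based confirmation is out of scope.
* **Yields**: a patient counts once regardless of P/LP count; stratum and
  group denominators come from the full patient table, or from explicit
  `cohort_denominators()` when (as with the packaged fixture) only the
  positive patients are tabulated. Percentages display at one decimal,
  rounded half up, matching clinical-report convention (13.2%, 14.7%,
  53.1%, ...).
* **Lesional fraction**: etiologies are free text with the reserved token
  `"Non-lesional"`; anything else counts as lesional.
* **Group contrasts**: Fisher's exact test for categorical contrasts and
  the equal-variance Student's t for continuous ones, via the standard
  `stats` implementations.

```{r fixture-yield}
rep <- diagnostic_yield(load_fixture_cohort(), fixture_patients(),
                        denominators = cohort_denominators())
rep
```

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the screen so every stage is
testable without any download: 243 patients by default, onset ages drawn
in 8:126:109 stratum proportions, half drug-resistant, ~30 background
calls per patient drawn from a shared site pool, and 32 planted causal
variants in 32 distinct patients (matching the published positive count,
so the expected yield is 13.2%).

Background sites each carry one built-in reason to fail the cascade (low
depth, non-disrupting consequence, off-panel gene, common frequency, or a
sub-threshold vote). Planted variants follow one of three evidence
templates mirroring the published criteria sets: a known-rare missense
with case-control evidence ({PS4, PM6, PP3, PP5} → likely pathogenic,
weight 0.6), a novel missense ({PM2, PM6, PP3, PP5} → likely pathogenic,
0.25), and a null variant in an LOF-mechanism gene
({PVS1, PS3, PM2, PM6, PP3} → pathogenic, 0.15). Planted control
frequencies are ≤ 10⁻⁵ or absent; planted genes are drawn from
autosomal-dominant panel genes so the recessive-heterozygote exclusion
cannot silently remove them.

All randomness flows through one integer seed, split into fixed per-stage
substreams drawn up front, so adding a later stage never perturbs earlier
draws and the site pool shared between the variant table and the frequency
table is identical by construction.

What the generator does *not* emulate: linkage structure, sequencing
error, annotation disagreement between predictors correlated with true
effect, somatic mosaicism, and the long tail of borderline evidence
profiles seen in real cohorts. Passing end-to-end recovery (sensitivity
≥ 0.9, false-discovery proportion ≤ 0.1 over 20 seeds) therefore shows the
pipeline is internally consistent with its own rules, not that those rules
are clinically sufficient.

## Numerical choices and degenerate inputs

* Frequency rounding in control-count reconstruction is round half to
  even (the R default), documented because counts of 0.5 arise at rare
  frequencies.
* Report percentages round half up at one decimal.
* Zero-cell 2×2 tables take the Haldane–Anscombe correction; an all-zero
  table is an error, as is a case margin of zero.
* Empty inputs (zero variants, zero patients, zero assignments) produce
  structurally valid empty outputs throughout; the generator validates
  impossible profiles (e.g. a causal template with a zero probability of
  deleterious calls) at spec construction.
* Problem sizes in the shipped tests — cohorts of a few hundred variants
  for property checks, 10,000 simulated tables for CI coverage, 20 seeds
  of the full 243-patient cohort for recovery — were chosen as the
  smallest sizes at which the checked properties are statistically
  meaningful.

## Known limitations

* The transcript set against which canonical-splice-site status is judged
  is whatever the upstream annotator used; the package trusts the
  consequence column.
* Compound-heterozygote detection is genotype-based (no phasing, no CNV
  support); it flags candidates rather than confirming trans
  configuration.
* "Adjusted" control allele frequencies are consumed as plain
  frequencies; no population re-weighting is attempted.
* No Bayesian point-based ACMG refinement and no gene-specific (VCEP)
  rule customisations; no multiple-testing correction is applied to the
  OR screen, matching the screen design the package models.
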