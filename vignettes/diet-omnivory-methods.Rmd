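---
title: "Methods: filtering, consolidation and the coefficient of omnivory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, consolidation and the coefficient of omnivory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietbreadth)
```

## The problem

Gut-content metabarcoding of an omnivorous insect yields, per individual,
read counts for plant and metazoan taxa from several amplicon markers of
unequal taxonomic resolution. Three features make the downstream analysis
non-trivial: the predator's own (conspecific) DNA dominates the metazoan
markers; laboratory contamination shows up in PCR negative controls and at
trace level in field samples; and the same ingested taxon may be reported
at species rank by one marker and only at genus rank by another.
`dietbreadth` implements the rule-based cleanup, the multi-marker
consolidation, the descriptive diet metrics, and a resampling framework for
the coefficient of omnivory.

## Data model

A lineage is a contiguous prefix of the seven Linnaean ranks
(kingdom ... species); its identity is the full rank tuple, never just the
deepest label, so homonyms across kingdoms cannot collide. A detection is
one (sample, marker, lineage, reads) row; duplicate rows for one triple are
summed (classifiers often split a taxon across sequence variants). Months
are integers and (year, month) is the temporal stratum key everywhere.

## Filters and their fixed order

Each rule partitions its input into retained and removed records and
returns a per-sample report; retained + removed always reconciles exactly
with the input, and each rule is idempotent.

1. **Self-host masking.** A record is removed when its lineage matches a
   host lineage by prefix at the *coarser* of the two resolutions: a
   genus-level record falls to a species-level host because conspecific
   reads frequently classify only to genus or family. Masking at the
   host's family is available (`mask_family = TRUE`) but off by default,
   since it can swallow true congeneric or confamilial prey.
2. **Negative-control thresholds.** Per (marker, lineage) seen in the
   controls, field records with reads at or below the control maximum are
   removed. Ties are removed: "lower than the controls" is ambiguous at
   equality and the conservative reading discards. The comparison is per
   marker because contamination is assay-specific.
3. **Singletons.** Records with exactly one read are removed. A sample
   whose records are all singletons remains in the cohort with zero
   detections (it becomes "undetected", which is information).
4. **RRA threshold.** Within each (sample, target group), pooling the
   group's markers, records below 1% relative read abundance are removed
   with a strict `<` (so exactly 1% survives). Abundances are not
   re-normalized afterwards. Pooling per (sample, marker) is available by
   configuration.
5. **Rank inclusion.** The statistics dataset keeps genus- and
   species-level entries; the pre-rank dataset is kept for resolution
   profiling.

The order is part of the contract: applying the RRA cutoff before
singleton removal would change denominators, and host reads must leave
before any relative measure is computed. The source study does not state
its filter order or its tie rule; both are fixed here by decision and
documented rather than inferred.

## Multi-marker consolidation

Within a sample and target group, records with identical lineages pool
(reads summed, markers unioned). Then every lineage that is a strict
ancestor of exactly one *maximal* lineage in the set merges into it; a
lineage compatible with two or more non-nested finer lineages — say genus
*Pteris* next to *P. cretica* and *P. vittata* — is an **ambiguous parent**
and is retained as its own entry. Apportioning its reads among the children
would require an abundance model the data do not support, and published
occurrence tables in this field display genus- and species-level entries
side by side. The "unique maximal extension" formulation is the
order-independent closure of pairwise merging: chains (family → genus →
species) collapse into the leaf regardless of input order, reads are
conserved, and consolidation is idempotent. Merging never crosses target
groups, and equal-rank label conflicts (two species under one genus from
different markers) are retained as separate entries.

## Diet metrics

- **RRA%** is per (sample, target group); each vector sums to 100 within
  1e-9.
- **FOO%** divides a taxon's occurrence count by a *stated* denominator
  (e.g. the 70 field samples). The genus roll-up truncates species to their
  genus and counts a genus and its species once per sample.
- **Richness/Shannon** use occurrence counts with the natural logarithm;
  the published per-period tables print H = 0.69 for two equally frequent
  taxa, which is ln 2 and fixes the base empirically. Period summaries are
  computed on occurrence counts pooled over a period's individuals —
  presence per individual, not reads — because read depth is
  marker-confounded.
- **Diet states**: plant-only s = 1, both s = 0.5, animal-only s = 0,
  neither undetected (excluded from CO but reported).
- **Hellinger + Bray–Curtis** are provided as utilities for community
  composition; the Bray–Curtis computation is delegated to vegan behind the
  package's surface, with zero-sum rows flagged and undefined pairs set to
  0 with a warning.

## The coefficient of omnivory

With `P = Σ s_i` and `Z = Σ (1 − s_i)` over detected individuals,
`CO = P / (P + Z)` equals the mean of `s` (since p + z = 1 per
individual), which the implementation exploits: a stratified bootstrap
replicate reduces to a stratified mean, making the B = 2000 default
essentially free.

**Bootstrap CI.** Individuals are resampled with replacement within each
stratum at the stratum's own size, preserving the sampling design.
Schemes: month × year (default; the two seasons are distinct temporal
strata), month × sex, month only, none. The CI is the percentile interval
(2.5th–97.5th): the simplest scheme consistent with a statistic bounded in
[0, 1]; the source study does not state its interval type. A degenerate
replicate with P + Z = 0 cannot occur, because detected individuals always
carry p + z = 1. Undetected individuals never enter resampling.

**Permutation test.** The statistic is `T = CO_F − CO_M`. Sex labels are
shuffled only within constraint strata (default month × year; month-only
matches the looser wording "within months"), preserving seasonal structure
while breaking the sex–diet association. The Monte-Carlo p-value uses the
add-one correction `p = (1 + #{|T_b| ≥ |T_obs|}) / (B + 1)`, so
`p ≥ 1/(B+1)`; ties count as exceedances (with a 1e-12 float guard), which
is the standard, slightly conservative choice given that `T` is highly
discrete on scores {0, 0.5, 1}. For tiny strata, `exact = TRUE` enumerates
all distinct within-stratum label assignments (guarded at 2e5) and returns
the exact tail proportion.

**Stratum QC** flags strata with n ≥ 5 as `ok`, 3 ≤ n < 5 as `acceptable`,
n < 3 as `small`, and checks the design guidelines: ≥ 3 sampling dates,
≥ 50 individuals, both sexes represented.

**Randomness contract.** Every stochastic function takes an explicit
integer seed and calls `set.seed()` at entry, so identical seed + input is
bit-reproducible per platform. The pipeline derives its permutation seed as
`seed + 1` from the single run seed.

## The synthetic cohort: what it emulates, what it does not

`cohort_config()` defaults *are* the stated world: 7 (year, month) periods
of 10 individuals; female probability 43/70; state probabilities
(50, 15, 4, 1)/70 for (plant-only, both, animal-only, undetected) — the
detected part implies CO ≈ 0.833; 1–9 plant taxa per plant-feeding
individual via a truncated geometric (mean ≈ 2, matching the reported mean
for strict plant-feeders; the per-individual distribution beyond the 1–9
range is not published, so the geometric is a package choice); 1–3 metazoan
taxa with weights 0.65/0.30/0.05 (65% of predation events involve a single
taxon); marker detection probabilities 0.9/0.75 (plants) and 0.9/0.45
(metazoans) with species-resolution probabilities 0.52/0.25 and 0.4/0.2 —
the plant primary marker resolves species in ~52% of detections, roughly
double its partner, so consolidation gains are visible; 85% of each
sample's metazoan reads assigned to the conspecific host (samples without
true prey get a fixed block of pure host signal), reproducing the >80%
read loss to self-host masking; negative-control contaminants (a wheat
lineage on the plant marker, a human lineage on both COI assays) injected
into field samples below the control maximum; and sporadic single-read
artifacts.

True-record reads are log-normal, clamped to [600, 3000]. The clamp is a
deliberate sharpness device: with at most 18 true records per (sample,
group), the worst-case share is 600/(600 + 17·3000) ≈ 1.16% > 1%, so every
true record provably survives the singleton, negative-control and RRA
rules, and the filter-recovery tests can demand exactly 100% artifact
removal with 0% true-record loss. A true taxon missed by every marker's
detection draw is forced into one observation on the group's primary
marker, so declared diet states are always realizable and the generator's
state-probability contract holds exactly.

What the generator does **not** emulate: sequence-level error (chimeras,
index hopping), correlated taxon choice across individuals (seasonal
turnover), marker-specific amplification bias beyond a detection
probability, cross-kingdom homonyms, and reference-database gaps. A green
recovery test therefore establishes that the *rules* are implemented
exactly as stated, not that the rules are sufficient for any particular
real dataset. With `noiseless = TRUE` both markers always detect and the
primary markers always resolve species, making consolidated sets equal to
truth sets exactly — the configuration used for the recovery acceptance
test; the default (noisy) configuration is scored by prefix-matching
(a genus-level consolidated entry counts as recovering its species), with
exact-match rates reported separately.

## Numerical choices and degenerate inputs

- Percentages are computed in double precision and rounded only for
  display (2 decimals); RRA sums are checked to 1e-9.
- Quantiles for the percentile CI use R's default type-7 rule; on the
  highly discrete bootstrap distributions of small cohorts, different
  schemes can land on identical order statistics.
- All-zero count vectors return richness 0 and Shannon 0 with
  `defined = FALSE` rather than NaN; zero-total RRA scopes yield no rows;
  an empty record set passes through every filter with a zero report.
- Expected chi-squared cells below 5 warn (the conventional exact-test
  fallback is out of scope); a zero expected cell errors.
- No continuity correction in the chi-squared test: the published df = 1
  statistic equals the uncorrected value, fixing the choice empirically.

## Known limitations

- The below-family inclusion rule and the 1% RRA cutoff are conventions of
  the source protocol, not estimated; sensitivity to them is the user's
  responsibility (both are parameters).
- The permutation test is conservative for very small or single-sex strata
  (such strata contribute no label variation and are logged).
- FOO and CO treat detection as binary evidence of ingestion; secondary
  predation and environmental contamination below the filter thresholds
  are indistinguishable from diet.
- Consolidation resolves ambiguity structurally, never by abundance; a
  coarse lineage above two children remains its own occurrence, which can
  inflate richness by one per ambiguous parent relative to a
  read-apportionment approach.
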