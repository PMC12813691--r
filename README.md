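# dietbreadth

Downstream analysis of dietary (gut-content) metabarcoding for omnivorous
arthropods.

Field studies of omnivores such as the tarnished plant bug (*Lygus
lineolaris*) sequence short plant and metazoan barcodes (e.g. trnL P6-loop,
ITS2, two COI assays) from individual guts and classify the reads to taxa.
`dietbreadth` starts where the classifier stops: it takes long-format
detection tables (sample × marker × lineage × reads), applies the explicit
rule-based post-classification filters, merges detections across markers
into unique ingested taxa per individual, computes the descriptive diet
statistics, and quantifies where a population sits on the
phytozoophagous continuum with the **coefficient of omnivory**

```
CO = P / (P + Z),   P = Σ p_i,  Z = Σ z_i
```

where each detected individual scores `p_i = 1` (plant detections only),
`p_i = 0.5` (both plant and animal), or `p_i = 0` (animal only), and
`z_i = 1 − p_i`. CO ranges from 1 (strictly phytophagous) to 0 (strictly
zoophagous). Uncertainty is quantified with a **stratified bootstrap**
(resampling individuals with replacement within month × year strata,
preserving stratum sizes; percentile CI), and sex differences are tested
with a **month-constrained permutation test** that shuffles sex labels only
within temporal strata.

The package covers:

- **I/O** — tab-separated detection, metadata and annotation tables with
  seven-rank lineages (`read_detections()`, `read_metadata()`,
  `read_annotations()`).
- **Filters** — self-host (conspecific) masking by lineage prefix,
  negative-control read thresholds per marker, singleton removal, a strict
  <1% relative-read-abundance cutoff, and a below-family rank-inclusion
  rule; every rule returns an auditable removal report (`filter_chain()`).
- **Consolidation** — merging less resolved lineages into compatible
  higher-resolved ones from complementary markers, keeping ambiguous
  parents separate (`consolidate_all()`).
- **Diet metrics** — RRA%, FOO% (with genus roll-up), richness and Shannon
  diversity (natural log), per-individual diet states, period summaries,
  rank-resolution profiles, co-occurrence, Hellinger + Bray–Curtis
  utilities.
- **Omnivory** — `compute_co()`, `bootstrap_co()`, `permutation_sex_test()`
  (Monte-Carlo or exact enumeration), `stratum_qc()`.
- **Synthetic cohorts** — `generate_cohort()` draws a fully ground-truthed
  cohort (states, taxa, host/contaminant/singleton artifacts) so every
  stage is testable without sequence data; `truth_check()` scores recovery.

## Worked example

```r
library(dietbreadth)

cohort <- generate_cohort(cohort_config(seed = 42))
fc <- filter_chain(cohort$detections, host_lineages = host_lineage(),
                   nc_records = cohort$nc_detections)
for (r in fc$reports) print(r)
#> Filter rule 'self_host': removed 140/558 records (806834/1256247 reads)
#> Filter rule 'negative_control': removed 114/418 records (1967/449413 reads)
#> Filter rule 'singleton': removed 28/304 records (28/447446 reads)
#> Filter rule 'rra': removed 0/276 records (0/447418 reads)

cons <- consolidate_all(fc$statistics, cohort$metadata, default_annotations())
states <- classify_diet_state(cons, cohort$metadata)
table(states$state)
#>   omnivorous phytophagous   zoophagous
#>           17           48            5

bootstrap_co(states, scheme = "month_x_year", B = 2000, seed = 42)
#> Coefficient of omnivory: 0.807 (P = 56.5, Z = 13.5, n = 70)
#>   95% bootstrap CI [month_x_year, B = 2000, seed = 42]: 0.736-0.871

permutation_sex_test(states, B = 10000, seed = 43)
#> Sex difference in CO (F - M): -0.140 (CO_F = 0.735, CO_M = 0.875)
#>   Monte-Carlo (B = 10000) permutation test [month_x_year]: p = 0.077
```

The self-host rule removes 64% of all reads here (>80% of the metazoan
reads — conspecific DNA dominates predator COI data); the remaining
artifacts fall to the negative-control and singleton rules; the filtered
cohort of 70 individuals splits 48/17/5 into plant-only, both, and
animal-only feeders, giving a strongly phytophagous CO of 0.81 whose
bootstrap CI spans 0.74–0.87; the sexes do not differ significantly.

The reference worked examples (embedded published counts, recomputed at
call time) print:

```r
ex <- reference_worked_examples()
ex$co         #> Coefficient of omnivory: 0.833 (P = 57.5, Z = 11.5, n = 69)
ex$diet_test  #> Chi-squared goodness of fit: X2(2) = 50.174, p = 0.000
ex$sex_ratio  #> Sex ratio (proportion male): 0.39 (43 F / 27 M)
              #>   2019: 0.40
              #>   2020: 0.37
              #> Chi-squared goodness of fit: X2(1) = 3.657, p = 0.056
```

## Command line

```sh
Rscript inst/cli/dietbreadth.R simulate --seed 1 --out outdir
Rscript inst/cli/dietbreadth.R run --seed 1 --out outdir
Rscript inst/cli/dietbreadth.R co --states outdir/diet_states.tsv --seed 1
Rscript inst/cli/dietbreadth.R reproduce
```

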