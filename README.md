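# clonetrace

Clonal-evolution analysis for paired diagnosis / remission / relapse
acute myeloid leukemia (AML) exomes, built around the NPM1-mutated
subtype.

When NPM1-mutated AML relapses, two mechanisms are possible. A leukemic
subclone may survive chemotherapy and re-expand (**clonal evolution**:
the diagnosis and relapse exomes share a backbone of somatic mutations
and the founder NPM1 insertion persists), or the original leukemia is
eradicated and a **second de novo leukemia** grows out of persistent
preleukemic clonal hematopoiesis (DNMT3A/TET2/IDH1/2/ASXL1 mutations that
ride through remission at VAF ≈ 40–50%): NPM1 is lost at relapse, almost
no somatic mutation is shared, and remission lasts much longer.
`clonetrace` is for genomics analysts who have per-timepoint variant
calls (VCF or annotated tables) and want the full comparative analysis,
reproducibly and with every stage testable against simulated truth.

## What it computes

* **Filter cascade** — the exome somatic filter set (effect class,
  per-strand read support, common-SNP rule with COSMIC exemption,
  segmental-duplication/repeat flags, 10% VAF floor) with a
  keep-and-flag rescue rule for recurrently mutated cancer genes.
* **Trajectory classification** — each variant becomes
  `PRELEUKEMIC_GERMLINE` (present at remission), `SHARED`,
  `DIAGNOSIS_ONLY` or `RELAPSE_SPECIFIC` from presence thresholds
  (tumor 10%, remission 5%), plus deep-amplicon backtracking of
  relapse-specific mutations down to a 0.5% VAF detection limit.
* **Cohort statistics** — per-gene mutation stability
  (persisted-at-relapse / mutated-at-diagnosis), FLT3-ITD clone identity
  by duplication length, mutation-pattern shift, burden summaries, and
  the copy-number/UPD aberration burden ratio.
* **Mutation spectrum** — six-class A/C-reference substitution spectrum
  under a 20% VAF floor, with Mann–Whitney group comparison.
* **Clinical statistics** — self-contained two-sided Fisher exact test,
  Kaplan–Meier estimation (Greenwood log-log CI) and the two-sided
  log-rank test.
* **Mechanism call** — `SECOND_DE_NOVO` vs `CLONAL_EVOLUTION_RELAPSE`
  vs `AMBIGUOUS` from NPM1 loss and the shared somatic count
  (threshold 3, configurable).
* **Synthetic cohorts** — a read-count-resolution generator with full
  ground truth (binomial reads at 91× exome depth, burden means 9.7 /
  11.4, shared backbone mean 7.6, relapse C>A boost, exponential
  remission medians 30 vs 8 months) validating the pipeline end to end.

## Worked example

The package bundles 24 relapse-associated mutations from six patients
(three NPM1-loss, three NPM1-persistent) with exome VAFs at all three
timepoints and an ultra-deep re-assay of the diagnosis samples:

```r
library(clonetrace)
ex <- backtracking_example()
vt <- classify_trajectories(ex$variants)
table(vt$trajectory, useNA = "ifany")
#> PRELEUKEMIC_GERMLINE     RELAPSE_SPECIFIC               SHARED                 <NA>
#>                    7                   12                    1                    4
```

Seven mutations persist through remission at VAF ≥ 5% — the
preleukemic/clonal-hematopoiesis compartment; twelve are relapse-specific;
the four `NA`s are rows with no timepoint above its presence threshold
(e.g. an 8% relapse VAF). One NPM1-loss patient in detail:

```r
vaf_trajectory_matrix(vt[vt$patient_id == "172L", ])
#>     gene aa_change vaf_dx vaf_rem vaf_rel           trajectory
#> 3 DNMT3A     R882C 0.3846    0.36  0.3846 PRELEUKEMIC_GERMLINE
#> 1 PTPN11      E76A 0.0000    0.00  0.1429     RELAPSE_SPECIFIC
#> 2  RUNX1    S322fs 0.0000    0.00  0.5000     RELAPSE_SPECIFIC
#> 4   NRAS      G13D 0.0000    0.00  0.0800                 <NA>
```

The DNMT3A R882C hotspot is stable across all three timepoints — the
preleukemic clone — while the relapse carries new PTPN11 and RUNX1
drivers: the signature of a second de novo leukemia. Backtracking the
relapse mutations in the ultra-deep diagnosis assay
(`backtrack_relapse_variant(alt_reads, depth)`) reproduces all 24
printed detection calls under the 0.5% LOD with a 3-read floor.

Clinical contrast between the groups:

```r
fisher_exact_two_sided(2, 9, 58, 38)   # second-CR response, loss vs persistent
#> [1] 0.009949049
aberration_ratio(23, 79)$ratio         # aberration events, relapse vs diagnosis
#> [1] 3.4
set.seed(1)
coh <- generate_cohort(11, 95)          # synthetic cohort, medians 30 vs 8 months
clinical_summary(coh$clinical)$logrank
#> log-rank test: chisq = 15.932 (1 df), two-sided p = 6.566e-05
```

## Command line

A thin CLI wraps the main entry points:

```sh
Rscript inst/cli/clonetrace.R simulate --n-loss 10 --n-persistent 10 \
    --seed 1 --outdir cohort
Rscript inst/cli/clonetrace.R classify --variants cohort/variants.csv
Rscript inst/cli/clonetrace.R mechanism --variants cohort/variants.csv \
    --panel cohort/gene_panel.csv
```

(After installation the script also lives at
`system.file("cli", "clonetrace.R", package = "clonetrace")`.)

## Documentation

The methods vignette (`vignettes/clonal-trajectories.Rmd`) describes the
model and its assumptions, every tunable threshold with its default and
rationale, what the synthetic generator does and does not emulate, and
the package's numerical conventions.
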