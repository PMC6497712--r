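---
title: "Tracing clonal evolution in paired leukemia exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing clonal evolution in paired leukemia exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

## The problem

In NPM1-mutated acute myeloid leukemia (AML), the relapse that follows a
complete remission can arise in two fundamentally different ways. Either a
leukemic subclone survives chemotherapy and re-expands — classical clonal
evolution, recognizable by a backbone of somatic mutations shared between
the diagnosis and relapse exomes — or the original leukemia is eradicated
and a *second de novo* leukemia grows out of persistent preleukemic clonal
hematopoiesis (typically marked by DNMT3A, TET2, IDH1/2 or ASXL1 mutations
that ride through remission at near-germline allele fractions). The second
route announces itself by loss of the founder NPM1 mutation at relapse,
near-zero overlap of somatic mutations between the two tumors, and a much
longer remission.

`clonetrace` implements the full comparative analysis for paired
diagnosis / remission / relapse samples: somatic-variant filtering,
temporal trajectory classification, cohort-level stability and spectrum
statistics, low-VAF backtracking, mechanism calling, the clinical
statistics, and a ground-truthed synthetic cohort generator used to
validate every stage.

## Data model

The central container is the `variant_table`: one row per patient and
variant, with 1-based inclusive coordinates and `"-"` alleles for indels
(the annotated-variant-table convention; `normalize_variant_key()` maps
VCF-anchored records onto it so keys from both sources compare equal).
Each timepoint contributes a VAF, a depth and strand-split alt counts; a
missing timepoint is NA, never a fabricated zero, and a zero VAF is an
observation of absence. VAFs are fractions internally and percentages at
every file boundary.

## The filter cascade

`apply_wes_filters()` reproduces a standard exome somatic filter set:
intronic and synonymous calls, variants with fewer than 2 alt reads on
either strand, common SNPs above 0.01% population allele frequency without
a COSMIC entry, segmental-duplication and polymer-repeat loci, and
variants below 10% VAF in the tumor sample are removed, in that fixed
reason order (membership in the kept set is order-independent; only the
reported reason depends on the order). The 0.01% SNP cutoff is unusually
stringent but is the cascade's defining value; it is configurable in
`filter_config()`. Variants in a configurable list of recurrently mutated
cancer genes whose only failure is the common-SNP rule are *rescued*:
kept and flagged for manual review, because a clonal-hematopoiesis hotspot
that persists at remission is easily mistaken for germline by a
tumor/normal caller. Variants that carry VAFs but no strand counts (as
table-sourced calls do) skip the strand predicate with a notice rather
than failing it.

The tumor-side VAF rule is applied to the chosen tumor timepoint only
(diagnosis by default); whether the original analysis applied it per
timepoint is not documented, so this is a configurable choice.

## Trajectory classification

`classify_trajectories()` assigns each variant one of four labels from its
presence pattern: present at remission → `PRELEUKEMIC_GERMLINE`;
otherwise present at diagnosis and relapse → `SHARED`; otherwise
`DIAGNOSIS_ONLY` or `RELAPSE_SPECIFIC`. Presence means VAF at or above
10% for the tumor samples and 5% for remission, plus at least 2 alt reads
per strand where counts exist. The remission threshold is the one
genuinely open parameter: persisting preleukemic mutations sit at 25–37%
remission VAF while a 0.45% remission read-through must count as absence;
5% cleanly separates the regimes and is configurable
(`presence_thresholds()`). Raising it can only move variants out of the
preleukemic label (a tested monotonicity). Germline variants are *not*
distinguished from preleukemic ones — the analysis pools them — but an
informational `germline_like` flag (VAF ≈ 50% everywhere) is emitted.
A variant reaching no threshold anywhere is an error for the scalar
classifier and an NA-with-warning for the table classifier.

`backtrack_relapse_variant()` models the deep-amplicon confirmation assay
(≈3000× with molecular barcodes, limit of detection 0.5% VAF): a variant
is detected when its measured VAF reaches the LOD *and* at least 3
supporting reads are seen. A signal above the read floor but below the
LOD is reported separately (`sub_lod_signal`) rather than silently
dropped or promoted — the bundled worked example contains exactly one
such printed detection (0.2% at 4553 reads), which motivates keeping the
borderline channel explicit.

## Cohort statistics

Per-gene *stability* is the fraction of diagnosis mutations persisting
identically at relapse; a mutation that persists with a different
identity (for example a FLT3 internal tandem duplication whose length
changes, i.e. a distinct ITD clone) counts as changed, not persistent.
Patients with an unknown status at either timepoint leave the
denominator, and the policy is recorded in the output row. Reported
percentages round half-up to integers, matching the convention of the
summaries they reproduce. `pattern_shift()` is true when any panel gene
changes status or identity — loss of the founder NPM1 mutation itself
counts, and zygosity or mutation-type changes participate through the
identity fields; exclude a marker by subsetting before the call.
`aberration_ratio()` consumes pre-counted copy-number/UPD event totals
only; no segmentation is performed.

## Mutation spectrum

Single-nucleotide substitutions collapse onto six classes with an A/C
reference convention (G- and T-reference changes map through the reverse
complement), so `A>C`, `A>T`, `C>A`, `C>G` are the transversions and
`A>G`, `C>T` the transitions. Class frequencies are computed per sample
with a 20% VAF floor (false positives concentrate at low VAF and would
distort the spectrum; this threshold lives in the spectrum module only).
Group comparisons use the two-tailed Mann–Whitney test on per-sample
proportions: exact when both groups have at most eight untied values,
otherwise the tie-corrected normal approximation with continuity
correction. The comparison is unpaired by default, matching the stated
test; a paired Wilcoxon option exists for within-patient
diagnosis/relapse designs, where it is the more appropriate choice.

## Clinical statistics

The stats module is self-contained and oracle-tested rather than
delegated: the two-sided Fisher exact test uses the probability-mass
convention (sum of all same-margin tables no more probable than the
observed one, within 1e-7 relative tolerance) — the convention of R's
`fisher.test`, stated explicitly because mid-p and tail-doubling differ.
`km_estimate()` is the product-limit estimator with Greenwood variance
and log-log confidence bands, chosen for stability at small group sizes;
the median is the first time the curve reaches 0.5 ("not reached" when it
never does) and its CI is read off the band crossings.
`logrank_two_sided()` is the standard one-degree-of-freedom log-rank
test. All three are checked against independent oracles in the suite:
exhaustive hypergeometric enumeration, the survival package, and a
permutation log-rank.

## Mechanism calling

`call_mechanism()` encodes the two-mechanism dichotomy as a pure function
of three evidence fields: NPM1 lost with fewer than 3 shared somatic
mutations (preleukemic/germline excluded) → `SECOND_DE_NOVO`; NPM1
retained with at least 3 → `CLONAL_EVOLUTION_RELAPSE`; anything else →
`AMBIGUOUS` with an explanatory note. No numeric cut-off is stated in the
source analysis; 3 is induced from its reported extremes (persistent
cases share at least three mutations, mean 7.6; loss cases almost none)
and stays configurable. Remission persistence of the preleukemic clone is
reported as supporting evidence but does not gate the verdict, because it
holds in all loss cases yet only 6 of 10 persistent cases.

## The synthetic cohort generator

`generate_case()` and `generate_cohort()` state the world the analysis
assumes, at read-count resolution, with complete ground truth:

* 1–2 preleukemic mutations per patient at clone fractions 0.8–1.0
  (heterozygous VAF 40–50% at all three timepoints);
* the founder NPM1 exon-12 TCTG insertion in every case — shared under
  clonal evolution, diagnosis-only under second de novo;
* leukemic mutations at clone fractions 0.4–1.0 (VAF 20–50%), cleared at
  remission (a residual fraction is a parameter, default 0);
* burden means per group and timepoint of 8.8/9.4 (loss) and 10.6/13.4
  (persistent) — 9.7 and 11.4 overall — with the shared backbone drawn as
  3 + Poisson(4.6) (mean 7.6, minimum 3) in clonal-evolution cases and
  exactly 0 in second-de-novo cases;
* depth Poisson around 91× (exome) or 3000× (amplicon), alt reads
  binomial at the true VAF with a fair strand split; beta-binomial
  overdispersion is available but off by default, as the real data do not
  characterize it;
* substitution classes drawn from a uniform six-class base spectrum, with
  the C>A probability doubled for relapse-private variants;
* exponential remission durations with group medians 30 and 8 months,
  10% administrative censoring (uniform fraction of the event time — the
  real censoring pattern is unknown), and second-CR probabilities 2/11
  and 58/96.

Component Poisson means are derived from the *configured* group means
(not the realized draws), so expected burdens match the configuration
exactly without truncation bias; this is verified by a
law-of-large-numbers test at n = 500 within three standard errors.

What a green test establishes — and what it does not: the generator
draws clone fractions rather than evolving clones, uses one clone
fraction per variant (no subclonal tree), plants a uniform base spectrum
rather than a realistic AML trinucleotide signature, and ignores mapping
artifacts, contamination and copy-number distortion of VAFs. End-to-end
recovery (trajectory labels ≥ 99% for variants planted at VAF ≥ 20%;
mechanism verdicts ≥ 95% over 100 cases) therefore validates the
pipeline's logic under its own stated assumptions, not its robustness to
real-world noise. Two printed quantities are out of the stated world's
reach by construction: the 45%/27% relapse transversion means belong to
the real exomes' transition-heavy spectrum, and with a uniform base the
suite asserts the planted directional C>A enrichment instead. Detection
power for that enrichment at the emulated 10+10 exome design is only
~25–40% (mirroring how close to the significance boundary the original
per-group comparisons sit); the detection-rate invariant is therefore
exercised at the 100-case cohort scale used by the other end-to-end
checks, where measured power is ≈ 97%.

## Numerical choices and degenerate inputs

* Ties in rank tests take mid-ranks; the normal approximation carries a
  continuity correction.
* A 2×2 table with a zero margin returns Fisher p = 1 with a message.
* Zero sequencing depth yields VAF 0 in the generator and an error in the
  backtracker.
* An empty variant table is a valid value everywhere (empty spectra have
  `NA` transversion fraction; zero evaluable patients give `NA`
  stability).
* Indel keys are right-trimmed then prefix-trimmed; full reference-aware
  left-alignment is out of scope since no genome is consulted, and the
  VCF writer uses an `N` anchor base that trimming removes on re-read.

## Worked example

The bundled `backtracking_example()` carries 24 relapse-associated
mutations from six patients. Classifying them labels exactly the seven
mutations with remission VAF ≥ 5% as preleukemic/germline, the ten
mutations absent at diagnosis and remission with relapse VAF ≥ 10% as
relapse-specific, and reproduces all 24 printed ultra-deep YES/NO
backtracking calls under the 0.5% LOD with the 3-read floor (the single
sub-LOD YES through the explicit borderline channel).

```{r example}
ex <- backtracking_example()
vt <- suppressWarnings(classify_trajectories(ex$variants))
table(vt$trajectory, useNA = "ifany")
```

## Known limitations

Annotations (effect, population AF, COSMIC membership) are consumed, not
computed; no subclone deconvolution, phylogenetic reconstruction,
copy-number segmentation or trinucleotide-signature analysis is
attempted, and survival modelling stops at the remission-duration
endpoint (no Cox regression, no overall survival).
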