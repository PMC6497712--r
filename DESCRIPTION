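Package: clonetrace
Title: Clonal Trajectory Analysis of Paired Diagnosis, Remission and
    Relapse Leukemia Exomes
Version: 0.1.0
Authors@R: person("clonetrace", "developers", role = c("aut", "cre"),
    email = "maintainers@clonetrace.dev")
Description: Tools for studying clonal evolution in acute myeloid leukemia
    from paired samples taken at diagnosis, remission and relapse. Implements
    a whole-exome somatic variant filter cascade with a germline rescue rule,
    four-way temporal trajectory classification of variants (preleukemic or
    germline, diagnosis-only, shared, relapse-specific), low-VAF deep-amplicon
    backtracking of relapse-specific mutations into diagnosis samples,
    per-gene mutation stability and mutation-pattern shift statistics,
    transition/transversion spectrum analysis, relapse-mechanism calling
    (clonal evolution versus second de novo leukemia arising from persistent
    clonal hematopoiesis), self-contained clinical statistics (two-sided
    Fisher exact test, Kaplan-Meier estimation, log-rank test), and a
    read-count-resolution synthetic paired-cohort generator with full ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
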