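#' Deep-amplicon backtracking worked example
#'
#' A small bundled dataset of relapse-associated mutations from six
#' patients (three with NPM1 loss at relapse, three with persistent
#' NPM1), each with exome VAFs at diagnosis, remission and relapse plus
#' an ultra-deep amplicon re-assay of the diagnosis sample (coverage 423
#' to 16031 reads) used to backtrack relapse-specific mutations below
#' the exome detection limit.  It exercises the trajectory classifier and
#' [backtrack_relapse_variant()] end to end.
#'
#' One insertion allele in the source table is not machine-readable; a
#' four-base placeholder sequence is used for it (synthetic), which
#' affects neither classification nor backtracking.  `nd` VAF cells
#' ("not detected by exome sequencing") are missing observations.
#'
#' @return list with `variants` (a [variant_table()]) and `ultradeep`
#'   (data.frame with `found_at_diagnosis` = `"YES"`/`"NO"`,
#'   `coverage_ultradeep`, `vaf_pct_ultradeep`, plus patient, key and
#'   group columns).
#' @examples
#' ex <- backtracking_example()
#' classify_trajectories(ex$variants)
#' @export
backtracking_example <- function() {
  path <- system.file("extdata", "ultradeep_backtracking_example.tsv",
                      package = "clonetrace", mustWork = TRUE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  vt <- data.frame(patient_id = raw$patient_id, chrom = raw$chrom,
                   start = as.integer(raw$start), end = as.integer(raw$end),
                   ref = raw$ref, alt = raw$alt, gene = raw$gene,
                   aa_change = raw$aa_change, effect = "other",
                   vaf_dx = .num_or_na(raw$vaf_pct_dx) / 100,
                   vaf_rem = .num_or_na(raw$vaf_pct_rem) / 100,
                   vaf_rel = .num_or_na(raw$vaf_pct_rel) / 100,
                   stringsAsFactors = FALSE)
  ud <- data.frame(patient_id = raw$patient_id, group = raw$group,
                   gene = raw$gene, aa_change = raw$aa_change,
                   found_at_diagnosis = raw$found_at_diagnosis,
                   coverage_ultradeep = as.integer(raw$coverage_ultradeep),
                   vaf_pct_ultradeep = as.numeric(raw$vaf_pct_ultradeep),
                   stringsAsFactors = FALSE)
  list(variants = variant_table(vt), ultradeep = ud)
}
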