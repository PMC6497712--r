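## Somatic variant filter cascade for whole-exome calls, with a
## germline-rescue rule for genes recurrently mutated in cancer.

FILTER_REASONS <- c("INTRONIC", "SYNONYMOUS", "LOW_STRAND_SUPPORT",
                    "COMMON_SNP", "SEGDUP", "REPEAT", "LOW_VAF")

#' Filter cascade configuration
#'
#' Defaults reproduce the standard exome filter set for tumor/remission
#' somatic calls: drop intronic and synonymous variants, variants with
#' fewer than `min_strand_reads` alt reads on either strand, common SNPs
#' above `max_pop_af_without_cosmic` population allele frequency unless
#' catalogued in COSMIC, variants in segmental duplications or polymer
#' repeats, and variants below `min_vaf` in the tumor sample.  The SNP
#' cutoff is 0.01\% (`1e-4` as a fraction): stringent, but it is the value
#' the cascade is defined with; change it via this constructor if needed.
#' `spectrum_min_vaf` is the separate 20\% threshold used only when
#' tallying SNV classes (see [sample_spectrum()]).
#'
#' @param min_vaf minimum tumor VAF (fraction), default 0.10.
#' @param min_strand_reads minimum alt reads required on each strand.
#' @param max_pop_af_without_cosmic population AF cutoff (fraction) above
#'   which a variant without a COSMIC entry is dropped.
#' @param drop_effects effect classes removed outright.
#' @param drop_segdup,drop_repeat,rescue_cancer_genes enable flags.
#' @param spectrum_min_vaf VAF floor for spectrum tallies (fraction).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_vaf = 0.10, min_strand_reads = 2,
                          max_pop_af_without_cosmic = 1e-4,
                          drop_effects = c("intronic", "synonymous"),
                          drop_segdup = TRUE, drop_repeat = TRUE,
                          rescue_cancer_genes = TRUE,
                          spectrum_min_vaf = 0.20) {
  stopifnot(min_vaf >= 0, min_vaf <= 1, min_strand_reads >= 0,
            max_pop_af_without_cosmic >= 0, max_pop_af_without_cosmic <= 1,
            spectrum_min_vaf >= 0, spectrum_min_vaf <= 1)
  structure(list(min_vaf = min_vaf, min_strand_reads = min_strand_reads,
                 max_pop_af_without_cosmic = max_pop_af_without_cosmic,
                 drop_effects = drop_effects, drop_segdup = drop_segdup,
                 drop_repeat = drop_repeat,
                 rescue_cancer_genes = rescue_cancer_genes,
                 spectrum_min_vaf = spectrum_min_vaf),
            class = "filter_config")
}

#' Default rescue gene list
#'
#' Genes recurrently mutated in myeloid and other cancers for which a
#' germline-looking call (common-SNP hit, or persistence at remission) is
#' kept and flagged for manual review instead of being auto-dropped.  The
#' list is an editable default, not a fixed vocabulary.
#'
#' @return character vector of gene symbols.
#' @export
default_rescue_genes <- function() {
  c("NPM1", "DNMT3A", "TET2", "ASXL1", "IDH1", "IDH2", "FLT3", "NRAS",
    "KRAS", "KIT", "TP53", "RUNX1", "WT1", "PTPN11", "BRAF", "NF1",
    "CEBPA", "GATA2", "JAK2", "SF3B1", "SRSF2", "U2AF1", "EZH2", "BCOR",
    "STAG2", "RAD21", "PHF6", "CBL", "MLL", "PAX5", "PTK2B", "NPAT")
}

## per-row failed-predicate matrix in the fixed reason order
.failed_predicates <- function(vt, config, sfx) {
  n <- nrow(vt)
  vaf <- vt[[paste0("vaf_", sfx)]]
  fwd <- vt[[paste0("alt_fwd_", sfx)]]
  rev <- vt[[paste0("alt_rev_", sfx)]]
  fail <- matrix(FALSE, n, length(FILTER_REASONS),
                 dimnames = list(NULL, FILTER_REASONS))
  fail[, "INTRONIC"] <- "intronic" %in% config$drop_effects &
    vt$effect == "intronic"
  fail[, "SYNONYMOUS"] <- "synonymous" %in% config$drop_effects &
    vt$effect == "synonymous"
  counts_known <- !is.na(fwd) & !is.na(rev)
  fail[, "LOW_STRAND_SUPPORT"] <- counts_known &
    (fwd < config$min_strand_reads | rev < config$min_strand_reads)
  fail[, "COMMON_SNP"] <- !is.na(vt$pop_af) &
    vt$pop_af > config$max_pop_af_without_cosmic & !vt$in_cosmic
  fail[, "SEGDUP"] <- config$drop_segdup & vt$in_segdup
  fail[, "REPEAT"] <- config$drop_repeat & vt$in_repeat
  fail[, "LOW_VAF"] <- vaf < config$min_vaf
  attr(fail, "strand_skipped") <- sum(!counts_known)
  fail
}

#' Apply the whole-exome somatic filter cascade
#'
#' Partitions variants into kept and removed sets.  A variant is kept iff
#' it fails no enabled predicate, or it is rescued: a member of the
#' recurrently-mutated-cancer-gene list whose only failure is the
#' common-SNP rule (the germline-looking situation the rescue rule
#' targets) is kept and flagged rather than dropped.  Removal reasons
#' report the first failed predicate in the fixed order
#' INTRONIC, SYNONYMOUS, LOW_STRAND_SUPPORT, COMMON_SNP, SEGDUP, REPEAT,
#' LOW_VAF; kept membership does not depend on that order.  Variants
#' without strand counts skip the strand-support predicate (a notice is
#' emitted), mirroring table-sourced calls that carry VAFs only.
#'
#' @param vt a `variant_table`; every row must carry an observation at
#'   `tumor_timepoint`.
#' @param config a [filter_config()].
#' @param tumor_timepoint `"diagnosis"` or `"relapse"`: the sample whose
#'   VAF and strand counts the tumor-side predicates consult.
#' @return a list of class `filter_result` with elements `kept`
#'   (`variant_table`), `removed` (`variant_table` plus `reason`) and
#'   `rescued` (`variant_table` plus `rescue_note`).
#' @examples
#' vt <- variant_table(data.frame(patient_id = "P1", chrom = "chr1",
#'   start = 1:2, end = 1:2, ref = "C", alt = "A",
#'   effect = c("missense", "synonymous"), vaf_dx = c(0.4, 0.3)))
#' apply_wes_filters(vt)
#' @export
apply_wes_filters <- function(vt, config = filter_config(),
                              tumor_timepoint = "diagnosis") {
  stopifnot(inherits(vt, "variant_table"), inherits(config, "filter_config"))
  sfx <- tp_suffix(tumor_timepoint)
  if (nrow(vt) == 0)
    return(structure(list(kept = vt, removed = cbind(as.data.frame(vt),
                                                     reason = character(0)),
                          rescued = cbind(as.data.frame(vt),
                                          rescue_note = character(0)),
                          tumor_timepoint = tumor_timepoint),
                     class = "filter_result"))
  no_obs <- which(!has_observation(vt, tumor_timepoint))
  if (length(no_obs))
    stop("variant lacks ", tumor_timepoint, " observation: ",
         variant_key_id(vt[no_obs[1], ]))
  fail <- .failed_predicates(vt, config, sfx)
  if (attr(fail, "strand_skipped") > 0)
    message(attr(fail, "strand_skipped"),
            " variant(s) without strand counts: strand-support rule skipped")
  n_fail <- rowSums(fail)
  rescue <- config$rescue_cancer_genes & vt$in_cancer_gene_list &
    n_fail > 0 & n_fail == fail[, "COMMON_SNP"]
  keep <- n_fail == 0 | rescue
  first_reason <- FILTER_REASONS[apply(fail, 1, function(f)
    if (any(f)) which(f)[1] else NA_integer_)]
  removed <- cbind(as.data.frame(vt[!keep, , drop = FALSE]),
                   reason = first_reason[!keep])
  rescued <- cbind(as.data.frame(vt[rescue, , drop = FALSE]),
                   rescue_note = rep("cancer-gene rescue: common-SNP hit kept for manual review",
                                     sum(rescue)))
  structure(list(kept = vt[keep, , drop = FALSE], removed = removed,
                 rescued = rescued, tumor_timepoint = tumor_timepoint),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("filter_result:", nrow(x$kept), "kept,", nrow(x$removed), "removed,",
      nrow(x$rescued), "rescued (tumor timepoint:", x$tumor_timepoint, ")\n")
  if (nrow(x$removed))
    print(table(x$removed$reason))
  invisible(x)
}

#' Identify germline-looking rescue candidates
#'
#' Returns variants in rescue-list genes that look germline: present in
#' the remission sample at a high VAF (clonal-hematopoiesis or true
#' germline regime) or carrying a population allele frequency above the
#' common-SNP cutoff.  Such variants are kept and flagged for manual
#' review, never decided automatically.
#'
#' @param vt a `variant_table`.
#' @param rescue_list gene symbols eligible for rescue (non-empty).
#' @param remission_germline_vaf remission VAF at or above which a variant
#'   looks germline (fraction, default 0.30).
#' @param pop_af_cutoff population AF above which a variant looks like a
#'   common SNP (fraction, default `1e-4`).
#' @return a `variant_table` subset with an added `rescue_note` column.
#' @export
rescue_candidates <- function(vt, rescue_list = default_rescue_genes(),
                              remission_germline_vaf = 0.30,
                              pop_af_cutoff = 1e-4) {
  stopifnot(inherits(vt, "variant_table"))
  if (length(rescue_list) == 0) {
    out <- cbind(as.data.frame(vt[0, , drop = FALSE]),
                 rescue_note = character(0))
    return(out)
  }
  germline_rem <- !is.na(vt$vaf_rem) & vt$vaf_rem >= remission_germline_vaf
  common <- !is.na(vt$pop_af) & vt$pop_af > pop_af_cutoff
  sel <- vt$gene %in% rescue_list & (germline_rem | common)
  note <- paste0("germline-like (",
                 ifelse(germline_rem[sel], "remission persistence",
                        "population AF"),
                 "); flagged for manual review")
  cbind(as.data.frame(vt[sel, , drop = FALSE]), rescue_note = note)
}
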