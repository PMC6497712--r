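## Temporal trajectory classification across diagnosis/remission/relapse,
## and low-VAF deep-amplicon backtracking of relapse-specific variants.

#' Presence thresholds for trajectory classification
#'
#' A variant is "present" at a timepoint when its VAF reaches the
#' threshold for that sample class: `tumor_presence_vaf` for diagnosis and
#' relapse (matching the 10\% exome filter floor) and
#' `remission_presence_vaf` for remission.  The remission default of 5\%
#' separates the clonal-hematopoiesis regime (remission VAFs of 25--37\%
#' for persisting preleukemic mutations) from trace signals well below it
#' (a 0.45\% remission read-through is absence, not persistence).  When
#' strand counts are available, presence additionally requires
#' `min_strand_reads` alt reads per strand.  `deep_lod_vaf` is the
#' detection limit of the deep-amplicon confirmation assay (0.5\%).
#'
#' @param tumor_presence_vaf fraction, default 0.10.
#' @param remission_presence_vaf fraction, default 0.05.
#' @param min_strand_reads integer, default 2.
#' @param deep_lod_vaf fraction, default 0.005.
#' @return list of class `presence_thresholds`.
#' @export
presence_thresholds <- function(tumor_presence_vaf = 0.10,
                                remission_presence_vaf = 0.05,
                                min_strand_reads = 2,
                                deep_lod_vaf = 0.005) {
  stopifnot(deep_lod_vaf >= 0,
            deep_lod_vaf <= remission_presence_vaf,
            remission_presence_vaf <= tumor_presence_vaf,
            tumor_presence_vaf <= 1, min_strand_reads >= 0)
  structure(list(tumor_presence_vaf = tumor_presence_vaf,
                 remission_presence_vaf = remission_presence_vaf,
                 min_strand_reads = min_strand_reads,
                 deep_lod_vaf = deep_lod_vaf),
            class = "presence_thresholds")
}

.present_at <- function(vt, timepoint, thresholds) {
  sfx <- tp_suffix(timepoint)
  thr <- if (timepoint == "remission") thresholds$remission_presence_vaf
         else thresholds$tumor_presence_vaf
  vaf <- vt[[paste0("vaf_", sfx)]]
  fwd <- vt[[paste0("alt_fwd_", sfx)]]
  rev <- vt[[paste0("alt_rev_", sfx)]]
  ok <- !is.na(vaf) & vaf >= thr
  counts_known <- !is.na(fwd) & !is.na(rev)
  ok & (!counts_known | (fwd >= thresholds$min_strand_reads &
                           rev >= thresholds$min_strand_reads))
}

#' Classify the temporal trajectory of variants
#'
#' Assigns each variant one of four labels from its presence pattern
#' across the three timepoints:
#' \describe{
#'   \item{PRELEUKEMIC_GERMLINE}{present at remission -- carried by
#'     clonal hematopoiesis surviving chemotherapy, or germline.}
#'   \item{SHARED}{absent at remission but present at both diagnosis and
#'     relapse -- the persisting leukemic lineage.}
#'   \item{DIAGNOSIS_ONLY}{present only at diagnosis.}
#'   \item{RELAPSE_SPECIFIC}{present only at relapse.}
#' }
#' `classify_trajectory` operates on a single variant (a one-row
#' `variant_table`) and errors when no timepoint reaches its presence
#' threshold; `classify_trajectories` labels a whole table, records
#' unclassifiable rows as `NA` with a warning, and additionally emits a
#' `germline_like` flag (VAF near 50\% at every observed timepoint,
#' informational only -- germline and preleukemic are deliberately pooled).
#'
#' @param variant a one-row `variant_table`.
#' @param thresholds a [presence_thresholds()].
#' @return `classify_trajectory`: a single label string.
#' @export
classify_trajectory <- function(variant, thresholds = presence_thresholds()) {
  stopifnot(inherits(variant, "variant_table"), nrow(variant) == 1)
  lab <- .classify_rows(variant, thresholds)
  if (is.na(lab))
    stop("unclassifiable: no timepoint reaches its presence threshold ",
         "(vaf dx/rem/rel = ",
         paste(signif(c(variant$vaf_dx, variant$vaf_rem, variant$vaf_rel), 3),
               collapse = "/"), ")")
  lab
}

.classify_rows <- function(vt, thresholds) {
  p_dx <- .present_at(vt, "diagnosis", thresholds)
  p_rem <- .present_at(vt, "remission", thresholds)
  p_rel <- .present_at(vt, "relapse", thresholds)
  lab <- rep(NA_character_, nrow(vt))
  lab[p_rem] <- "PRELEUKEMIC_GERMLINE"
  lab[is.na(lab) & p_dx & p_rel] <- "SHARED"
  lab[is.na(lab) & p_dx] <- "DIAGNOSIS_ONLY"
  lab[is.na(lab) & p_rel] <- "RELAPSE_SPECIFIC"
  lab
}

#' @rdname classify_trajectory
#' @param vt a `variant_table`.
#' @return `classify_trajectories`: the input with added `trajectory` and
#'   `germline_like` columns.
#' @export
classify_trajectories <- function(vt, thresholds = presence_thresholds()) {
  stopifnot(inherits(vt, "variant_table"))
  if (nrow(vt) == 0) {
    vt$trajectory <- character(0)
    vt$germline_like <- logical(0)
    return(vt)
  }
  lab <- .classify_rows(vt, thresholds)
  if (anyNA(lab))
    warning(sum(is.na(lab)), " variant(s) unclassifiable: no timepoint ",
            "reaches its presence threshold")
  vafs <- as.matrix(as.data.frame(vt)[, paste0("vaf_", TIMEPOINTS)])
  near_half <- abs(vafs - 0.5) <= 0.1
  vt$trajectory <- lab
  vt$germline_like <- apply(!is.na(vafs) & near_half, 1, all) &
    rowSums(!is.na(vafs)) == 3
  vt
}

#' Count mutations shared between diagnosis and relapse
#'
#' Counts variants labelled `SHARED`; with
#' `exclude_preleukemic = FALSE`, preleukemic/germline variants present at
#' both diagnosis and relapse are counted too.  The exclusive count is the
#' shared *somatic* burden used by the relapse-mechanism rule.
#'
#' @param vt a classified `variant_table` (see [classify_trajectories()]).
#' @param exclude_preleukemic drop preleukemic/germline variants from the
#'   count (default `TRUE`).
#' @param thresholds a [presence_thresholds()] (used to test
#'   diagnosis/relapse presence of preleukemic variants).
#' @return non-negative integer.
#' @export
shared_mutation_count <- function(vt, exclude_preleukemic = TRUE,
                                  thresholds = presence_thresholds()) {
  stopifnot(inherits(vt, "variant_table"))
  if (!"trajectory" %in% names(vt))
    stop("variants are not classified; run classify_trajectories() first")
  n <- sum(vt$trajectory == "SHARED", na.rm = TRUE)
  if (!exclude_preleukemic) {
    pre <- !is.na(vt$trajectory) & vt$trajectory == "PRELEUKEMIC_GERMLINE"
    both <- .present_at(vt, "diagnosis", thresholds) &
      .present_at(vt, "relapse", thresholds)
    n <- n + sum(pre & both)
  }
  as.integer(n)
}

#' Backtrack a relapse-specific variant in a deep-amplicon diagnosis assay
#'
#' Deep amplicon sequencing (about 3000x, molecular barcodes) can confirm
#' whether a relapse-specific mutation was already present in the
#' diagnosis sample down to a 0.5\% VAF.  A variant is `detected` when its
#' measured VAF reaches the limit of detection and at least `min_reads`
#' supporting reads are observed.  A read signal above the read floor but
#' below the LOD is not called detected; it is reported separately via
#' `sub_lod_signal` so that borderline signals can be reviewed manually.
#'
#' @param alt_reads variant-supporting read count.
#' @param depth total read depth (> 0).
#' @param lod limit of detection as a VAF fraction, default 0.005.
#' @param min_reads minimum supporting-read floor, default 3.
#' @return list with `verdict` (`"detected"`/`"not_detected"`), `vaf`,
#'   `alt_reads`, and `sub_lod_signal`.
#' @examples
#' backtrack_relapse_variant(31, 5151)   # detected at VAF 0.6%
#' backtrack_relapse_variant(0, 9660)    # not detected
#' @export
backtrack_relapse_variant <- function(alt_reads, depth, lod = 0.005,
                                      min_reads = 3) {
  stopifnot(length(alt_reads) == 1, length(depth) == 1,
            alt_reads >= 0, lod > 0, lod < 1)
  if (depth <= 0) stop("depth must be positive")
  if (alt_reads > depth) stop("alt_reads exceeds depth")
  vaf <- alt_reads / depth
  detected <- vaf >= lod && alt_reads >= min_reads
  list(verdict = if (detected) "detected" else "not_detected",
       vaf = vaf, alt_reads = alt_reads,
       sub_lod_signal = !detected && alt_reads >= min_reads)
}
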