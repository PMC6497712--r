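## Cohort-level summaries: per-gene mutation stability, FLT3-ITD clone
## identity, mutation-pattern shift, mutation burden, aberration burden.

## round-half-up to match reported integer percentages
pct_round <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Per-gene mutation stability between diagnosis and relapse
#'
#' Stability is the number of diagnosis mutations that persist identically
#' at relapse divided by all mutations present at diagnosis.  Patients
#' with an `na` status at either timepoint are excluded from the
#' denominator.  Persistence requires `mut` status at both timepoints and,
#' when mutation identities are recorded for both, an identical identity;
#' a changed identity (for example a different ITD length) is tallied
#' separately and does not count as persistence.  Gains are counted over
#' patients wild-type at diagnosis.
#'
#' @param panel a `gene_panel` data.frame (see [read_gene_panel()]).
#' @param gene marker name to summarize.
#' @return one-row data.frame: `gene`, `n_dx_mut`, `n_persist`, `n_lost`,
#'   `n_changed_identity`, `n_gained`, `stability` (NA when no evaluable
#'   diagnosis-mutated patient), `denominator_policy`.
#' @examples
#' panel <- data.frame(patient_id = c("A", "B"), gene = "DNMT3A",
#'   status_dx = c("mut", "mut"), status_rel = c("mut", "wt"),
#'   identity_dx = NA, identity_rel = NA, zygosity = NA)
#' gene_stability(panel, "DNMT3A")   # stability 0.5
#' @export
gene_stability <- function(panel, gene) {
  rec <- panel[panel$gene == gene, , drop = FALSE]
  eval <- rec[rec$status_dx != "na" & rec$status_rel != "na", , drop = FALSE]
  dxm <- eval[eval$status_dx == "mut", , drop = FALSE]
  both_id <- !is.na(dxm$identity_dx) & !is.na(dxm$identity_rel)
  persist <- dxm$status_rel == "mut" &
    (!both_id | dxm$identity_dx == dxm$identity_rel)
  changed <- dxm$status_rel == "mut" & both_id &
    dxm$identity_dx != dxm$identity_rel
  lost <- dxm$status_rel == "wt"
  gained <- eval$status_dx == "wt" & eval$status_rel == "mut"
  n_dx <- nrow(dxm)
  data.frame(gene = gene, n_dx_mut = n_dx, n_persist = sum(persist),
             n_lost = sum(lost), n_changed_identity = sum(changed),
             n_gained = sum(gained),
             stability = if (n_dx > 0) sum(persist) / n_dx else NA_real_,
             denominator_policy = "patients with na status at either timepoint excluded",
             stringsAsFactors = FALSE)
}

#' Stability table over all panel markers
#' @param panel a `gene_panel` data.frame.
#' @return data.frame with one [gene_stability()] row per gene present.
#' @export
stability_table <- function(panel) {
  do.call(rbind, lapply(unique(panel$gene), gene_stability, panel = panel))
}

#' Classify a FLT3-ITD diagnosis/relapse pair
#'
#' Internal-tandem-duplication clones are identified by duplication
#' length (with an optional insertion-site tie-break appended as
#' `"len@site"`): the same length at both timepoints is the identical
#' clone, a changed length a distinct clone.
#'
#' @param identity_dx,identity_rel ITD descriptors (e.g. `"48"`), or `NA`
#'   when no ITD is present at that timepoint.  Vectorized.
#' @return character vector over
#'   `{identical, distinct, lost, gained, none}`.
#' @examples
#' classify_itd_pair("48", "48")   # identical
#' classify_itd_pair("48", "21")   # distinct
#' classify_itd_pair(NA, "60")     # gained
#' @export
classify_itd_pair <- function(identity_dx, identity_rel) {
  n <- max(length(identity_dx), length(identity_rel))
  identity_dx <- rep_len(as.character(identity_dx), n)
  identity_rel <- rep_len(as.character(identity_rel), n)
  out <- rep("none", n)
  out[!is.na(identity_dx) & is.na(identity_rel)] <- "lost"
  out[is.na(identity_dx) & !is.na(identity_rel)] <- "gained"
  both <- !is.na(identity_dx) & !is.na(identity_rel)
  out[both & identity_dx == identity_rel] <- "identical"
  out[both & identity_dx != identity_rel] <- "distinct"
  out
}

#' Mutation-pattern shift for one patient
#'
#' `TRUE` when any panel gene changes status (`mut` to `wt` or back) or
#' changes mutation identity between diagnosis and relapse; comparisons
#' with an `na` side are ignored.  Zygosity changes count as identity
#' changes when recorded (switch off with `include_zygosity`).
#'
#' @param patient_records `gene_panel` rows for a single patient.
#' @param include_zygosity count zygosity changes as a shift.
#' @return logical scalar.
#' @export
pattern_shift <- function(patient_records, include_zygosity = TRUE) {
  rec <- patient_records[patient_records$status_dx != "na" &
                           patient_records$status_rel != "na", , drop = FALSE]
  if (nrow(rec) == 0)
    stop("no gene evaluable at both timepoints for patient ",
         paste(unique(patient_records$patient_id), collapse = ","))
  status_change <- rec$status_dx != rec$status_rel
  both_id <- !is.na(rec$identity_dx) & !is.na(rec$identity_rel)
  id_change <- both_id & rec$identity_dx != rec$identity_rel
  any(status_change | id_change)
}

#' Cohort-wide pattern-shift summary
#' @param panel a `gene_panel` data.frame.
#' @return data.frame with per-patient `shift` plus attributes `n_shift`
#'   and `pct_shift` (rounded half-up to an integer percent).
#' @export
cohort_shift <- function(panel) {
  by_pat <- split(panel, panel$patient_id)
  shift <- vapply(by_pat, pattern_shift, logical(1))
  out <- data.frame(patient_id = names(by_pat), shift = unname(shift),
                    stringsAsFactors = FALSE)
  attr(out, "n_shift") <- sum(shift)
  attr(out, "pct_shift") <- pct_round(100 * mean(shift))
  out
}

#' Mutation burden of a case at a timepoint
#'
#' The number of (filtered) variants present at a timepoint, presence
#' judged with the trajectory thresholds ([presence_thresholds()]).
#'
#' @param vt a `variant_table` for one case (post-filtering).
#' @param timepoint `"diagnosis"`, `"remission"` or `"relapse"`.
#' @param thresholds a [presence_thresholds()].
#' @return integer count.
#' @export
mutation_burden <- function(vt, timepoint, thresholds = presence_thresholds()) {
  stopifnot(inherits(vt, "variant_table"))
  if (nrow(vt) == 0) return(0L)
  sum(.present_at(vt, timepoint, thresholds))
}

#' Per-group burden summary
#'
#' @param cases named list of `variant_table`s, one per patient.
#' @param groups character vector parallel to `cases` (e.g. `npm1_loss`
#'   / `npm1_persistent`).
#' @param thresholds a [presence_thresholds()].
#' @return data.frame with mean and median burden per group and timepoint.
#' @export
burden_summary <- function(cases, groups, thresholds = presence_thresholds()) {
  stopifnot(length(cases) == length(groups))
  rows <- list()
  for (tp in names(TIMEPOINTS)) {
    b <- vapply(cases, mutation_burden, numeric(1), timepoint = tp,
                thresholds = thresholds)
    for (g in unique(groups)) {
      bg <- b[groups == g]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, timepoint = tp, n = length(bg),
        mean_burden = mean(bg), median_burden = stats::median(bg),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Chromosomal aberration burden ratio
#'
#' Ratio of chromosomal aberration events (deletions, gains, UPDs) at
#' relapse over diagnosis; only pre-counted event totals are consumed.
#'
#' @param n_dx event count at diagnosis (> 0).
#' @param n_rel event count at relapse.
#' @return list of class `aberration_burden` with `n_events_dx`,
#'   `n_events_rel`, `ratio` (one decimal, as reported) and `ratio_exact`.
#' @examples
#' aberration_ratio(23, 79)$ratio   # 3.4
#' @export
aberration_ratio <- function(n_dx, n_rel) {
  stopifnot(n_dx >= 0, n_rel >= 0)
  if (n_dx == 0) {
    message("aberration ratio undefined: zero diagnosis events")
    ratio <- NA_real_
  } else ratio <- n_rel / n_dx
  structure(list(n_events_dx = n_dx, n_events_rel = n_rel,
                 ratio = pct_round(ratio, 1), ratio_exact = ratio),
            class = "aberration_burden")
}
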