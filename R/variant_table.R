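#' @keywords internal
"_PACKAGE"

## Canonical wide layout: one row per (patient, variant), one set of
## observation columns per timepoint.  A missing observation is NA in the
## vaf column (never zero-filled); depth NA means "counts unavailable"
## (strand-based rules are skipped for such rows).

TIMEPOINTS <- c(diagnosis = "dx", remission = "rem", relapse = "rel")

EFFECT_LEVELS <- c("intronic", "synonymous", "missense", "nonsense",
                   "frameshift", "inframe_indel", "splice", "other")

TRAJECTORY_LEVELS <- c("PRELEUKEMIC_GERMLINE", "DIAGNOSIS_ONLY",
                       "SHARED", "RELAPSE_SPECIFIC")

.obs_cols <- function(tp) {
  sfx <- tp_suffix(tp)
  paste0(c("vaf_", "depth_", "alt_fwd_", "alt_rev_"), sfx)
}

#' Map a timepoint name to its column suffix
#'
#' Timepoints are `"diagnosis"`, `"remission"` and `"relapse"`; the wide
#' variant-table columns use the suffixes `dx`, `rem` and `rel`.
#'
#' @param timepoint character scalar, possibly abbreviated.
#' @return the column suffix as a string.
#' @keywords internal
tp_suffix <- function(timepoint) {
  tp <- match.arg(timepoint, names(TIMEPOINTS))
  unname(TIMEPOINTS[tp])
}

VT_ANNOT_COLS <- c("gene", "aa_change", "effect", "pop_af", "in_cosmic",
                   "in_segdup", "in_repeat", "in_cancer_gene_list")
VT_KEY_COLS <- c("patient_id", "chrom", "start", "end", "ref", "alt")
VT_OBS_COLS <- as.vector(vapply(names(TIMEPOINTS), .obs_cols,
                                character(4)))
VT_COLS <- c(VT_KEY_COLS, VT_ANNOT_COLS, VT_OBS_COLS)

.valid_allele <- function(x) grepl("^([ACGTN]+|-)$", x)

#' Construct a variant table
#'
#' Builds the package's central container: a `data.frame` of class
#' `variant_table` with one row per patient/variant and wide per-timepoint
#' observation columns (`vaf_dx`, `depth_dx`, `alt_fwd_dx`, `alt_rev_dx`,
#' and the `rem`/`rel` counterparts).  Coordinates are 1-based inclusive;
#' `ref = "-"` encodes an insertion anchored at `start` (so `start == end`)
#' and `alt = "-"` a deletion.  VAFs are fractions in `[0, 1]`; an NA VAF
#' means the timepoint was not observed.
#'
#' Missing annotation columns are filled with neutral defaults
#' (`effect = "other"`, `pop_af = NA`, all flags `FALSE`); missing
#' observation columns are filled with NA.
#'
#' @param df data.frame holding at least `patient_id`, `chrom`, `start`,
#'   `end`, `ref`, `alt`.
#' @return a `variant_table`.
#' @examples
#' variant_table(data.frame(patient_id = "P1", chrom = "chr2",
#'   start = 25457243, end = 25457243, ref = "G", alt = "A",
#'   gene = "DNMT3A", aa_change = "R882C", vaf_dx = 0.38))
#' @export
variant_table <- function(df = NULL) {
  if (is.null(df)) df <- data.frame()
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  missing_key <- setdiff(VT_KEY_COLS, names(df))
  if (n > 0 && length(missing_key))
    stop("variant table lacks required columns: ",
         paste(missing_key, collapse = ", "))
  defaults <- list(gene = NA_character_, aa_change = NA_character_,
                   effect = "other", pop_af = NA_real_,
                   in_cosmic = FALSE, in_segdup = FALSE, in_repeat = FALSE,
                   in_cancer_gene_list = FALSE)
  for (col in names(defaults))
    if (!col %in% names(df)) df[[col]] <- rep(defaults[[col]], length.out = n)
  for (col in VT_OBS_COLS)
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, n)
  if (n == 0) {
    for (col in VT_COLS) if (!col %in% names(df)) df[[col]] <- logical(0)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  keep <- c(VT_COLS, setdiff(names(df), VT_COLS))
  df <- df[, keep, drop = FALSE]
  validate_variant_table(df)
  class(df) <- c("variant_table", "data.frame")
  rownames(df) <- NULL
  df
}

#' @rdname variant_table
#' @export
empty_variant_table <- function() variant_table(NULL)

validate_variant_table <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$start > df$end)
  if (length(bad)) stop("start > end at row(s) ", paste(bad, collapse = ", "))
  bad <- which(!.valid_allele(df$ref) | !.valid_allele(df$alt))
  if (length(bad)) stop("malformed allele at row(s) ", paste(bad, collapse = ", "))
  bad <- which(df$ref == df$alt)
  if (length(bad)) stop("ref equals alt at row(s) ", paste(bad, collapse = ", "))
  bad <- which(df$ref == "-" & df$start != df$end)
  if (length(bad)) stop("insertion with start != end at row(s) ",
                        paste(bad, collapse = ", "))
  for (tp in names(TIMEPOINTS)) {
    sfx <- tp_suffix(tp)
    vaf <- df[[paste0("vaf_", sfx)]]
    bad <- which(!is.na(vaf) & (vaf < 0 | vaf > 1))
    if (length(bad)) stop("vaf_", sfx, " outside [0,1] at row(s) ",
                          paste(bad, collapse = ", "))
    dep <- df[[paste0("depth_", sfx)]]
    af <- df[[paste0("alt_fwd_", sfx)]]
    ar <- df[[paste0("alt_rev_", sfx)]]
    bad <- which(!is.na(dep) & !is.na(af) & !is.na(ar) & (af + ar > dep))
    if (length(bad)) stop("alt reads exceed depth (", tp, ") at row(s) ",
                          paste(bad, collapse = ", "))
  }
  n_obs <- rowSums(!is.na(df[, paste0("vaf_", TIMEPOINTS), drop = FALSE]))
  bad <- which(n_obs == 0)
  if (length(bad)) stop("variant with no observation at any timepoint, row(s) ",
                        paste(bad, collapse = ", "))
  invisible(df)
}

#' Observation presence per timepoint
#'
#' An observation exists where the VAF column for the timepoint is non-NA
#' (a VAF of zero is an observation of absence, not a missing sample).
#'
#' @param vt a `variant_table`.
#' @param timepoint one of `"diagnosis"`, `"remission"`, `"relapse"`.
#' @return logical vector along the rows of `vt`.
#' @export
has_observation <- function(vt, timepoint) {
  !is.na(vt[[paste0("vaf_", tp_suffix(timepoint))]])
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x), "variant(s),",
      length(unique(x$patient_id)), "patient(s)\n")
  NextMethod()
}

## subsetting keeps the class
#' @export
`[.variant_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("variant_table", "data.frame")
  out
}
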