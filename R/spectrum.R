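## Single-nucleotide substitution spectrum: six-class collapsing with an
## A/C reference convention, per-sample transversion proportions under a
## 20% VAF floor, and nonparametric group comparison.

SNV_CLASSES <- c("A>C", "A>T", "C>A", "C>G", "A>G", "C>T")
TRANSVERSION_CLASSES <- c("A>C", "A>T", "C>A", "C>G")

.REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Collapse a single-nucleotide substitution into one of six classes
#'
#' Substitutions are strand-collapsed to an A or C reference base:
#' a change whose reference is G or T is mapped through the reverse
#' complement (G>T becomes C>A, T>C becomes A>G, ...), giving the four
#' transversion classes A>C, A>T, C>A, C>G and the two transition classes
#' A>G, C>T.
#'
#' @param ref,alt single bases over A,C,G,T (vectorized, equal length).
#' @return character vector of classes.
#' @examples
#' collapse_snv_class("C", "A")   # "C>A"
#' collapse_snv_class("G", "T")   # "C>A" via reverse complement
#' @export
collapse_snv_class <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  ok <- ref %in% names(.REVCOMP) & alt %in% names(.REVCOMP) & ref != alt
  if (!all(ok))
    stop("not an SNV: ", paste(unique(paste0(ref[!ok], ">", alt[!ok])),
                               collapse = ", "))
  flip <- ref %in% c("G", "T")
  ref[flip] <- .REVCOMP[ref[flip]]
  alt[flip] <- unname(.REVCOMP[alt[flip]])
  cls <- paste0(ref, ">", alt)
  stopifnot(all(cls %in% SNV_CLASSES))
  cls
}

.is_snv <- function(vt) {
  nchar(vt$ref) == 1 & nchar(vt$alt) == 1 &
    vt$ref %in% names(.REVCOMP) & vt$alt %in% names(.REVCOMP)
}

#' Per-sample substitution spectrum
#'
#' Tallies the six substitution classes over the SNVs of one sample that
#' are present at `timepoint` with a VAF at or above `min_vaf`.  The
#' default 20\% floor suppresses low-VAF false positives when estimating
#' class frequencies; indels are excluded.
#'
#' @param vt a `variant_table` for one sample/case.
#' @param timepoint `"diagnosis"`, `"remission"` or `"relapse"`.
#' @param min_vaf VAF floor (fraction), default 0.20.
#' @return list of class `spectrum_counts`: `counts` (named over the six
#'   classes), `n_snv`, `transversion_fraction` (NA when `n_snv` is 0).
#' @export
sample_spectrum <- function(vt, timepoint, min_vaf = 0.20) {
  stopifnot(inherits(vt, "variant_table"), min_vaf >= 0, min_vaf <= 1)
  sfx <- tp_suffix(timepoint)
  vaf <- vt[[paste0("vaf_", sfx)]]
  sel <- .is_snv(vt) & !is.na(vaf) & vaf >= min_vaf
  counts <- stats::setNames(integer(length(SNV_CLASSES)), SNV_CLASSES)
  if (any(sel)) {
    tab <- table(collapse_snv_class(vt$ref[sel], vt$alt[sel]))
    counts[names(tab)] <- as.integer(tab)
  }
  n <- sum(counts)
  structure(list(counts = counts, n_snv = n,
                 transversion_fraction =
                   if (n > 0) sum(counts[TRANSVERSION_CLASSES]) / n
                   else NA_real_),
            class = "spectrum_counts")
}

#' Compare two groups of per-sample transversion fractions
#'
#' Two-tailed Mann--Whitney (Wilcoxon rank-sum) test on per-sample
#' proportions.  The exact rank-sum distribution is used when both groups
#' have at most eight values and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction.  A
#' paired Wilcoxon signed-rank alternative is available for
#' within-patient diagnosis/relapse designs.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @param paired use the paired signed-rank test.
#' @return two-tailed p-value in (0, 1].
#' @examples
#' compare_spectra(c(1, 2, 3), c(4, 5, 6))   # 0.1 (exact)
#' @export
compare_spectra <- function(group_a, group_b, paired = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must contain at least one value")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && !paired &&
    length(group_a) <= 8 && length(group_b) <= 8
  if (paired) exact <- !ties
  p <- suppressWarnings(stats::wilcox.test(group_a, group_b, paired = paired,
                                           exact = exact,
                                           correct = TRUE)$p.value)
  min(p, 1)
}
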