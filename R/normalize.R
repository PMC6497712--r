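#' Normalize a variant key to the anchored 1-based dialect
#'
#' Variant keys use 1-based inclusive coordinates with `"-"` alleles for
#' indels (the convention of ANNOVAR-style variant tables): an insertion has
#' `ref = "-"` and `start = end =` the position of the first inserted base;
#' a deletion has `alt = "-"` and `start`/`end` spanning the deleted bases.
#' Normalization right-trims the common allele suffix, then left-trims the
#' common prefix while advancing `start`, so that keys derived from VCF
#' anchored records and keys read from tables compare equal field-wise.
#' Full reference-aware left-alignment of repeats is not attempted (no
#' genome is consulted); trimming alone makes the two dialects meet.
#'
#' @param chrom contig name.
#' @param start 1-based position of the first `ref` base.
#' @param ref,alt allele strings over A,C,G,T,N (not yet `"-"`-coded) or
#'   already normalized alleles.
#' @return list with fields `chrom`, `start`, `end`, `ref`, `alt`.
#' @examples
#' normalize_variant_key("chr5", 170837542, "C", "CTCTG")
#' # insertion anchored at 170837543: ref "-", alt "TCTG"
#' @export
normalize_variant_key <- function(chrom, start, ref, alt) {
  stopifnot(length(chrom) == 1, length(start) == 1)
  start <- as.integer(start)
  if (ref == "-" || alt == "-") {   # already in anchored dialect
    end <- if (ref == "-") start else start + nchar(ref) - 1L
    return(list(chrom = chrom, start = start, end = end, ref = ref, alt = alt))
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  ## right-trim common suffix
  while (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  ## left-trim common prefix, advancing start
  while (length(r) > 0 && length(a) > 0 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    start <- start + 1L
  }
  if (length(r) == 0 && length(a) == 0)
    stop("ref and alt identical after trimming: not a variant")
  if (length(r) == 0) {              # insertion: anchor at next base
    list(chrom = chrom, start = start, end = start,
         ref = "-", alt = paste(a, collapse = ""))
  } else if (length(a) == 0) {       # deletion
    list(chrom = chrom, start = start, end = start + length(r) - 1L,
         ref = paste(r, collapse = ""), alt = "-")
  } else {                            # SNV / MNV / block substitution
    list(chrom = chrom, start = start, end = start + length(r) - 1L,
         ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
  }
}

#' Format a normalized key as a single id string
#' @param vt a `variant_table` (or data.frame with key columns).
#' @return character vector `chrom:start-end:ref>alt`.
#' @keywords internal
variant_key_id <- function(vt) {
  if (nrow(vt) == 0) return(character(0))
  paste0(vt$chrom, ":", vt$start, "-", vt$end, ":", vt$ref, ">", vt$alt)
}
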