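## Readers and writers for the external representations: annotated variant
## tables (long or wide), VCF triplets, gene-panel matrices, clinical tables.
## VAFs are percent at every I/O boundary and fractions internally.

GENE_PANEL_MARKERS <- c("NPM1", "DNMT3A", "FLT3-ITD", "FLT3-TKD", "NRAS",
                        "IDH1", "IDH2", "MLL-PTD", "ASXL1", "TP53", "RUNX1")

CLINICAL_GROUPS <- c("npm1_loss", "npm1_persistent")

.open_stream <- function(x) {
  if (length(x) == 1 && !grepl("[\n,\t]", x) && file.exists(x))
    return(readLines(x))
  unlist(strsplit(x, "\n", fixed = TRUE))
}

.detect_sep <- function(header) if (grepl("\t", header)) "\t" else ","

.canon_name <- function(x) {
  x <- tolower(gsub("[ .]", "_", x))
  map <- c(chr = "chrom", chromosome = "chrom", aachange = "aa_change",
           cosmic = "in_cosmic", segdup = "in_segdup", "repeat" = "in_repeat",
           cancer_gene = "in_cancer_gene_list", patient = "patient_id",
           sample = "patient_id")
  ifelse(x %in% names(map), map[x], x)
}

.parse_logical <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "yes", "1")] <- TRUE
  out[tolower(x) %in% c("false", "f", "no", "0", "")] <- FALSE
  out
}

.num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c("", "na", "NA", "nd"), NA, x)))

#' Read an annotated variant table
#'
#' Parses a tab- or comma-separated table of annotated variant calls into a
#' [variant_table()].  Two dialects are accepted and auto-detected:
#' \describe{
#'   \item{long}{a `timepoint` column (`diagnosis`/`remission`/`relapse`)
#'     with per-row `vaf_pct`, `depth`, `alt_fwd`, `alt_rev`; rows sharing a
#'     patient and variant key are merged across timepoints.}
#'   \item{wide}{per-timepoint columns `vaf_pct_dx`, `vaf_pct_rem`,
#'     `vaf_pct_rel` (and optional `depth_*`, `alt_fwd_*`, `alt_rev_*`).}
#' }
#' VAF columns are percentages and divided by 100 on read.  Missing
#' observations stay missing: an empty or `nd` VAF cell yields no
#' observation for that timepoint, never a zero.
#'
#' @param x path to a file, or the table text itself.
#' @return a `variant_table` covering all patients in the input.
#' @seealso [write_variant_table()]
#' @export
read_variant_table <- function(x) {
  lines <- .open_stream(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty input: no header row")
  sep <- .detect_sep(lines[1])
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  names(df) <- .canon_name(names(df))
  if (nrow(df) == 0) return(empty_variant_table())
  need <- c("patient_id", "chrom", "start", "end", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table lacks column(s): ",
                         paste(miss, collapse = ", "))

  start <- .num_or_na(df$start); end <- .num_or_na(df$end)
  bad <- which(is.na(start) | is.na(end) | start != round(start) |
                 end != round(end) | start > end)
  if (length(bad))
    stop("malformed coordinates at line(s) ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header line
  bad <- which(!.valid_allele(toupper(df$ref)) | !.valid_allele(toupper(df$alt)))
  if (length(bad))
    stop("malformed alleles at line(s) ", paste(bad + 1L, collapse = ", "))

  out <- data.frame(patient_id = df$patient_id, chrom = df$chrom,
                    start = as.integer(start), end = as.integer(end),
                    ref = toupper(df$ref), alt = toupper(df$alt),
                    stringsAsFactors = FALSE)
  for (col in c("gene", "aa_change"))
    if (col %in% names(df)) {
      v <- df[[col]]
      v[v == ""] <- NA
      out[[col]] <- v
    }
  if ("effect" %in% names(df)) {
    v <- df$effect
    v[v == "" | is.na(v)] <- "other"
    out$effect <- v
  }
  if ("pop_af" %in% names(df)) out$pop_af <- .num_or_na(df$pop_af)
  for (col in c("in_cosmic", "in_segdup", "in_repeat", "in_cancer_gene_list"))
    if (col %in% names(df)) {
      v <- .parse_logical(df[[col]])
      v[is.na(v)] <- FALSE
      out[[col]] <- v
    }

  long <- "timepoint" %in% names(df)
  if (long) {
    vaf_col <- intersect(c("vaf_pct", "vaf"), names(df))[1]
    if (is.na(vaf_col)) stop("long dialect requires a vaf_pct column")
    tp <- vapply(df$timepoint, tp_suffix, character(1))
    vaf <- .num_or_na(df[[vaf_col]]) / 100
    rows <- split(seq_len(nrow(df)),
                  paste(out$patient_id, variant_key_id(out), sep = "|"))
    merged <- lapply(rows, function(idx) {
      rec <- out[idx[1], , drop = FALSE]
      for (i in idx) {
        s <- tp[i]
        prev <- rec[[paste0("vaf_", s)]]
        if (!is.null(prev) && !is.na(prev) && !isTRUE(all.equal(prev, vaf[i])))
          stop("conflicting duplicate observation for patient ",
               rec$patient_id, " at ", variant_key_id(rec), " (", s, ")")
        rec[[paste0("vaf_", s)]] <- vaf[i]
        for (col in c("depth", "alt_fwd", "alt_rev"))
          if (col %in% names(df))
            rec[[paste0(col, "_", s)]] <- .num_or_na(df[[col]][i])
      }
      rec
    })
    out <- do.call(rbind, merged)
  } else {
    for (s in TIMEPOINTS) {
      vcol <- intersect(paste0(c("vaf_pct_", "vaf_"), s), names(df))[1]
      if (!is.na(vcol)) out[[paste0("vaf_", s)]] <- .num_or_na(df[[vcol]]) / 100
      for (col in c("depth_", "alt_fwd_", "alt_rev_")) {
        cc <- paste0(col, s)
        if (cc %in% names(df)) out[[cc]] <- .num_or_na(df[[cc]])
      }
    }
    dup <- duplicated(paste(out$patient_id, variant_key_id(out)))
    if (any(dup)) {
      i <- which(dup)[1]
      stop("duplicate wide-format row for patient ", out$patient_id[i],
           " at ", variant_key_id(out[i, ]))
    }
  }
  variant_table(out)
}

#' Write a variant table
#'
#' Emits the wide CSV dialect read back by [read_variant_table()]
#' (RFC-4180-style, fixed column order, VAFs in percent).  `write` then
#' `read` is the identity on valid tables.
#'
#' @param vt a `variant_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  out <- as.data.frame(vt)[, c(VT_KEY_COLS, VT_ANNOT_COLS), drop = FALSE]
  for (s in TIMEPOINTS) {
    out[[paste0("vaf_pct_", s)]] <- vt[[paste0("vaf_", s)]] * 100
    for (col in c("depth_", "alt_fwd_", "alt_rev_"))
      out[[paste0(col, s)]] <- vt[[paste0(col, s)]]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a diagnosis/remission/relapse VCF triplet
#'
#' Reads up to three single-sample VCF 4.x files for one patient and merges
#' them into a [variant_table()] by normalized variant key
#' ([normalize_variant_key()]; anchored VCF indels become the `"-"`
#' dialect).  Per-sample allelic depths (`AD`) are required; strand-split
#' alt counts are taken from `ADF`/`ADR` when present.  INFO fields
#' `GENE`, `AACHANGE`, `EFFECT`, `POP_AF`, `COSMIC`, `SEGDUP`, `REPEAT`
#' and `CANCER_GENE` are mapped onto the annotation columns when present.
#'
#' @param dx,rem,rel file paths (any may be `NULL` for a missing timepoint).
#' @param patient_id patient identifier for the returned rows.
#' @return a `variant_table`.
#' @export
read_vcf_triplet <- function(dx = NULL, rem = NULL, rel = NULL,
                             patient_id = "patient") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_triplet requires the VariantAnnotation package")
  paths <- list(diagnosis = dx, remission = rem, relapse = rel)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0) return(empty_variant_table())
  info_flag_map <- c(COSMIC = "in_cosmic", SEGDUP = "in_segdup",
                     REPEAT = "in_repeat", CANCER_GENE = "in_cancer_gene_list")
  info_chr_map <- c(GENE = "gene", AACHANGE = "aa_change", EFFECT = "effect")
  recs <- list()
  for (tp in names(paths)) {
    vcf <- suppressWarnings(VariantAnnotation::readVcf(paths[[tp]]))
    n <- length(vcf)
    if (n == 0) next
    rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
    refs <- as.character(VariantAnnotation::ref(vcf))
    alts <- VariantAnnotation::alt(vcf)
    geno <- VariantAnnotation::geno(vcf)
    info <- VariantAnnotation::info(vcf)
    if (!"AD" %in% names(geno))
      stop("missing allelic-depth (AD) field in ", paths[[tp]])
    .info1 <- function(fld, i) {
      v <- info[[fld]][i]
      if (is.list(v) || inherits(v, "List")) v <- unlist(v)[1]
      v
    }
    for (i in seq_len(n)) {
      alt_i <- as.character(alts[[i]])
      ad <- geno$AD[i, 1][[1]]
      if (is.null(ad) || all(is.na(ad)))
        stop("missing allelic-depth (AD) values for record ",
             rownames(rr)[i], " in ", paths[[tp]])
      for (j in seq_along(alt_i)) {
        key <- normalize_variant_key(as.character(rr$seqnames[i]),
                                     rr$start[i], refs[i], alt_i[j])
        dp <- sum(ad)
        altn <- ad[j + 1]
        rec <- list(timepoint = tp, chrom = key$chrom, start = key$start,
                    end = key$end, ref = key$ref, alt = key$alt,
                    raw_pos = rr$start[i], raw_ref = refs[i],
                    depth = dp, alt_n = altn,
                    vaf = if (dp > 0) altn / dp else 0,
                    alt_fwd = NA_real_, alt_rev = NA_real_)
        for (fld in c("ADF", "ADR")) if (fld %in% names(geno)) {
          v <- geno[[fld]][i, 1][[1]]
          if (length(v) >= j + 1)
            rec[[if (fld == "ADF") "alt_fwd" else "alt_rev"]] <- v[j + 1]
        }
        for (fld in names(info_chr_map)) if (fld %in% names(info))
          rec[[info_chr_map[[fld]]]] <- as.character(.info1(fld, i))
        if ("POP_AF" %in% names(info))
          rec$pop_af <- as.numeric(.info1("POP_AF", i))
        for (fld in names(info_flag_map)) if (fld %in% names(info))
          rec[[info_flag_map[[fld]]]] <- isTRUE(info[[fld]][i])
        recs[[length(recs) + 1]] <- rec
      }
    }
  }
  if (length(recs) == 0) return(empty_variant_table())
  long <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  ## contradictory REF at the same raw locus across files
  loci <- split(long$raw_ref, paste(long$chrom, long$raw_pos))
  bad <- names(loci)[vapply(loci, function(x) length(unique(x)) > 1, logical(1))]
  if (length(bad))
    stop("contradictory REF alleles at locus ", bad[1], " across the triplet")

  ids <- paste(long$chrom, long$start, long$end, long$ref, long$alt)
  merged <- lapply(split(seq_len(nrow(long)), ids), function(idx) {
    rec <- data.frame(patient_id = patient_id, chrom = long$chrom[idx[1]],
                      start = long$start[idx[1]], end = long$end[idx[1]],
                      ref = long$ref[idx[1]], alt = long$alt[idx[1]],
                      stringsAsFactors = FALSE)
    for (col in c("gene", "aa_change", "effect", "pop_af", "in_cosmic",
                  "in_segdup", "in_repeat", "in_cancer_gene_list"))
      if (col %in% names(long)) {
        v <- long[[col]][idx]
        v <- v[!is.na(v)]
        if (length(v)) rec[[col]] <- v[1]
      }
    for (i in idx) {
      s <- tp_suffix(long$timepoint[i])
      rec[[paste0("vaf_", s)]] <- long$vaf[i]
      rec[[paste0("depth_", s)]] <- long$depth[i]
      rec[[paste0("alt_fwd_", s)]] <- long$alt_fwd[i]
      rec[[paste0("alt_rev_", s)]] <- long$alt_rev[i]
    }
    rec
  })
  cols <- unique(unlist(lapply(merged, names)))
  merged <- lapply(merged, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[cols]
  })
  variant_table(do.call(rbind, merged))
}

.parse_status <- function(x, what) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^(wt|mut|na)(\\(([^)]*)\\))?$", tolower(x)))
  status <- vapply(m, function(g) if (length(g)) g[2] else NA_character_,
                   character(1))
  if (anyNA(status) || any(!nzchar(status)))
    stop("unknown ", what, " status token: ",
         paste(unique(x[is.na(status) | !nzchar(status)]), collapse = ", "))
  identity <- vapply(seq_along(m), function(i) {
    g <- m[[i]]
    if (length(g) >= 4 && nzchar(g[4])) {
      raw <- regmatches(x[i], regexec("\\(([^)]*)\\)", x[i]))[[1]][2]
      gsub("bp$", "", raw)
    } else NA_character_
  }, character(1))
  list(status = status, identity = identity)
}

#' Read a gene-panel status matrix
#'
#' CSV with columns `patient_id`, `gene`, `status_dx`, `status_rel`, and
#' optional `identity_dx`, `identity_rel`, `zygosity`.  Status tokens are
#' `wt`, `mut`, `na`; a mutation identity (for example an ITD length) may
#' be embedded as `mut(48bp)` or supplied in the identity columns.
#' Unknown status tokens are an error; a gene outside the marker panel
#' raises a warning but the record is kept.
#'
#' @param x path to a file or the CSV text.
#' @return data.frame of class `gene_panel`.
#' @export
read_gene_panel <- function(x) {
  lines <- .open_stream(x)
  lines <- lines[nzchar(trimws(lines))]
  df <- utils::read.table(text = lines, sep = .detect_sep(lines[1]),
                          header = TRUE, colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
  names(df) <- .canon_name(names(df))
  need <- c("patient_id", "gene", "status_dx", "status_rel")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene panel lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0)
    return(structure(data.frame(patient_id = character(), gene = character(),
                                status_dx = character(), status_rel = character(),
                                identity_dx = character(), identity_rel = character(),
                                zygosity = character(), stringsAsFactors = FALSE),
                     class = c("gene_panel", "data.frame")))
  dx <- .parse_status(df$status_dx, "diagnosis")
  rel <- .parse_status(df$status_rel, "relapse")
  out <- data.frame(patient_id = df$patient_id, gene = df$gene,
                    status_dx = dx$status, status_rel = rel$status,
                    identity_dx = dx$identity, identity_rel = rel$identity,
                    zygosity = if ("zygosity" %in% names(df))
                      ifelse(df$zygosity %in% c("", "na", "NA"),
                             NA_character_,
                             tolower(df$zygosity)) else NA_character_,
                    stringsAsFactors = FALSE)
  for (side in c("dx", "rel")) {
    icol <- paste0("identity_", side)
    if (icol %in% names(df)) {
      explicit <- ifelse(df[[icol]] %in% c("", "na", "NA"), NA, df[[icol]])
      out[[icol]] <- ifelse(is.na(out[[icol]]), explicit, out[[icol]])
    }
    bad <- !is.na(out[[icol]]) & out[[paste0("status_", side)]] != "mut"
    if (any(bad))
      stop("mutation identity given for non-mut ", side, " status (patient ",
           out$patient_id[which(bad)[1]], ", ", out$gene[which(bad)[1]], ")")
  }
  unknown <- setdiff(unique(out$gene), GENE_PANEL_MARKERS)
  if (length(unknown))
    warning("gene(s) outside the marker panel kept as-is: ",
            paste(unknown, collapse = ", "))
  structure(out, class = c("gene_panel", "data.frame"))
}

#' @rdname read_gene_panel
#' @param panel a `gene_panel` data.frame.
#' @param path output file path.
#' @export
write_gene_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  sd <- ifelse(!is.na(out$identity_dx),
               paste0(out$status_dx, "(", out$identity_dx, ")"), out$status_dx)
  sr <- ifelse(!is.na(out$identity_rel),
               paste0(out$status_rel, "(", out$identity_rel, ")"), out$status_rel)
  utils::write.csv(data.frame(patient_id = out$patient_id, gene = out$gene,
                              status_dx = sd, status_rel = sr,
                              zygosity = out$zygosity),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with columns `patient_id`, `group` (`npm1_loss` or
#' `npm1_persistent`), `remission_duration_months` (non-negative),
#' `relapse_event` (`TRUE` = relapse observed, `FALSE` = censored) and
#' `second_cr` (`yes`/`no`/`na`).
#'
#' @param x path to a file or the CSV text.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical <- function(x) {
  lines <- .open_stream(x)
  lines <- lines[nzchar(trimws(lines))]
  df <- utils::read.table(text = lines, sep = .detect_sep(lines[1]),
                          header = TRUE, colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
  names(df) <- .canon_name(names(df))
  need <- c("patient_id", "group", "remission_duration_months",
            "relapse_event", "second_cr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0)
    return(structure(data.frame(patient_id = character(), group = character(),
                                remission_duration_months = numeric(),
                                relapse_event = logical(),
                                second_cr = character()),
                     class = c("clinical_table", "data.frame")))
  grp <- tolower(df$group)
  bad <- setdiff(unique(grp), CLINICAL_GROUPS)
  if (length(bad)) stop("unknown group token: ", paste(bad, collapse = ", "))
  dur <- .num_or_na(df$remission_duration_months)
  if (any(is.na(dur) | dur < 0))
    stop("remission_duration_months must be non-negative")
  ev <- .parse_logical(df$relapse_event)
  if (anyNA(ev)) stop("relapse_event must be true/false")
  scr <- tolower(df$second_cr)
  bad <- setdiff(unique(scr), c("yes", "no", "na"))
  if (length(bad)) stop("unknown second_cr token: ", paste(bad, collapse = ", "))
  structure(data.frame(patient_id = df$patient_id, group = grp,
                       remission_duration_months = dur, relapse_event = ev,
                       second_cr = scr, stringsAsFactors = FALSE),
            class = c("clinical_table", "data.frame"))
}

#' @rdname read_clinical
#' @param clin a `clinical_table` data.frame.
#' @param path output file path.
#' @export
write_clinical <- function(clin, path) {
  utils::write.csv(as.data.frame(clin), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a generic report table as CSV
#'
#' Fixed-column-order RFC-4180-style CSV used by the command-line
#' subcommands for audit and summary outputs.
#'
#' @param df any data.frame.
#' @param path output file path.
#' @export
write_report <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
  invisible(path)
}
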