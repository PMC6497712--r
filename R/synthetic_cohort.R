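## Synthetic paired-cohort generator at read-count resolution.  The
## generator's defaults state the world the analysis assumes: one to two
## preleukemic mutations per patient at clone fractions 0.8-1.0 (VAF
## 40-50% at every timepoint), leukemic mutations at clone fractions
## 0.4-1.0 (VAF 20-50%) cleared at remission, diagnosis/relapse burden
## means of 8.8/9.4 (NPM1 loss) and 10.6/13.4 (NPM1 persistent), a shared
## backbone of at least 3 mutations with mean 7.6 in clonal-evolution
## cases and none in second-de-novo cases, binomial read sampling at a
## mean exome depth of 91x (amplicon confirmation 3000x), and a two-fold
## C>A boost on relapse-private substitutions.

PRELEUKEMIC_GENES <- c("DNMT3A", "TET2", "IDH1", "IDH2", "ASXL1")

#' Define a synthetic patient scenario
#'
#' Collects the generative parameters for one simulated patient.  Burden
#' means default per scenario to the group means of the emulated study
#' design: diagnosis/relapse 10.6/13.4 for `clonal_evolution` (NPM1
#' persistent) and 8.8/9.4 for `second_de_novo` (NPM1 loss; the relapse
#' is a new leukemia sharing no somatic mutation with diagnosis).
#'
#' @param scenario `"clonal_evolution"` or `"second_de_novo"`.
#' @param n_preleukemic number of preleukemic mutations; `NULL` draws 1
#'   or 2 with equal probability.
#' @param preleukemic_ccf_range clone-fraction range of the preleukemic
#'   clone (VAF = ccf/2 for heterozygous variants).
#' @param leukemic_ccf_range clone-fraction range of leukemic mutations.
#' @param mean_dx_burden,mean_relapse_burden expected mutation counts per
#'   timepoint; `NULL` = scenario default.
#' @param mean_shared,min_shared shared-backbone size in
#'   `clonal_evolution` cases: `min_shared + Poisson(mean_shared -
#'   min_shared)` mutations (the founder NPM1 insertion included).
#' @param relapse_cA_boost multiplier on the C>A probability for
#'   relapse-private substitutions (default 2).
#' @param wes_depth,deep_depth mean sequencing depths (reads).
#' @param remission_leukemic_ccf residual leukemic clone fraction at
#'   remission (default 0).
#' @param base_spectrum probability vector over the six substitution
#'   classes (default uniform).
#' @param overdispersion beta-binomial overdispersion rho in [0, 1);
#'   0 = pure binomial read sampling.
#' @param homozygous plant variants at VAF = ccf instead of ccf/2
#'   (copy-neutral LOH regime).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param patient_id identifier used in the emitted variant table.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(scenario = c("clonal_evolution", "second_de_novo"),
                               n_preleukemic = NULL,
                               preleukemic_ccf_range = c(0.8, 1.0),
                               leukemic_ccf_range = c(0.4, 1.0),
                               mean_dx_burden = NULL,
                               mean_relapse_burden = NULL,
                               mean_shared = 7.6, min_shared = 3,
                               relapse_cA_boost = 2,
                               wes_depth = 91, deep_depth = 3000,
                               remission_leukemic_ccf = 0,
                               base_spectrum = rep(1 / 6, 6),
                               overdispersion = 0, homozygous = FALSE,
                               seed = NULL, patient_id = "case") {
  scenario <- match.arg(scenario)
  if (is.null(mean_dx_burden))
    mean_dx_burden <- if (scenario == "clonal_evolution") 10.6 else 8.8
  if (is.null(mean_relapse_burden))
    mean_relapse_burden <- if (scenario == "clonal_evolution") 13.4 else 9.4
  stopifnot(length(base_spectrum) == 6, all(base_spectrum >= 0),
            sum(base_spectrum) > 0, relapse_cA_boost > 0,
            wes_depth > 0, deep_depth > 0,
            remission_leukemic_ccf >= 0, remission_leukemic_ccf <= 1,
            overdispersion >= 0, overdispersion < 1,
            min_shared >= 0, mean_shared >= min_shared)
  if (!is.null(n_preleukemic)) stopifnot(n_preleukemic >= 0)
  if (scenario == "second_de_novo") {
    min_shared <- 0
    mean_shared <- 0
  }
  structure(list(scenario = scenario, n_preleukemic = n_preleukemic,
                 preleukemic_ccf_range = preleukemic_ccf_range,
                 leukemic_ccf_range = leukemic_ccf_range,
                 mean_dx_burden = mean_dx_burden,
                 mean_relapse_burden = mean_relapse_burden,
                 mean_shared = mean_shared, min_shared = min_shared,
                 relapse_cA_boost = relapse_cA_boost,
                 wes_depth = wes_depth, deep_depth = deep_depth,
                 remission_leukemic_ccf = remission_leukemic_ccf,
                 base_spectrum = base_spectrum / sum(base_spectrum),
                 overdispersion = overdispersion, homozygous = homozygous,
                 seed = seed, patient_id = patient_id),
            class = "synthetic_scenario")
}

.boosted_spectrum <- function(base, boost) {
  p <- base
  p[SNV_CLASSES == "C>A"] <- p[SNV_CLASSES == "C>A"] * boost
  p / sum(p)
}

.draw_alleles <- function(classes) {
  ref <- substr(classes, 1, 1)
  alt <- substr(classes, 3, 3)
  flip <- stats::runif(length(classes)) < 0.5
  ref[flip] <- .REVCOMP[ref[flip]]
  alt[flip] <- unname(.REVCOMP[alt[flip]])
  list(ref = ref, alt = alt)
}

.sample_reads <- function(true_vaf, mean_depth, rho) {
  n <- length(true_vaf)
  depth <- stats::rpois(n, mean_depth)
  p <- true_vaf
  if (rho > 0) {
    ab <- (1 - rho) / rho
    mid <- true_vaf > 0 & true_vaf < 1
    p[mid] <- stats::rbeta(sum(mid), true_vaf[mid] * ab,
                           (1 - true_vaf[mid]) * ab)
  }
  alt <- stats::rbinom(n, depth, p)
  fwd <- stats::rbinom(n, alt, 0.5)
  cbind(depth = depth, alt = alt, fwd = fwd, rev = alt - fwd)
}

#' Generate one synthetic patient case
#'
#' Plants preleukemic, diagnosis-only, shared and relapse-private
#' mutations per the scenario, then samples read counts: per timepoint,
#' depth is Poisson around the mean depth and alt reads binomial (or
#' beta-binomial) at the true VAF, with a fair binomial strand split.
#' The NPM1 founder insertion (chr5:170837543, TCTG) is planted in every
#' case: shared in `clonal_evolution`, diagnosis-only (lost at relapse)
#' in `second_de_novo`.  All three timepoints are observed for every
#' variant -- absence is a true VAF of zero, not a missing observation.
#' Identical seeds give identical output.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list of class `synthetic_case`: `variants` (a
#'   `variant_table`), `truth` (per-variant intended trajectory, class
#'   and true VAFs), `npm1_status_dx`, `npm1_status_rel`, `scenario`.
#' @export
generate_case <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  if (!is.null(sc$seed)) set.seed(sc$seed)
  n_pre <- if (is.null(sc$n_preleukemic)) sample(1:2, 1) else sc$n_preleukemic
  lambda_pre <- if (is.null(sc$n_preleukemic)) 1.5 else sc$n_preleukemic
  if (sc$scenario == "clonal_evolution") {
    n_shared <- sc$min_shared + stats::rpois(1, sc$mean_shared - sc$min_shared)
    n_dx_only <- stats::rpois(1, max(0, sc$mean_dx_burden - lambda_pre -
                                       sc$mean_shared))
    n_rel_priv <- stats::rpois(1, max(0, sc$mean_relapse_burden - lambda_pre -
                                        sc$mean_shared))
  } else {
    n_shared <- 0L   # the defining property of a second de novo leukemia
    n_dx_only <- stats::rpois(1, max(0, sc$mean_dx_burden - lambda_pre - 1))
    n_rel_priv <- stats::rpois(1, max(0, sc$mean_relapse_burden - lambda_pre))
  }

  runit <- function(range, n) stats::runif(n, range[1], range[2])

  pre_genes <- sample(PRELEUKEMIC_GENES, min(n_pre, length(PRELEUKEMIC_GENES)))
  n_pre <- length(pre_genes)
  n_shared_other <- max(0L, n_shared - 1L)   # NPM1 is one of the shared
  boosted <- .boosted_spectrum(sc$base_spectrum, sc$relapse_cA_boost)
  n_snv <- n_pre + n_shared_other + n_dx_only + n_rel_priv
  cls <- c(sample(SNV_CLASSES, n_pre + n_shared_other + n_dx_only,
                  replace = TRUE, prob = sc$base_spectrum),
           sample(SNV_CLASSES, n_rel_priv, replace = TRUE, prob = boosted))
  al <- .draw_alleles(cls)

  pre_ccf <- runit(sc$preleukemic_ccf_range, n_pre)
  zero <- function(n) rep(0, n)
  rem_ccf <- sc$remission_leukemic_ccf
  ## founder NPM1 exon-12 insertion (type A): present at diagnosis always,
  ## retained at relapse only under clonal evolution
  npm1_rel_ccf <- if (sc$scenario == "clonal_evolution")
    runit(sc$leukemic_ccf_range, 1) else 0
  truth <- data.frame(
    gene = c(pre_genes, "NPM1",
             sprintf("%s_SH%02d", sc$patient_id, seq_len(n_shared_other)),
             sprintf("%s_DX%02d", sc$patient_id, seq_len(n_dx_only)),
             sprintf("%s_RL%02d", sc$patient_id, seq_len(n_rel_priv))),
    effect = c(rep("missense", n_pre), "frameshift",
               rep("missense", n_shared_other + n_dx_only + n_rel_priv)),
    trajectory = c(rep("PRELEUKEMIC_GERMLINE", n_pre),
                   if (sc$scenario == "clonal_evolution") "SHARED"
                   else "DIAGNOSIS_ONLY",
                   rep("SHARED", n_shared_other),
                   rep("DIAGNOSIS_ONLY", n_dx_only),
                   rep("RELAPSE_SPECIFIC", n_rel_priv)),
    class = append(cls, NA_character_, after = n_pre),
    chrom = append(paste0("chr", sample(1:22, n_snv, replace = TRUE)),
                   "chr5", after = n_pre),
    start = append(sample.int(2e8, n_snv), 170837543L, after = n_pre),
    ref = append(al$ref, "-", after = n_pre),
    alt = append(al$alt, "TCTG", after = n_pre),
    cancer_gene = append(c(rep(TRUE, n_pre),
                           rep(FALSE, n_snv - n_pre)), TRUE, after = n_pre),
    ccf_dx = append(c(pre_ccf, runit(sc$leukemic_ccf_range,
                                     n_shared_other + n_dx_only),
                      zero(n_rel_priv)),
                    runit(sc$leukemic_ccf_range, 1), after = n_pre),
    ccf_rem = append(c(pre_ccf, rep(rem_ccf, n_shared_other + n_dx_only),
                       zero(n_rel_priv)), rem_ccf, after = n_pre),
    ccf_rel = append(c(pre_ccf, runit(sc$leukemic_ccf_range, n_shared_other),
                       zero(n_dx_only),
                       runit(sc$leukemic_ccf_range, n_rel_priv)),
                     npm1_rel_ccf, after = n_pre),
    stringsAsFactors = FALSE)
  truth$end <- truth$start + ifelse(truth$ref == "-", 0L,
                                    nchar(truth$ref) - 1L)
  half <- if (sc$homozygous) 1 else 0.5
  for (s in TIMEPOINTS)
    truth[[paste0("vaf_true_", s)]] <- truth[[paste0("ccf_", s)]] * half
  truth$scenario <- sc$scenario
  ## ensure unique keys (collisions are vanishingly rare but would break joins)
  stopifnot(!anyDuplicated(paste(truth$chrom, truth$start, truth$ref, truth$alt)))

  vt <- data.frame(patient_id = sc$patient_id, chrom = truth$chrom,
                   start = truth$start, end = truth$end, ref = truth$ref,
                   alt = truth$alt, gene = truth$gene, aa_change = NA_character_,
                   effect = truth$effect, pop_af = NA_real_,
                   in_cosmic = FALSE, in_segdup = FALSE, in_repeat = FALSE,
                   in_cancer_gene_list = truth$cancer_gene,
                   stringsAsFactors = FALSE)
  for (s in TIMEPOINTS) {
    obs <- .sample_reads(truth[[paste0("vaf_true_", s)]],
                         mean_depth = sc$wes_depth,
                         rho = sc$overdispersion)
    vt[[paste0("vaf_", s)]] <- ifelse(obs[, "depth"] > 0,
                                      obs[, "alt"] / obs[, "depth"], 0)
    vt[[paste0("depth_", s)]] <- obs[, "depth"]
    vt[[paste0("alt_fwd_", s)]] <- obs[, "fwd"]
    vt[[paste0("alt_rev_", s)]] <- obs[, "rev"]
  }
  structure(list(variants = variant_table(vt),
                 truth = truth,
                 npm1_status_dx = "mut",
                 npm1_status_rel = if (sc$scenario == "clonal_evolution")
                   "mut" else "wt",
                 scenario = sc),
            class = "synthetic_case")
}

#' Generate a synthetic two-group cohort
#'
#' `n_loss` patients follow the `second_de_novo` scenario (NPM1 lost at
#' relapse) and `n_persistent` the `clonal_evolution` scenario.  Remission
#' durations are exponential with group medians of 30 and 8 months, with
#' a fraction of patients administratively censored at a uniform fraction
#' of their event time; second-CR probabilities default to the observed
#' salvage-response rates (2/11 and 58/96).  When `outdir` is given the
#' cohort is written in the package's file dialects (variant CSV,
#' gene-panel CSV, clinical CSV, truth JSON).
#'
#' @param n_loss,n_persistent group sizes (non-negative).
#' @param seed integer seed for the whole cohort; `NULL` continues the
#'   current RNG stream.
#' @param outdir optional output directory.
#' @param median_remission months, per group (defaults 30 and 8).
#' @param censor_prob administrative censoring probability (default 0.10).
#' @param p_second_cr second-CR probability per group.
#' @param ... forwarded to [synthetic_scenario()] for every case.
#' @return list of class `synthetic_cohort`: `cases` (named list of
#'   `synthetic_case`), `variants` (combined `variant_table`),
#'   `gene_panel`, `clinical`, `truth` (per-patient group/scenario).
#' @export
generate_cohort <- function(n_loss, n_persistent, seed = NULL, outdir = NULL,
                            median_remission = c(npm1_loss = 30,
                                                 npm1_persistent = 8),
                            censor_prob = 0.10,
                            p_second_cr = c(npm1_loss = 2 / 11,
                                            npm1_persistent = 58 / 96),
                            ...) {
  stopifnot(n_loss >= 0, n_persistent >= 0)
  if (!is.null(seed)) set.seed(seed)
  ids <- c(if (n_loss > 0) sprintf("L%03d", seq_len(n_loss)),
           if (n_persistent > 0) sprintf("P%03d", seq_len(n_persistent)))
  groups <- rep(c("npm1_loss", "npm1_persistent"), c(n_loss, n_persistent))
  scenarios <- ifelse(groups == "npm1_loss", "second_de_novo",
                      "clonal_evolution")
  cases <- list()
  panel_rows <- list()
  clin_rows <- list()
  for (i in seq_along(ids)) {
    case <- generate_case(synthetic_scenario(scenario = scenarios[i],
                                             patient_id = ids[i], ...))
    cases[[ids[i]]] <- case
    pre_markers <- intersect(case$truth$gene[case$truth$trajectory ==
                                               "PRELEUKEMIC_GERMLINE"],
                             GENE_PANEL_MARKERS)
    panel_rows[[length(panel_rows) + 1]] <- data.frame(
      patient_id = ids[i], gene = c("NPM1", pre_markers),
      stringsAsFactors = FALSE)
    med <- median_remission[[groups[i]]]
    dur <- stats::rexp(1, rate = log(2) / med)
    censored <- stats::runif(1) < censor_prob
    if (censored) dur <- dur * stats::runif(1)
    second_cr <- if (censored) "na" else
      if (stats::runif(1) < p_second_cr[[groups[i]]]) "yes" else "no"
    clin_rows[[length(clin_rows) + 1]] <- data.frame(
      patient_id = ids[i], group = groups[i],
      remission_duration_months = dur, relapse_event = !censored,
      second_cr = second_cr, stringsAsFactors = FALSE)
  }
  empty_panel <- data.frame(patient_id = character(), gene = character(),
                            status_dx = character(), status_rel = character(),
                            identity_dx = character(),
                            identity_rel = character(),
                            zygosity = character(), stringsAsFactors = FALSE)
  panel_list <- lapply(seq_along(panel_rows), function(i) {
    pr <- panel_rows[[i]]
    data.frame(patient_id = pr$patient_id, gene = pr$gene,
               status_dx = "mut",
               status_rel = ifelse(pr$gene == "NPM1" &
                                     groups[i] == "npm1_loss", "wt", "mut"),
               identity_dx = NA_character_, identity_rel = NA_character_,
               zygosity = NA_character_, stringsAsFactors = FALSE)
  })
  panel <- if (length(panel_list))
    do.call(rbind, c(panel_list, list(make.row.names = FALSE)))
  else empty_panel
  clinical <- do.call(rbind, clin_rows)
  if (is.null(clinical))
    clinical <- data.frame(patient_id = character(), group = character(),
                           remission_duration_months = numeric(),
                           relapse_event = logical(),
                           second_cr = character(), stringsAsFactors = FALSE)
  if (length(cases)) {
    variants <- variant_table(do.call(rbind, lapply(cases, function(cs)
      as.data.frame(cs$variants))))
  } else variants <- empty_variant_table()
  truth <- data.frame(patient_id = ids, group = groups, scenario = scenarios,
                      stringsAsFactors = FALSE)
  out <- structure(list(cases = cases, variants = variants,
                        gene_panel = structure(panel,
                                               class = c("gene_panel",
                                                         "data.frame")),
                        clinical = structure(clinical,
                                             class = c("clinical_table",
                                                       "data.frame")),
                        truth = truth),
                   class = "synthetic_cohort")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_variant_table(variants, file.path(outdir, "variants.csv"))
    write_gene_panel(out$gene_panel, file.path(outdir, "gene_panel.csv"))
    write_clinical(out$clinical, file.path(outdir, "clinical.csv"))
    jsonlite::write_json(list(
      patients = truth,
      variant_truth = lapply(cases, function(cs) cs$truth)),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Write a synthetic case as a diagnosis/remission/relapse VCF triplet
#'
#' Emits three minimal single-sample VCF 4.2 files with `AD`, `DP`,
#' `ADF`, `ADR` FORMAT fields and the annotation INFO fields understood
#' by [read_vcf_triplet()].  Indels are re-anchored to the VCF
#' representation using an `N` anchor base (no reference genome is
#' consulted); [normalize_variant_key()] strips the anchor on re-read, so
#' the round trip reproduces the generator's keys exactly.
#'
#' @param case a `synthetic_case` from [generate_case()].
#' @param dir output directory.
#' @param prefix file-name prefix, default the patient id.
#' @return named character vector of the three paths.
#' @export
write_vcf_triplet <- function(case, dir, prefix = NULL) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vt <- case$variants
  if (is.null(prefix)) prefix <- vt$patient_id[1]
  paths <- c(diagnosis = file.path(dir, paste0(prefix, "_dx.vcf")),
             remission = file.path(dir, paste0(prefix, "_rem.vcf")),
             relapse = file.path(dir, paste0(prefix, "_rel.vcf")))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
    "##INFO=<ID=CANCER_GENE,Number=0,Type=Flag,Description=\"Recurrently mutated cancer gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward-strand allelic depths\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse-strand allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", prefix))
  ord <- order(vt$chrom, vt$start)
  vt <- vt[ord, , drop = FALSE]
  for (tp in names(paths)) {
    s <- tp_suffix(tp)
    lines <- character(nrow(vt))
    for (i in seq_len(nrow(vt))) {
      if (vt$ref[i] == "-") {            # insertion: anchor base before
        pos <- vt$start[i] - 1L
        ref <- "N"; alt <- paste0("N", vt$alt[i])
      } else if (vt$alt[i] == "-") {     # deletion
        pos <- vt$start[i] - 1L
        ref <- paste0("N", vt$ref[i]); alt <- "N"
      } else {
        pos <- vt$start[i]; ref <- vt$ref[i]; alt <- vt$alt[i]
      }
      dp <- vt[[paste0("depth_", s)]][i]
      af <- vt[[paste0("alt_fwd_", s)]][i]
      ar <- vt[[paste0("alt_rev_", s)]][i]
      rf <- floor((dp - af - ar) / 2)     # ref strand split not tracked
      rr <- dp - af - ar - rf
      info <- paste0("GENE=", vt$gene[i], ";EFFECT=", vt$effect[i],
                     if (vt$in_cancer_gene_list[i]) ";CANCER_GENE" else "")
      lines[i] <- paste(vt$chrom[i], pos, ".", ref, alt, ".", "PASS", info,
                        "GT:AD:DP:ADF:ADR",
                        paste0("0/1:", dp - af - ar, ",", af + ar, ":", dp,
                               ":", rf, ",", af, ":", rr, ",", ar),
                        sep = "\t")
    }
    writeLines(c(header, lines), paths[[tp]])
  }
  paths
}
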