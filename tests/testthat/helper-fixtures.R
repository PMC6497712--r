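# Fixture builders shared across the suite.  All randomness is drawn from
# the caller's RNG stream; tests seed explicitly.

BASES <- c("A", "C", "G", "T")

# ref/alt pairs guaranteed distinct
rand_alleles <- function(n) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

# random annotated variants exercising every filter predicate
rand_variant_table <- function(n) {
  al <- rand_alleles(n)
  depth <- rpois(n, 91)
  vaf <- round(runif(n, 0, 0.6), 4)
  alt_reads <- rbinom(n, depth, pmax(vaf, 0.01))
  fwd <- rbinom(n, alt_reads, 0.5)
  has_counts <- runif(n) < 0.8
  variant_table(data.frame(
    patient_id = "PX",
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L,
    ref = al$ref, alt = al$alt,
    gene = sample(c("DNMT3A", "NPM1", "GENEA", "GENEB", "GENEC"),
                  n, replace = TRUE),
    effect = sample(c("intronic", "synonymous", "missense", "nonsense",
                      "frameshift", "splice"), n, replace = TRUE),
    pop_af = ifelse(runif(n) < 0.3, runif(n, 0, 0.01), NA),
    in_cosmic = runif(n) < 0.3,
    in_segdup = runif(n) < 0.15,
    in_repeat = runif(n) < 0.15,
    in_cancer_gene_list = runif(n) < 0.4,
    vaf_dx = vaf,
    depth_dx = ifelse(has_counts, depth, NA),
    alt_fwd_dx = ifelse(has_counts, fwd, NA),
    alt_rev_dx = ifelse(has_counts, alt_reads - fwd, NA),
    vaf_rem = ifelse(runif(n) < 0.3, round(runif(n, 0, 0.5), 4), NA),
    stringsAsFactors = FALSE))
}

# gene panel with planted counts: n_persist persisting of n_dx mutated,
# n_changed with a different identity, remainder lost; n_gained gains.
make_panel <- function(gene, n_dx, n_persist, n_changed = 0, n_gained = 0,
                       n_wt = 0, n_na = 0, id_prefix = "S") {
  n_lost <- n_dx - n_persist - n_changed
  stopifnot(n_lost >= 0)
  status_dx <- c(rep("mut", n_dx), rep("wt", n_gained + n_wt), rep("na", n_na))
  status_rel <- c(rep("mut", n_persist + n_changed), rep("wt", n_lost),
                  rep("mut", n_gained), rep("wt", n_wt), rep("na", n_na))
  identity_dx <- c(rep("A", n_persist), rep("A", n_changed),
                   rep(NA, n_lost + n_gained + n_wt + n_na))
  identity_rel <- c(rep("A", n_persist), rep("B", n_changed),
                    rep(NA, n_lost), rep("C", n_gained), rep(NA, n_wt + n_na))
  n <- length(status_dx)
  data.frame(patient_id = paste0(id_prefix, seq_len(n)), gene = gene,
             status_dx = status_dx, status_rel = status_rel,
             identity_dx = identity_dx, identity_rel = identity_rel,
             zygosity = NA_character_, stringsAsFactors = FALSE)
}

# one-row variant table from bare VAFs (NA = unobserved timepoint)
vt_row <- function(vaf_dx = NA, vaf_rem = NA, vaf_rel = NA, gene = "GENE",
                   ref = "C", alt = "A", ...) {
  variant_table(data.frame(patient_id = "P", chrom = "chr1", start = 100L,
                           end = 100L, ref = ref, alt = alt, gene = gene,
                           vaf_dx = vaf_dx, vaf_rem = vaf_rem,
                           vaf_rel = vaf_rel, ..., stringsAsFactors = FALSE))
}
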