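test_that("single-predicate behaviour matches the rule set", {
  # COSMIC membership exempts an otherwise-common SNP
  cosmic <- vt_row(vaf_dx = 0.48, gene = "DNMT3A", effect = "missense",
                   pop_af = 0.005, in_cosmic = TRUE,
                   depth_dx = 120, alt_fwd_dx = 30, alt_rev_dx = 28)
  res <- apply_wes_filters(cosmic)
  expect_equal(nrow(res$kept), 1)
  expect_equal(nrow(res$removed), 0)

  # same variant without the COSMIC entry is a common SNP
  no_cosmic <- cosmic
  no_cosmic$in_cosmic <- FALSE
  no_cosmic$in_cancer_gene_list <- FALSE
  res <- apply_wes_filters(no_cosmic)
  expect_equal(res$removed$reason, "COMMON_SNP")

  # fewer than 2 alt reads on one strand
  weak <- vt_row(vaf_dx = 0.2, effect = "missense",
                 depth_dx = 40, alt_fwd_dx = 1, alt_rev_dx = 7)
  expect_equal(apply_wes_filters(weak)$removed$reason, "LOW_STRAND_SUPPORT")

  # VAF below 10%
  low <- vt_row(vaf_dx = 0.09, effect = "missense")
  expect_equal(apply_wes_filters(low)$removed$reason, "LOW_VAF")

  # reasons follow the fixed order: intronic wins over low VAF
  both <- vt_row(vaf_dx = 0.05, effect = "intronic")
  expect_equal(apply_wes_filters(both)$removed$reason, "INTRONIC")

  # empty input, and a variant missing the tumor observation
  empty <- empty_variant_table()
  res <- apply_wes_filters(empty)
  expect_equal(nrow(res$kept) + nrow(res$removed), 0)
  expect_error(apply_wes_filters(vt_row(vaf_rel = 0.3), filter_config(),
                                 tumor_timepoint = "diagnosis"),
               "lacks diagnosis observation")
})

test_that("kept set equals an independent predicate-set oracle and partitions", {
  cfg <- filter_config()
  set.seed(101)
  for (rep in 1:5) {
    vt <- rand_variant_table(50)
    res <- suppressMessages(apply_wes_filters(vt, cfg))
    # oracle: evaluate each predicate independently and intersect the passes
    pass <- rep(TRUE, nrow(vt))
    pass <- pass & !(vt$effect %in% c("intronic", "synonymous"))
    strand_ok <- is.na(vt$alt_fwd_dx) | is.na(vt$alt_rev_dx) |
      (vt$alt_fwd_dx >= 2 & vt$alt_rev_dx >= 2)
    pass <- pass & strand_ok
    snp <- !is.na(vt$pop_af) & vt$pop_af > 1e-4 & !vt$in_cosmic
    pass <- pass & !snp
    pass <- pass & !vt$in_segdup & !vt$in_repeat
    pass <- pass & vt$vaf_dx >= 0.10
    # rescue: cancer-gene variants failing only the SNP rule stay
    only_snp <- snp & (vt$effect %in% c("intronic", "synonymous")) == FALSE &
      strand_ok & !vt$in_segdup & !vt$in_repeat & vt$vaf_dx >= 0.10
    keep_oracle <- pass | (only_snp & vt$in_cancer_gene_list)
    expect_identical(variant_key_id(res$kept),
                     variant_key_id(vt[keep_oracle, ]))
    # partition invariant
    expect_equal(nrow(res$kept) + nrow(res$removed), nrow(vt))
    expect_length(intersect(variant_key_id(res$kept),
                            res$removed$chrom), 0)
    # every rescued variant is kept
    expect_true(all(variant_key_id(res$rescued) %in%
                      variant_key_id(res$kept)))
  }
})

test_that("filters are monotone in their thresholds and switches", {
  set.seed(102)
  vt <- rand_variant_table(80)
  base <- suppressMessages(apply_wes_filters(vt, filter_config()))
  stricter <- suppressMessages(
    apply_wes_filters(vt, filter_config(min_vaf = 0.25)))
  expect_true(all(variant_key_id(stricter$kept) %in%
                    variant_key_id(base$kept)))
  looser <- suppressMessages(apply_wes_filters(vt, filter_config(
    drop_effects = character(0), drop_segdup = FALSE, drop_repeat = FALSE)))
  expect_true(all(variant_key_id(base$kept) %in%
                    variant_key_id(looser$kept)))
})

test_that("germline rescue keeps and flags, and differences two runs", {
  # a clonal-hematopoiesis hotspot persisting at remission is a candidate
  dnmt3a <- vt_row(vaf_dx = 0.5, vaf_rem = 0.37, gene = "DNMT3A",
                   effect = "missense", in_cancer_gene_list = TRUE)
  cand <- rescue_candidates(dnmt3a)
  expect_equal(nrow(cand), 1)
  expect_match(cand$rescue_note, "manual review")
  expect_equal(nrow(rescue_candidates(dnmt3a, rescue_list = character(0))), 0)

  # disabling rescue changes kept-count by exactly the rescued rows
  set.seed(103)
  vt <- rand_variant_table(200)
  with_rescue <- suppressMessages(apply_wes_filters(vt, filter_config()))
  without <- suppressMessages(
    apply_wes_filters(vt, filter_config(rescue_cancer_genes = FALSE)))
  expect_equal(nrow(with_rescue$kept) - nrow(without$kept),
               nrow(with_rescue$rescued))
})
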