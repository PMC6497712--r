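test_that("gene stability reproduces the persistence fraction and partitions", {
  panel <- make_panel("DNMT3A", n_dx = 83, n_persist = 79, n_gained = 2,
                      n_wt = 40, n_na = 4)
  row <- gene_stability(panel, "DNMT3A")
  expect_equal(row$stability, 79 / 83)
  expect_equal(pct_round(100 * row$stability), 95)
  expect_equal(row$n_persist + row$n_lost + row$n_changed_identity,
               row$n_dx_mut)
  expect_equal(row$n_gained, 2)
  # identity changes do not count as persistence
  panel2 <- make_panel("FLT3-ITD", n_dx = 40, n_persist = 16, n_changed = 14)
  row2 <- gene_stability(panel2, "FLT3-ITD")
  expect_equal(row2$n_persist, 16)
  expect_equal(row2$n_changed_identity, 14)
  expect_equal(row2$n_lost, 10)
  # empty denominator
  expect_true(is.na(gene_stability(make_panel("TP53", 0, 0, n_wt = 5),
                                   "TP53")$stability))
  # invariant under patient reordering
  shuf <- panel[sample(nrow(panel)), ]
  expect_equal(gene_stability(shuf, "DNMT3A")$stability, row$stability)
})

test_that("stability estimates recover a planted persistence probability", {
  set.seed(301)
  p <- 0.7; n <- 200
  persist <- rbinom(1, n, p)
  panel <- make_panel("IDH1", n_dx = n, n_persist = persist)
  est <- gene_stability(panel, "IDH1")$stability
  expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
})

test_that("ITD pair classification covers the five outcomes", {
  expect_equal(classify_itd_pair("48", "48"), "identical")
  expect_equal(classify_itd_pair("48", "21"), "distinct")
  expect_equal(classify_itd_pair("48", NA), "lost")
  expect_equal(classify_itd_pair(NA, "60"), "gained")
  expect_equal(classify_itd_pair(NA, NA), "none")
  expect_equal(classify_itd_pair(c("48", NA), c("48", "21")),
               c("identical", "gained"))
})

test_that("pattern shift reacts to status and identity changes only", {
  stable <- data.frame(patient_id = "P", gene = c("NPM1", "DNMT3A"),
                       status_dx = "mut", status_rel = "mut",
                       identity_dx = NA, identity_rel = NA, zygosity = NA)
  expect_false(pattern_shift(stable))
  npm1_loss <- stable
  npm1_loss$status_rel[1] <- "wt"
  expect_true(pattern_shift(npm1_loss))
  itd <- data.frame(patient_id = "P", gene = "FLT3-ITD",
                    status_dx = "mut", status_rel = "mut",
                    identity_dx = "48", identity_rel = "21", zygosity = NA)
  expect_true(pattern_shift(itd))
  # na rows are ignored; all-na is an error; order does not matter
  with_na <- rbind(stable, data.frame(patient_id = "P", gene = "NRAS",
                                      status_dx = "na", status_rel = "mut",
                                      identity_dx = NA, identity_rel = NA,
                                      zygosity = NA))
  expect_false(pattern_shift(with_na))
  expect_false(pattern_shift(with_na[rev(seq_len(nrow(with_na))), ]))
  all_na <- with_na[3, ]
  expect_error(pattern_shift(all_na), "evaluable")
})

test_that("mutation burden counts present variants and summarizes by group", {
  set.seed(302)
  case <- generate_case(synthetic_scenario("clonal_evolution"))
  truth_dx <- sum(case$truth$vaf_true_dx >= 0.10)
  # read sampling can flip the rare borderline row
  expect_lte(abs(mutation_burden(case$variants, "diagnosis") - truth_dx), 1)
  expect_equal(mutation_burden(empty_variant_table(), "diagnosis"), 0L)
  # Poisson simulation: cohort mean within 3 standard errors
  n <- 100
  cohort <- generate_cohort(0, n)
  b <- vapply(cohort$cases, function(cs)
    sum(cs$truth$vaf_true_dx >= 0.10), numeric(1))
  expect_lt(abs(mean(b) - 10.6), 3 * sqrt(10.6 / n))
  bs <- burden_summary(lapply(cohort$cases, `[[`, "variants"),
                       rep("npm1_persistent", n))
  expect_equal(nrow(bs), 3)
  expect_lt(abs(bs$mean_burden[bs$timepoint == "diagnosis"] - 10.6), 1)
})

test_that("aberration burden ratio is reported to one decimal", {
  expect_equal(aberration_ratio(23, 79)$ratio, 3.4)
  expect_equal(aberration_ratio(10, 10)$ratio, 1.0)
  expect_equal(aberration_ratio(7, 21)$ratio, 3.0)
  expect_message(res <- aberration_ratio(0, 5), "undefined")
  expect_true(is.na(res$ratio))
})
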