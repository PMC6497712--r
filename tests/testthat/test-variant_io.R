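test_that("wide variant tables parse with percent VAFs and missing cells", {
  txt <- paste(
    "patient_id,chr,start,end,ref,alt,gene,aa_change,vaf_pct_rel,vaf_pct_rem,vaf_pct_dx",
    "172L,chr2,25457243,25457243,G,A,DNMT3A,R882C,38.46,36,38.46",
    "103L,chr11,32417907,32417907,-,CCGA,WT1,A382fs,13.54,0,",
    sep = "\n")
  vt <- read_variant_table(txt)
  expect_s3_class(vt, "variant_table")
  expect_equal(nrow(vt), 2)
  r1 <- vt[vt$patient_id == "172L", ]
  expect_equal(c(r1$vaf_dx, r1$vaf_rem, r1$vaf_rel), c(0.3846, 0.36, 0.3846))
  r2 <- vt[vt$patient_id == "103L", ]
  expect_true(is.na(r2$vaf_dx))          # missing observation, not zero
  expect_equal(r2$vaf_rem, 0)            # observed absence stays zero
  expect_equal(r2$ref, "-")
})

test_that("empty input with a valid header gives an empty table", {
  vt <- read_variant_table("patient_id,chr,start,end,ref,alt,vaf_pct_dx")
  expect_equal(nrow(vt), 0)
  expect_s3_class(vt, "variant_table")
})

test_that("malformed rows fail with line numbers; duplicates are checked", {
  hdr <- "patient_id,chr,start,end,ref,alt,vaf_pct_dx"
  expect_error(read_variant_table(paste(hdr, "P,chr1,abc,5,C,A,10", sep = "\n")),
               "line\\(s\\) 2")
  expect_error(read_variant_table(paste(hdr, "P,chr1,5,5,C,X,10", sep = "\n")),
               "allele")
  long <- paste(
    "patient_id,chr,start,end,ref,alt,timepoint,vaf_pct",
    "P,chr1,5,5,C,A,diagnosis,40",
    "P,chr1,5,5,C,A,relapse,30",
    "P,chr1,5,5,C,A,diagnosis,20",
    sep = "\n")
  expect_error(read_variant_table(long), "conflicting duplicate")
  ok <- read_variant_table(sub(",diagnosis,20", ",remission,20", long))
  expect_equal(nrow(ok), 1)
  expect_equal(c(ok$vaf_dx, ok$vaf_rem, ok$vaf_rel), c(0.40, 0.20, 0.30))
})

test_that("write/read round trip is the identity on generator output", {
  set.seed(401)
  vt <- generate_case(synthetic_scenario("clonal_evolution"))$variants
  path <- withr::local_tempfile(fileext = ".csv")
  write_variant_table(vt, path)
  back <- read_variant_table(path)
  ord <- function(x) x[order(x$chrom, x$start), VT_COLS]
  expect_equal(as.data.frame(ord(back)), as.data.frame(ord(vt)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("indel normalization matches the anchored dialect and an oracle", {
  # worked VCF insertion: anchored C -> CTCTG becomes "-"/TCTG one base right
  key <- normalize_variant_key("chr5", 170837542, "C", "CTCTG")
  expect_equal(key[c("start", "end", "ref", "alt")],
               list(start = 170837543L, end = 170837543L,
                    ref = "-", alt = "TCTG"))
  # deletion
  key <- normalize_variant_key("chr1", 100, "CTG", "C")
  expect_equal(key[c("start", "end", "ref", "alt")],
               list(start = 101L, end = 102L, ref = "TG", alt = "-"))

  # brute-force re-anchoring oracle: trim with string ops, not vectors
  oracle <- function(chrom, start, ref, alt) {
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
      ref <- substring(ref, 1, nchar(ref) - 1)
      alt <- substring(alt, 1, nchar(alt) - 1)
    }
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           substring(ref, 1, 1) == substring(alt, 1, 1)) {
      ref <- substring(ref, 2); alt <- substring(alt, 2); start <- start + 1
    }
    if (nchar(ref) == 0)
      list(chrom = chrom, start = start, end = start, ref = "-", alt = alt)
    else if (nchar(alt) == 0)
      list(chrom = chrom, start = start, end = start + nchar(ref) - 1,
           ref = ref, alt = "-")
    else list(chrom = chrom, start = start, end = start + nchar(ref) - 1,
              ref = ref, alt = alt)
  }
  set.seed(402)
  for (i in 1:1000) {
    anchor <- paste(sample(BASES, sample(1:3, 1), replace = TRUE),
                    collapse = "")
    ins <- paste(sample(BASES, sample(1:6, 1), replace = TRUE), collapse = "")
    pos <- sample.int(1e6, 1)
    if (runif(1) < 0.5) { ref <- anchor; alt <- paste0(anchor, ins) }
    else { ref <- paste0(anchor, ins); alt <- anchor }
    got <- normalize_variant_key("chrX", pos, ref, alt)
    want <- oracle("chrX", pos, ref, alt)
    want$start <- as.integer(want$start); want$end <- as.integer(want$end)
    expect_identical(got, want)
    # idempotence on the already-normalized key
    expect_identical(normalize_variant_key(got$chrom, got$start,
                                           got$ref, got$alt), got)
  }
})

test_that("VCF triplets merge by normalized key with AD-derived VAFs", {
  dir <- withr::local_tempdir()
  vcf <- function(path, rows) {
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
                 "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
                 paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                        "\tFORMAT\tS1"),
                 rows), path)
    path
  }
  dx <- vcf(file.path(dir, "dx.vcf"),
            c("chr2\t25457243\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1:60,40",
              "chr5\t170837542\t.\tC\tCTCTG\t.\tPASS\t.\tGT:AD\t0/1:55,45"))
  rel <- vcf(file.path(dir, "rel.vcf"),
             c("chr2\t25457243\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1:70,30"))
  vt <- read_vcf_triplet(dx = dx, rel = rel, patient_id = "P9")
  expect_equal(nrow(vt), 2)
  ins <- vt[vt$ref == "-", ]
  expect_equal(ins$start, 170837543L)
  expect_equal(ins$alt, "TCTG")
  expect_equal(ins$vaf_dx, 0.45)
  expect_true(is.na(ins$vaf_rel))
  snv <- vt[vt$ref == "G", ]
  expect_equal(snv$vaf_dx, 0.4)
  expect_equal(snv$vaf_rel, 0.3)
  expect_true(is.na(snv$vaf_rem))

  # diagnosis-only single record
  solo <- read_vcf_triplet(dx = dx)
  expect_equal(nrow(solo), 2)
  expect_true(all(is.na(solo$vaf_rel)))

  # missing AD errors; contradictory REF at the same locus errors
  bad <- vcf(file.path(dir, "bad.vcf"),
             "chr2\t25457243\t.\tG\tA\t.\tPASS\t.\tGT\t0/1")
  expect_error(read_vcf_triplet(dx = bad), "AD")
  rel2 <- vcf(file.path(dir, "rel2.vcf"),
              "chr2\t25457243\t.\tT\tA\t.\tPASS\t.\tGT:AD\t0/1:70,30")
  expect_error(read_vcf_triplet(dx = dx, rel = rel2), "contradictory REF")
})

test_that("synthetic VCF triplets round-trip to the generator's keys", {
  set.seed(403)
  case <- generate_case(synthetic_scenario("clonal_evolution",
                                           patient_id = "RT"))
  dir <- withr::local_tempdir()
  paths <- write_vcf_triplet(case, dir)
  vt <- read_vcf_triplet(paths["diagnosis"], paths["remission"],
                         paths["relapse"], patient_id = "RT")
  key <- function(df) sort(paste(df$chrom, df$start, df$end, df$ref, df$alt))
  expect_identical(key(vt), key(case$truth))
  # VAFs survive the round trip
  m <- merge(as.data.frame(vt), case$variants,
             by = c("chrom", "start", "ref", "alt"))
  expect_equal(nrow(m), nrow(case$truth))
  expect_equal(m$vaf_dx.x, m$vaf_dx.y, tolerance = 1e-9)
})

test_that("gene panel statuses, embedded identities and vocab checks work", {
  panel <- read_gene_panel(paste(
    "patient_id,gene,status_dx,status_rel",
    "P01,NPM1,mut,wt",
    "P02,FLT3-ITD,mut(48bp),mut(21bp)",
    sep = "\n"))
  expect_equal(panel$status_dx, c("mut", "mut"))
  expect_equal(panel$status_rel, c("wt", "mut"))
  expect_equal(panel$identity_dx, c(NA, "48"))
  expect_equal(panel$identity_rel, c(NA, "21"))
  expect_error(read_gene_panel(paste("patient_id,gene,status_dx,status_rel",
                                     "P01,NPM1,mutated,wt", sep = "\n")),
               "status token")
  expect_warning(read_gene_panel(paste("patient_id,gene,status_dx,status_rel",
                                       "P01,NOTAGENE,mut,mut", sep = "\n")),
                 "marker panel")
  # identity on a non-mut status violates the record invariant
  expect_error(read_gene_panel(paste("patient_id,gene,status_dx,status_rel",
                                     "P01,NPM1,wt(4bp),wt", sep = "\n")),
               "identity")
  # writer round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_gene_panel(panel, path)
  expect_equal(as.data.frame(read_gene_panel(path)), as.data.frame(panel))
})

test_that("clinical tables validate tokens and round-trip", {
  clin <- read_clinical(paste(
    "patient_id,group,remission_duration_months,relapse_event,second_cr",
    "P1,npm1_loss,30,true,no",
    "P2,npm1_persistent,8,true,yes",
    "P3,npm1_persistent,12,false,na",
    sep = "\n"))
  expect_equal(clin$relapse_event, c(TRUE, TRUE, FALSE))
  expect_error(read_clinical(paste(
    "patient_id,group,remission_duration_months,relapse_event,second_cr",
    "P1,some_group,30,true,no", sep = "\n")), "group token")
  expect_error(read_clinical(paste(
    "patient_id,group,remission_duration_months,relapse_event,second_cr",
    "P1,npm1_loss,-3,true,no", sep = "\n")), "non-negative")
  path <- withr::local_tempfile(fileext = ".csv")
  write_clinical(clin, path)
  expect_equal(as.data.frame(read_clinical(path)), as.data.frame(clin))
  # na second_cr rows are excluded from the salvage-response table
  cs <- clinical_summary(clin)
  expect_equal(sum(cs$second_cr_table), 2)
})
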