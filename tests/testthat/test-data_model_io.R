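test_that("variant table TSV round-trips, including empty and typed fields", {
  v <- make_variants(3, predictors = "deleterious", gerp_rs = c(1, NA, 5),
                     maf_ExAC = c(NA, 0.002, 0.3), clinvar = "pathogenic",
                     assumed_de_novo = c(TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  back <- read_variant_table(path, dialect = "tsv")
  expect_equal(as.data.frame(back), as.data.frame(v))
  expect_equal(back$depth[1], 60)

  # zero data rows -> empty collection with the full schema
  empty <- v[0, ]
  write_variant_table(empty, path)
  back0 <- read_variant_table(path)
  expect_equal(nrow(back0), 0)
  expect_true(all(predictor_names() %in% names(back0)))
})

test_that("variant table validation rejects schema violations with row numbers", {
  v <- as.data.frame(make_variants(2))
  v$consequence[2] <- "stopgain"
  expect_error(as_variant_table(v), "accepted tokens")
  v2 <- as.data.frame(make_variants(2))
  v2$CADD <- "deleterious"
  expect_error(as_variant_table(v2), "unknown variant-table columns")
  v3 <- as.data.frame(make_variants(2))
  v3$pos[1] <- 0L
  expect_error(as_variant_table(v3), "row 1")
  v4 <- as.data.frame(make_variants(1))
  v4$alt <- v4$ref
  expect_error(as_variant_table(v4), "ref and alt")
  v5 <- as.data.frame(make_variants(1))
  v5$maf_ExAC <- 1.2
  expect_error(as_variant_table(v5), "\\[0, 1\\]")
})

test_that("missing optional annotation columns become explicit missing values", {
  df <- data.frame(patient_id = "P1", chrom = "chr1", pos = 5L, ref = "A",
                   alt = "T", gene = "SCN1A", consequence = "missense",
                   depth = 40, genotype = "het", stringsAsFactors = FALSE)
  v <- as_variant_table(df)
  expect_true(is.na(v$SIFT))
  expect_true(is.na(v$gerp_rs))
  expect_identical(v$clinvar, "absent")
  expect_false(v$assumed_de_novo)
})

test_that("VCF ingestion honours per-sample GT/DP and the INFO key mapping", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=MAF_EXAC,Number=1,Type=Float,Description=\"f\">",
    "##INFO=<ID=PRED_SIFT,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=GERP_RS,Number=1,Type=Float,Description=\"g\">",
    "##INFO=<ID=CLINVAR,Number=1,Type=String,Description=\"d\">",
    "##INFO=<ID=ASSUMED_DE_NOVO,Number=0,Type=Flag,Description=\"k\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    paste0("chr2\t166850785\t.\tC\tT\t50\tPASS\t",
           "GENE=SCN1A;CSQ=missense_variant;MAF_EXAC=0.001;PRED_SIFT=D;",
           "GERP_RS=5.1;CLINVAR=pathogenic;ASSUMED_DE_NOVO\t",
           "GT:DP\t0/1:44\t0/0:50"),
    paste0("chr9\t1000\t.\tG\tA\t50\tPASS\t",
           "GENE=TSC1;CSQ=stop_gained\tGT:DP\t1/1:33\t./.:10"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  v <- read_variant_table(path, dialect = "vcf")
  expect_equal(nrow(v), 2)  # S2 carries no alternate allele
  s1 <- v[v$pos == 166850785, ]
  expect_equal(s1$patient_id, "S1")
  expect_equal(s1$depth, 44)
  expect_equal(s1$genotype, "het")
  expect_equal(s1$consequence, "missense")
  expect_equal(s1$maf_EXAC, 0.001)
  expect_equal(s1$SIFT, "deleterious")
  expect_true(s1$assumed_de_novo)
  s2 <- v[v$pos == 1000, ]
  expect_equal(s2$genotype, "hom_alt")
  expect_equal(s2$consequence, "nonsense")
  expect_false(s2$assumed_de_novo)
})

test_that("the packaged panel has the published composition", {
  panel <- read_gene_panel()
  expect_equal(nrow(panel), 178)
  expect_equal(sum(panel$category == "epilepsy_gene"), 105)
  expect_equal(sum(panel$category == "neurodevelopment_gene"), 73)
  expect_false(anyDuplicated(panel$gene) > 0)
  # alias resolution: the cohort table's ADGRV1 maps onto panel gene GPR98
  expect_equal(panel_lookup("ADGRV1", panel)$gene, "GPR98")
})

test_that("reading a panel with duplicate symbols fails", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory", "SCN1A\tepilepsy_gene",
               "SCN1A\tepilepsy_gene"), path)
  expect_error(read_gene_panel(path), "duplicate")
})

test_that("classified-variant fixture matches the published table", {
  t3 <- load_fixture_classified()
  expect_equal(nrow(t3), 26)
  expect_equal(length(unique(t3$gene)), 15)
  expect_equal(sum(is.na(t3$or_value)), 3)
  row <- t3[t3$gene == "ADGRV1" & t3$hgvs_p == "p.His1859Arg", ]
  expect_equal(row$or_value, 11.7)
  expect_equal(c(row$ci_low, row$ci_high), c(3.6, 37.6))
  expect_setequal(parse_criteria(row$criteria)[[1]],
                  c("PS4", "PM6", "PP3", "PP5"))
  # the three control-absent rows carry no PS4
  na_rows <- t3[is.na(t3$or_value), ]
  expect_false(any(grepl("PS4", na_rows$criteria)))
})

test_that("cohort fixture matches the published table", {
  t4 <- load_fixture_cohort()
  expect_equal(nrow(t4), 37)
  expect_equal(length(unique(t4$patient_id)), 32)
  expect_equal(sum(table(t4$patient_id) > 1), 5)
  expect_equal(sum(t4$pathogenic), 3)
  pt <- fixture_patients()
  expect_equal(nrow(pt), 32)
})

test_that("cohort report round-trips and writes deterministically", {
  t4 <- load_fixture_cohort()
  rep <- diagnostic_yield(t4, fixture_patients(),
                          denominators = cohort_denominators())
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "r1.tsv")
  p2 <- file.path(dir, "r2.tsv")
  write_report(rep, p1)
  write_report(rep, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_report(p1)
  ov <- back[back$section == "overall", ]
  expect_equal(ov$percent, rep$overall_yield[["percent"]])
  expect_equal(ov$numerator, 32)
  # empty report still carries headers
  rep0 <- diagnostic_yield(t4[0, ], fixture_patients(),
                           denominators = cohort_denominators())
  write_report(rep0, p1)
  expect_equal(read_report(p1)[1, "numerator"], 0)
})

test_that("config YAML round-trips and rejects unknown keys", {
  cfg <- pipeline_config(min_depth = 20, maf_threshold = 0.005)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  back <- read_config_yaml(path)
  expect_equal(back$min_depth, 20)
  expect_equal(back$maf_threshold, 0.005)
  writeLines("min_dpeth: 10", path)
  expect_error(read_config_yaml(path), "unknown config keys")
  expect_error(pipeline_config(ci_level = 1.2), "ci_level")
})
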