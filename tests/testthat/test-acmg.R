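cfg <- pipeline_config()

test_that("evidence strength is a pure function of the code prefix", {
  expect_equal(evidence_strength(c("PVS1", "PS4", "PM6", "PP3", "BA1",
                                   "BS2", "BP4")),
               c("very_strong", "strong", "moderate", "supporting",
                 "stand_alone_benign", "strong_benign", "supporting_benign"))
  expect_error(evidence_strength("PX9"), "unknown ACMG code")
})

test_that("evidence assignment follows the documented rule table", {
  panel <- read_gene_panel()
  # nonsense variant in an LOF-mechanism gene, novel, assumed de novo,
  # well-voted: {PVS1, PM2, PM6, PP3}
  v <- make_variants(1, gene = "DEPDC5", consequence = "nonsense",
                     predictors = "deleterious", gerp_rs = 5.8,
                     lof_mechanism_gene = TRUE, assumed_de_novo = TRUE)
  ev <- assign_evidence(v, assoc = NULL, db_status = "uncertain",
                        panel_entry = NULL, cfg = cfg)
  expect_setequal(ev, c("PVS1", "PM2", "PM6", "PP3"))

  # case-control missense with concordant databases: {PS4, PM6, PP3, PP5}
  v2 <- make_variants(1, gene = "GPR98", maf_ExAC = 1e-5,
                      predictors = "deleterious", gerp_rs = 5.5,
                      clinvar = "pathogenic", hgmd = "disease_mutation",
                      assumed_de_novo = TRUE)
  ev2 <- assign_evidence(v2, assoc = list(ps4 = TRUE),
                         db_status = "consistent_pathogenic",
                         panel_entry = panel[panel$gene == "GPR98", ],
                         cfg = cfg)
  expect_setequal(ev2, c("PS4", "PM6", "PP3", "PP5"))

  # common tolerated variant: benign-side codes only
  v3 <- make_variants(1, maf_ExAC = 0.10, predictors = "tolerated",
                      gerp_rs = 1.0)
  ev3 <- assign_evidence(v3, cfg = cfg)
  expect_true(all(c("BA1", "BP4") %in% ev3))
  expect_false(any(grepl("^P", ev3)))

  # PP5/BP6 can be disabled
  cfg_nopp5 <- pipeline_config(use_pp5 = FALSE)
  ev4 <- assign_evidence(v2, assoc = list(ps4 = TRUE),
                         db_status = "consistent_pathogenic", cfg = cfg_nopp5)
  expect_false("PP5" %in% ev4)
})

test_that("combination rules reproduce the published verdict patterns", {
  lab <- function(codes) combine_evidence(codes)$label
  expect_equal(lab(c("PS4", "PM6", "PP3", "PP5")), "likely_pathogenic")
  expect_equal(lab(c("PS1", "PS3", "PM2", "PM6", "PP3")), "pathogenic")
  expect_equal(lab(c("PS4", "PM5", "PM6", "PP3", "PP5")), "pathogenic")
  expect_equal(lab(c("PM2", "PM6", "PP3", "PP5")), "likely_pathogenic")
  expect_equal(lab(c("PVS1", "PS3", "PM2", "PM6", "PP3")), "pathogenic")
  expect_equal(lab(character()), "uncertain_significance")
  expect_equal(lab("BA1"), "benign")
  expect_equal(lab(c("BS1", "BS2")), "benign")
  expect_equal(lab(c("BS1", "BP4")), "likely_benign")
  expect_equal(lab(c("BP4", "BP6")), "likely_benign")
  # conflicting evidence collapses to VUS with the flag set
  conf <- combine_evidence(c("PS1", "PS2", "BA1"))
  expect_equal(conf$label, "uncertain_significance")
  expect_true(conf$conflict)
})

test_that("combination engine equals an independent transcription over all small sets", {
  # independent oracle: a literal re-coding of the combining rules working
  # on strength counts, written without reference to combine_evidence()
  oracle <- function(codes) {
    s <- table(factor(evidence_strength(codes),
                      levels = c("very_strong", "strong", "moderate",
                                 "supporting", "stand_alone_benign",
                                 "strong_benign", "supporting_benign")))
    vs <- s[["very_strong"]]; st <- s[["strong"]]; mo <- s[["moderate"]]
    su <- s[["supporting"]]; ba <- s[["stand_alone_benign"]]
    bs <- s[["strong_benign"]]; bp <- s[["supporting_benign"]]
    p <- (vs >= 1 && (st >= 1 || mo >= 2 || (mo == 1 && su == 1) || su >= 2)) ||
      st >= 2 ||
      (st == 1 && (mo >= 3 || (mo == 2 && su >= 2) || (mo == 1 && su >= 4)))
    lp <- (vs >= 1 && mo == 1) || (st == 1 && mo >= 1 && mo <= 2) ||
      (st == 1 && su >= 2) || mo >= 3 || (mo == 2 && su >= 2) ||
      (mo == 1 && su >= 4)
    b <- ba >= 1 || bs >= 2
    lb <- (bs == 1 && bp >= 1) || bp >= 2
    if ((p || lp) && (b || lb)) return("uncertain_significance")
    if (p) return("pathogenic")
    if (lp) return("likely_pathogenic")
    if (b) return("benign")
    if (lb) return("likely_benign")
    "uncertain_significance"
  }
  pm_pool <- c("PM1", "PM2", "PM5")
  pp_pool <- c("PP1", "PP2", "PP3", "PP4", "PP5")
  for (pvs in 0:1) for (ps in 0:1) for (pm in 0:3) for (pp in 0:5) {
    codes <- c(if (pvs) "PVS1", if (ps) "PS4",
               pm_pool[seq_len(pm)], pp_pool[seq_len(pp)])
    expect_equal(combine_evidence(codes)$label, oracle(codes),
                 info = paste(codes, collapse = "+"))
  }
  # benign-side sweep
  for (ba in 0:1) for (bs in 0:2) for (bp in 0:3) {
    codes <- c(if (ba) "BA1", paste0("BS", seq_len(bs), recycle0 = TRUE),
               paste0("BP", seq_len(bp), recycle0 = TRUE))
    expect_equal(combine_evidence(codes)$label, oracle(codes),
                 info = paste(codes, collapse = "+"))
  }
})

test_that("adding pathogenic-side evidence never demotes the verdict", {
  rank <- c(benign = 1, likely_benign = 2, uncertain_significance = 3,
            likely_pathogenic = 4, pathogenic = 5)
  pool <- c("PVS1", "PS1", "PM1", "PM2", "PM5", "PP1", "PP2", "PP3")
  set.seed(99)
  for (i in 1:200) {
    codes <- sample(pool, sample(0:5, 1))
    extra <- sample(setdiff(pool, codes), 1)
    before <- combine_evidence(codes)
    after <- combine_evidence(c(codes, extra))
    if (!after$conflict && !before$conflict)
      expect_gte(rank[[after$label]], rank[[before$label]])
  }
})

test_that("classify_variants composes assignment and combination per survivor", {
  panel <- read_gene_panel()
  v <- as_variant_table(rbind(
    as.data.frame(make_passing_variant("P1", gene = "SCN1A", pos = 100L,
                                       maf_ExAC = 1e-5,
                                       clinvar = "pathogenic",
                                       hgmd = "disease_mutation",
                                       assumed_de_novo = TRUE)),
    as.data.frame(make_passing_variant("P2", gene = "TSC1", pos = 200L,
                                       assumed_de_novo = TRUE))))
  casc <- run_cascade(v, panel, cfg)
  freqs <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                      panel = "ExAC", af = 1e-5, allele_number = 121412L,
                      stringsAsFactors = FALSE)
  assoc <- associate_variants(casc$survivors, freqs, 243, cfg)
  cls <- classify_variants(casc$survivors, assoc, panel, cfg)
  r1 <- cls[cls$patient_id == "P1", ]
  expect_equal(r1$evidence, "PS4, PM6, PP3, PP5")
  expect_equal(r1$label, "likely_pathogenic")
  r2 <- cls[cls$patient_id == "P2", ]
  expect_equal(r2$evidence, "PM2, PM6, PP3")  # no DB record, no controls
  expect_equal(r2$label, "uncertain_significance")
})
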