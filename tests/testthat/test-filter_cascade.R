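cfg <- pipeline_config()

test_that("depth filter is inclusive at the threshold", {
  v <- make_variants(3, depth = c(30, 29, 0))
  res <- filter_by_depth(v, cfg)
  expect_equal(res$pass, c(TRUE, FALSE, FALSE))
  vna <- as.data.frame(make_variants(1))
  vna$depth <- NA_real_
  res_na <- filter_by_depth(vna, cfg)
  expect_false(res_na$pass)
  expect_equal(res_na$reason, "no-depth")
})

test_that("consequence filter keeps protein-disrupting classes only", {
  v <- make_variants(7, consequence = consequence_levels())
  res <- filter_by_consequence(v)
  expect_equal(res$pass, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("panel filter is exact and case-sensitive on the symbol", {
  panel <- read_gene_panel()
  v <- make_variants(4, gene = c("SCN1A", "BRCA1", "RELN", "scn1a"))
  expect_equal(filter_by_panel(v, panel)$pass, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(filter_by_panel(v, panel[0, ]), "empty")
})

test_that("frequency filter excludes strictly above threshold; absence passes", {
  v <- make_variants(3, maf_KRGDB = c(0.02, 0.01, NA),
                     maf_ExAC = c(NA, 0.01, NA))
  expect_equal(filter_by_frequency(v, cfg)$pass, c(FALSE, TRUE, TRUE))
})

test_that("vote counting collapses the correlated pairs and skips missing calls", {
  # maximum: all ten deleterious plus conserved GERP = 9 voting units
  v <- make_variants(1, predictors = "deleterious", gerp_rs = 6.0)
  expect_equal(deleteriousness_votes(v, cfg), 9L)
  # all missing = 0
  v0 <- make_variants(1, predictors = NA_character_)
  expect_equal(deleteriousness_votes(v0, cfg), 0L)
  # HDIV deleterious, HVAR tolerated -> the pair contributes exactly one
  v1 <- as.data.frame(make_variants(1, predictors = "tolerated"))
  v1$Polyphen2_HDIV <- "deleterious"
  expect_equal(deleteriousness_votes(as_variant_table(v1), cfg), 1L)
  # under the "both" pair rule the discordant pair stops voting
  cfg_and <- pipeline_config(pair_rule = "both")
  expect_equal(deleteriousness_votes(as_variant_table(v1), cfg_and), 0L)
  # GERP boundary: >= cutoff votes
  vg <- make_variants(2, predictors = NA_character_, gerp_rs = c(4.4, 4.39))
  expect_equal(deleteriousness_votes(vg, cfg), c(1L, 0L))
})

test_that("vote counting agrees with brute-force enumeration of voting units", {
  # enumerate all 3^4 call patterns over {HDIV, HVAR, SIFT, MetaSVM}
  lv <- c("deleterious", "tolerated", NA)
  grid <- expand.grid(hdiv = lv, hvar = lv, sift = lv, msvm = lv,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    v <- as.data.frame(make_variants(1, predictors = NA_character_))
    v$Polyphen2_HDIV <- grid$hdiv[i]
    v$Polyphen2_HVAR <- grid$hvar[i]
    v$SIFT <- grid$sift[i]
    v$MetaSVM <- grid$msvm[i]
    del <- function(x) !is.na(x) && x == "deleterious"
    expected <- (del(grid$hdiv[i]) || del(grid$hvar[i])) +
      del(grid$msvm[i]) + del(grid$sift[i])
    expect_equal(deleteriousness_votes(as_variant_table(v), cfg),
                 as.integer(expected), info = paste("pattern", i))
  }
})

test_that("deleteriousness filter requires two or more votes", {
  mk <- function(k) {
    v <- as.data.frame(make_variants(1, predictors = NA_character_))
    singles <- c("SIFT", "MutationTaster", "MutationAssessor")
    for (p in singles[seq_len(k)]) v[[p]] <- "deleterious"
    as_variant_table(v)
  }
  expect_false(filter_by_deleteriousness(mk(0), cfg)$pass)
  expect_false(filter_by_deleteriousness(mk(1), cfg)$pass)
  expect_true(filter_by_deleteriousness(mk(2), cfg)$pass)
})

test_that("database reconciliation flags any inconsistency as uncertain", {
  v <- make_variants(6,
    clinvar = c("pathogenic", "pathogenic", "absent", "benign", "absent",
                "uncertain"),
    hgmd = c("disease_mutation", "benign", "absent", "absent",
             "disease_mutation", "disease_mutation"))
  expect_equal(reconcile_database_assertions(v),
               c("consistent_pathogenic", "uncertain", "uncertain",
                 "consistent_benign", "consistent_pathogenic", "uncertain"))
})

test_that("the cascade short-circuits and its trace counts are monotone", {
  panel <- read_gene_panel()
  v <- rbind(as.data.frame(make_variants(1, depth = 10)),
             as.data.frame(make_passing_variant(pos = 200L)))
  out <- run_cascade(as_variant_table(v), panel, cfg)
  expect_equal(nrow(out$survivors), 1)
  expect_true(all(diff(out$trace$counts) <= 0))
  # the depth-failed variant has no entries for later steps
  d <- out$trace$detail
  failed <- d$variant[d$step == "depth" & !d$pass]
  expect_false(any(d$variant %in% failed & d$step != "depth"))
  # survivors carry the reconciliation annotation
  expect_true("db_status" %in% names(out$survivors))

  empty <- run_cascade(v[0, ], panel, cfg)
  expect_equal(nrow(empty$survivors), 0)
  expect_true(all(empty$trace$counts == 0))
})

test_that("cascade equals the conjunction of pure predicates in any order", {
  panel <- read_gene_panel()
  preds <- cascade_predicates(panel, cfg)
  for (seed in 1:5) {
    v <- random_cohort(300, seed, panel)
    surv <- run_cascade(v, panel, cfg)$survivors
    key <- paste(v$patient_id, variant_key(v))
    # conjunction, evaluated independently
    keep <- Reduce(`&`, lapply(preds, function(f) f(v)))
    expect_setequal(paste(surv$patient_id, variant_key(surv)), key[keep])
    # a random permutation of sequential application gives the same set
    ord <- sample(names(preds))
    w <- v
    for (nm in ord) w <- w[preds[[nm]](w), , drop = FALSE]
    expect_setequal(paste(w$patient_id, variant_key(w)),
                    paste(surv$patient_id, variant_key(surv)))
  }
})

test_that("cascade is idempotent and distributes over cohort union", {
  panel <- read_gene_panel()
  a <- random_cohort(150, 11, panel)
  b <- random_cohort(150, 12, panel)
  b$pos <- b$pos + 2e6L  # disjoint keys
  sa <- run_cascade(a, panel, cfg)$survivors
  sb <- run_cascade(b, panel, cfg)$survivors
  sab <- run_cascade(as_variant_table(rbind(as.data.frame(a),
                                            as.data.frame(b))),
                     panel, cfg)$survivors
  k <- function(x) sort(paste(x$patient_id, variant_key(x)))
  expect_equal(k(sab), sort(c(k(sa), k(sb))))
  # idempotence: re-filtering the survivors changes nothing
  again <- run_cascade(sa[, setdiff(names(sa), "db_status")], panel,
                       cfg)$survivors
  expect_equal(k(again), k(sa))
})

test_that("tightening thresholds never grows the survivor set (and vice versa)", {
  panel <- read_gene_panel()
  v <- random_cohort(400, 42, panel)
  k <- function(x) paste(x$patient_id, variant_key(x))
  base <- k(run_cascade(v, panel, cfg)$survivors)
  looser_maf <- k(run_cascade(v, panel,
                              pipeline_config(maf_threshold = 0.05))$survivors)
  expect_true(all(base %in% looser_maf))
  stricter_depth <- k(run_cascade(v, panel,
                                  pipeline_config(min_depth = 50))$survivors)
  expect_true(all(stricter_depth %in% base))
  stricter_votes <- k(run_cascade(
    v, panel, pipeline_config(min_deleterious_votes = 4))$survivors)
  expect_true(all(stricter_votes %in% base))
})
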