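# Builders for small in-code fixtures.

# one (or more) fully specified annotated call(s); any field overridable
make_variants <- function(n = 1, patient_id = "P1", chrom = "chr1",
                          pos = seq_len(n) * 100L, ref = "A", alt = "G",
                          gene = "SCN1A", consequence = "missense",
                          depth = 60, genotype = "het",
                          maf_KRGDB = NA_real_, maf_ExAC = NA_real_,
                          predictors = "tolerated", gerp_rs = NA_real_,
                          clinvar = "absent", hgmd = "absent", ...) {
  df <- data.frame(patient_id = patient_id, chrom = chrom, pos = pos,
                   ref = ref, alt = alt, gene = gene,
                   consequence = consequence, depth = depth,
                   genotype = genotype, maf_KRGDB = maf_KRGDB,
                   maf_ExAC = maf_ExAC, stringsAsFactors = FALSE)
  for (p in predictor_names()) df[[p]] <- predictors
  df$gerp_rs <- gerp_rs
  df$clinvar <- clinvar
  df$hgmd <- hgmd
  flags <- list(...)
  for (f in names(flags)) df[[f]] <- flags[[f]]
  as_variant_table(df)
}

# a variant whose profile passes every cascade step on the packaged panel
make_passing_variant <- function(patient_id = "P1", gene = "SCN1A",
                                 pos = 100L, ...) {
  make_variants(patient_id = patient_id, gene = gene, pos = pos,
                predictors = "deleterious", gerp_rs = 5.5, ...)
}

small_panel <- function() {
  data.frame(gene = c("SCN1A", "CLN3", "TSC1", "RELN"),
             category = c("epilepsy_gene", "epilepsy_gene",
                          "neurodevelopment_gene", "neurodevelopment_gene"),
             inheritance = c("dominant", "recessive", "dominant", "dominant"),
             functional_class = c("ion_channel", "other", "mtor", "ecm"),
             alias = "", stringsAsFactors = FALSE)
}

# random annotated cohorts for property tests (deliberately messy: mixed
# depths, frequencies, predictor calls, on/off-panel genes)
random_cohort <- function(n, seed, panel = read_gene_panel()) {
  set.seed(seed)
  preds <- matrix(sample(c("deleterious", "tolerated", NA), 10 * n,
                         replace = TRUE, prob = c(.3, .5, .2)), nrow = n)
  colnames(preds) <- predictor_names()
  df <- data.frame(
    patient_id = sample(sprintf("P%02d", 1:20), n, replace = TRUE),
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C"), n, replace = TRUE),
    alt = sample(c("G", "T"), n, replace = TRUE),
    gene = sample(c(panel$gene[1:30], "BRCA1", "TTN"), n, replace = TRUE),
    consequence = sample(consequence_levels(), n, replace = TRUE),
    depth = sample(10:80, n, replace = TRUE),
    genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
    maf_KRGDB = ifelse(runif(n) < .4, NA, runif(n, 0, 0.05)),
    maf_ExAC = ifelse(runif(n) < .4, NA, runif(n, 0, 0.05)),
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(preds, stringsAsFactors = FALSE))
  df$gerp_rs <- ifelse(runif(n) < .3, NA, runif(n, 0, 6.5))
  df$clinvar <- sample(c("pathogenic", "benign", "uncertain", "absent"),
                       n, replace = TRUE)
  df$hgmd <- sample(c("disease_mutation", "benign", "uncertain", "absent"),
                    n, replace = TRUE)
  as_variant_table(df)
}

# the five cascade predicates as pure, order-free filters
cascade_predicates <- function(panel, cfg) {
  list(
    depth = function(v) filter_by_depth(v, cfg)$pass,
    consequence = function(v) filter_by_consequence(v)$pass,
    panel = function(v) filter_by_panel(v, panel)$pass,
    frequency = function(v) filter_by_frequency(v, cfg)$pass,
    deleteriousness = function(v) filter_by_deleteriousness(v, cfg)$pass)
}
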