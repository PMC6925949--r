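# Synthetic cohorts with known ground truth. The generator emulates the
# structure of the published screen: ~243 adult patients, onset ages in
# 8:126:109 stratum proportions, a background of common / benign /
# low-quality calls that each fail at least one cascade step by
# construction, and planted rare deleterious variants in panel genes whose
# annotation profiles satisfy one of three evidence templates mirroring
# the published criteria sets.

#' Specification of a synthetic cohort
#'
#' @param n_patients number of patients (default 243, the published cohort
#'   size).
#' @param dr_fraction fraction of patients in the drug-resistant group.
#' @param n_background_variants_per_patient background calls drawn per
#'   patient from a shared site pool.
#' @param n_planted number of planted true-causal variants, each in a
#'   distinct patient (default 32, the published positive-patient count).
#' @param planted_profile list: `p_deleterious_call` (per-predictor
#'   probability of a deleterious call, > 0), `rare_af` (control-panel
#'   frequency of "known rare" planted sites, <= 1e-5), `template_weights`
#'   (named weights over the `ps4_missense`, `novel_missense`, `lof`
#'   evidence templates).
#' @param background_profile list: `common_af_range` (range of common
#'   background frequencies), `p_tolerated_call`.
#' @param onset_weights stratum weights (infantile, childhood, adulthood);
#'   default proportional to 8:126:109.
#' @param seed integer seed driving every draw.
#' @return validated list of class `epivar_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 243,
                        dr_fraction = 0.5,
                        n_background_variants_per_patient = 30,
                        n_planted = 32,
                        planted_profile = list(
                          p_deleterious_call = 0.9,
                          rare_af = 1e-5,
                          template_weights = c(ps4_missense = 0.6,
                                               novel_missense = 0.25,
                                               lof = 0.15)),
                        background_profile = list(
                          common_af_range = c(0.02, 0.4),
                          p_tolerated_call = 0.9),
                        onset_weights = c(infantile = 8, childhood = 126,
                                          adulthood = 109) / 243,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               dr_fraction = dr_fraction,
               n_background = as.integer(n_background_variants_per_patient),
               n_planted = as.integer(n_planted),
               planted_profile = planted_profile,
               background_profile = background_profile,
               onset_weights = onset_weights / sum(onset_weights),
               seed = as.integer(seed))
  class(spec) <- "epivar_cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_patients >= 0, spec$n_background >= 0, spec$n_planted >= 0,
            spec$dr_fraction >= 0, spec$dr_fraction <= 1,
            abs(sum(spec$onset_weights) - 1) < 1e-8)
  if (spec$n_planted > spec$n_patients)
    stop("cannot plant more variants than patients (one per patient)",
         call. = FALSE)
  pp <- spec$planted_profile
  if (is.null(pp$p_deleterious_call) || pp$p_deleterious_call <= 0)
    stop(paste("impossible planted profile: a causal variant cannot carry",
               "all-tolerated predictor calls (p_deleterious_call must be",
               "> 0)"), call. = FALSE)
  if (!is.null(pp$rare_af) && pp$rare_af > 1e-5)
    stop("planted rare_af must be <= 1e-5", call. = FALSE)
  spec
}

# one seed, deterministic per-stage substreams: the k-th stage seed does
# not change when later stages are added
.stage_seeds <- function(seed, n = 10L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# genes used for planted variants: autosomal-dominant panel genes spanning
# the five named functional classes
.planted_gene_pool <- function(panel) {
  g <- panel[panel$inheritance == "dominant" &
               panel$functional_class != "other", , drop = FALSE]
  if (nrow(g) == 0) stop("panel has no dominant genes to plant in")
  g
}

# long-format frequency table for the two emulated reference panels
.sites_to_freqs <- function(sites) {
  n <- nrow(sites)
  long <- rbind(
    data.frame(sites[, c("chrom", "pos", "ref", "alt")],
               panel = rep_len("KRGDB", n), af = sites$af_krgdb,
               allele_number = rep_len(3708L, n), stringsAsFactors = FALSE),
    data.frame(sites[, c("chrom", "pos", "ref", "alt")],
               panel = rep_len("ExAC", n), af = sites$af_exac,
               allele_number = rep_len(121412L, n), stringsAsFactors = FALSE))
  rownames(long) <- NULL
  long
}

# shared site-level generation so the cohort and the reference-frequency
# table are guaranteed to agree
.generate_sites <- function(spec, panel, seeds) {
  n_bg_sites <- max(0L, max(200L, 5L * spec$n_background) *
                      (spec$n_background > 0))
  bgp <- spec$background_profile
  set.seed(seeds[1])
  bg <- NULL
  if (n_bg_sites > 0) {
    # each background site gets one built-in reason to fail the cascade
    modes <- sample(c("common_af", "synonymous", "off_panel", "few_votes",
                      "low_depth"), n_bg_sites, replace = TRUE)
    genes <- character(n_bg_sites)
    on_panel <- modes != "off_panel"
    genes[on_panel] <- sample(panel$gene, sum(on_panel), replace = TRUE)
    genes[!on_panel] <- sample(c("BRCA1", "TTN", "APOE", "CFTR", "MYH7",
                                 "OBSCN", "MUC16"), sum(!on_panel),
                               replace = TRUE)
    af <- stats::runif(n_bg_sites, bgp$common_af_range[1],
                       bgp$common_af_range[2])
    # only the common_af mode needs a frequency above the exclusion
    # threshold; the other modes stay rare so they exercise later filters
    rare <- modes != "common_af"
    af[rare] <- stats::runif(sum(rare), 1e-4, 5e-3)
    bg <- data.frame(
      site_id = sprintf("bg%05d", seq_len(n_bg_sites)),
      kind = "background", mode = modes, gene = genes,
      chrom = sample(paste0("chr", 1:22), n_bg_sites, replace = TRUE),
      pos = sample.int(2e8, n_bg_sites),
      ref = sample(c("A", "C", "G", "T"), n_bg_sites, replace = TRUE),
      af_krgdb = af, af_exac = af,
      template = NA_character_, stringsAsFactors = FALSE)
    bg$alt <- vapply(bg$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  }
  set.seed(seeds[2])
  pl <- NULL
  if (spec$n_planted > 0) {
    pool <- .planted_gene_pool(panel)
    w <- spec$planted_profile$template_weights
    templates <- sample(names(w), spec$n_planted, replace = TRUE,
                        prob = w / sum(w))
    gidx <- sample.int(nrow(pool), spec$n_planted, replace = TRUE)
    rare_af <- spec$planted_profile$rare_af
    pl <- data.frame(
      site_id = sprintf("pl%04d", seq_len(spec$n_planted)),
      kind = "planted", mode = "planted", gene = pool$gene[gidx],
      chrom = sample(paste0("chr", 1:22), spec$n_planted, replace = TRUE),
      pos = sample.int(2e8, spec$n_planted),
      ref = sample(c("A", "C", "G", "T"), spec$n_planted, replace = TRUE),
      af_krgdb = NA_real_, af_exac = NA_real_,
      template = templates, stringsAsFactors = FALSE)
    pl$alt <- vapply(pl$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    # "known rare" templates are present in the control panel at <= 1e-5;
    # "novel" templates are absent everywhere
    known <- pl$template == "ps4_missense"
    pl$af_exac[known] <- rare_af
    pl$af_krgdb[known] <- rare_af
  }
  sites <- rbind(bg, pl)
  if (is.null(sites))
    sites <- data.frame(site_id = character(), kind = character(),
                        mode = character(), gene = character(),
                        chrom = character(), pos = integer(),
                        ref = character(), af_krgdb = numeric(),
                        af_exac = numeric(), template = character(),
                        alt = character(), stringsAsFactors = FALSE)
  # collapse accidental key collisions
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos, sites$ref,
                                   sites$alt)), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Generate the reference allele-frequency table of a synthetic cohort
#'
#' Two emulated panels (`KRGDB`, `ExAC`) with `af` and `allele_number` per
#' site. Planted sites are absent (`NA`) or at frequency <= 1e-5;
#' background sites built to fail the frequency filter carry common
#' frequencies. Deterministic in (`spec`, `seed`).
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed`.
#' @param panel gene panel (defaults to the packaged panel).
#' @return frequency table as in [read_frequency_table()].
#' @export
generate_reference_frequencies <- function(spec, seed = spec$seed,
                                           panel = read_gene_panel()) {
  seeds <- .stage_seeds(seed)
  sites <- .generate_sites(spec, panel, seeds)
  .sites_to_freqs(sites)
}

.template_annotations <- function(template, p_del, cfg) {
  # predictor calls: mostly deleterious, GERP above the cutoff
  calls <- ifelse(stats::runif(10) < p_del, "deleterious", "tolerated")
  # guarantee the vote threshold deterministically: SIFT + MutationTaster
  calls[3:4] <- "deleterious"
  ann <- as.list(stats::setNames(calls, predictor_names()))
  ann$gerp_rs <- stats::runif(1, cfg$gerp_deleterious_cutoff, 6.2)
  ann$consequence <- "missense"
  ann$clinvar <- "pathogenic"
  ann$hgmd <- "disease_mutation"
  ann$lof_mechanism_gene <- FALSE
  ann$functional_study_damaging <- FALSE
  if (template == "lof") {
    ann$consequence <- sample(c("nonsense", "frameshift"), 1)
    ann$lof_mechanism_gene <- TRUE
    ann$functional_study_damaging <- TRUE
    ann$clinvar <- "absent"
    ann$hgmd <- "absent"
  }
  if (template == "novel_missense") {
    # stays pathogenic in ClinVar/HGMD -> PP5; absent from panels -> PM2
  }
  ann
}

#' Generate a fully synthetic annotated cohort with ground truth
#'
#' Produces per-patient annotated variant calls, the patient metadata
#' table, the matching reference-frequency table, and truth labels for
#' every planted variant. Background calls each fail at least one cascade
#' step by construction; planted calls survive the cascade and carry
#' evidence sufficient for their intended class under the ACMG engine
#' (templates: `ps4_missense` -> PS4+PM6+PP3+PP5 likely pathogenic;
#' `novel_missense` -> PM2+PM6+PP3+PP5 likely pathogenic; `lof` ->
#' PVS1+PS3+PM2+PM6+PP3 pathogenic). All randomness flows through the
#' single spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param panel gene panel (defaults to the packaged panel).
#' @param cfg an [pipeline_config()] object.
#' @return list with `variants` (an `epivar_variants` table), `patients`,
#'   `frequencies`, and `truth` (data.frame `patient_id`, `variant`,
#'   `gene`, `template`, `intended_class`).
#' @export
generate_cohort <- function(spec, panel = read_gene_panel(),
                            cfg = pipeline_config()) {
  seeds <- .stage_seeds(spec$seed)
  sites <- .generate_sites(spec, panel, seeds)

  set.seed(seeds[3])
  n <- spec$n_patients
  strata <- c("infantile", "childhood", "adulthood")
  stratum <- if (n) sample(strata, n, replace = TRUE,
                           prob = spec$onset_weights) else character()
  age_onset <- integer(n)
  age_onset[stratum == "infantile"] <- sample(0:1, sum(stratum == "infantile"),
                                              replace = TRUE)
  age_onset[stratum == "childhood"] <- sample(2:18, sum(stratum == "childhood"),
                                              replace = TRUE)
  age_onset[stratum == "adulthood"] <- sample(19:55, sum(stratum == "adulthood"),
                                              replace = TRUE)
  n_dr <- round(spec$dr_fraction * n)
  drug <- sample(rep(c("DR", "DS"), c(n_dr, n - n_dr)))
  patients <- data.frame(
    patient_id = sprintf("SP%03d", seq_len(n)),
    sex = if (n) sample(c("M", "F"), n, replace = TRUE) else character(),
    age_recruit = pmin(age_onset + sample(1:30, n, replace = TRUE), 84L),
    age_onset = age_onset,
    drug_group = drug,
    classification = if (n) sample(c("focal", "generalized", "unknown"), n,
                                   replace = TRUE, prob = c(.88, .09, .03))
                     else character(),
    etiology = if (n) sample(c("Non-lesional", "HS", "FCD", "Trauma", "Tumor"),
                             n, replace = TRUE,
                             prob = c(.5, .2, .12, .12, .06)) else character(),
    febrile_seizure = if (n) sample(c("Y", "N"), n, replace = TRUE,
                                    prob = c(.2, .8)) else character(),
    stringsAsFactors = FALSE)

  set.seed(seeds[4])
  bg_sites <- sites[sites$kind == "background", , drop = FALSE]
  rows <- list()
  if (n > 0 && spec$n_background > 0 && nrow(bg_sites) > 0) {
    k <- min(spec$n_background, nrow(bg_sites))
    picks <- lapply(seq_len(n), function(i) sample.int(nrow(bg_sites), k))
    idx <- unlist(picks)
    b <- bg_sites[idx, , drop = FALSE]
    m <- nrow(b)
    bgp <- spec$background_profile
    calls <- matrix(ifelse(stats::runif(10 * m) < bgp$p_tolerated_call,
                           "tolerated", NA_character_), nrow = m)
    # few_votes sites carry exactly one deleterious call (below threshold)
    fv <- b$mode == "few_votes"
    calls[fv, 3] <- "deleterious"
    calls[fv, 4] <- "tolerated"
    # off-panel and common sites may look damaging; panel/frequency stops them
    dmg <- b$mode %in% c("off_panel", "common_af")
    calls[dmg, 3:8] <- "deleterious"
    bg <- data.frame(
      patient_id = rep(patients$patient_id, each = k),
      chrom = b$chrom, pos = b$pos, ref = b$ref, alt = b$alt, gene = b$gene,
      hgvs_p = NA_character_,
      consequence = ifelse(b$mode == "synonymous",
                           sample(c("synonymous", "other"), m, replace = TRUE),
                           "missense"),
      depth = ifelse(b$mode == "low_depth",
                     sample(5:29, m, replace = TRUE),
                     sample(31:120, m, replace = TRUE)),
      genotype = sample(c("het", "hom_alt"), m, replace = TRUE,
                        prob = c(.7, .3)),
      maf_KRGDB = b$af_krgdb, maf_ExAC = b$af_exac,
      stringsAsFactors = FALSE)
    # low-depth/synonymous sites in rare bands must still fail their own
    # step only; give them sub-threshold votes so no accidental survivor
    colnames(calls) <- predictor_names()
    sub <- b$mode %in% c("low_depth", "synonymous")
    calls[sub, c(3:8)][calls[sub, 3:8] == "deleterious"] <- "tolerated"
    bg <- cbind(bg, as.data.frame(calls, stringsAsFactors = FALSE))
    bg$gerp_rs <- stats::runif(m, 0, 3.5)
    bg$clinvar <- sample(c("benign", "uncertain", "absent"), m, replace = TRUE)
    bg$hgmd <- sample(c("benign", "uncertain", "absent"), m, replace = TRUE)
    rows$background <- bg
  }

  set.seed(seeds[5])
  truth <- data.frame(patient_id = character(), variant = character(),
                      gene = character(), template = character(),
                      intended_class = character(), stringsAsFactors = FALSE)
  pl_sites <- sites[sites$kind == "planted", , drop = FALSE]
  if (nrow(pl_sites) > 0 && n > 0) {
    carriers <- sample(patients$patient_id, nrow(pl_sites))
    pp <- spec$planted_profile
    pls <- lapply(seq_len(nrow(pl_sites)), function(i) {
      s <- pl_sites[i, ]
      ann <- .template_annotations(s$template, pp$p_deleterious_call, cfg)
      row <- data.frame(
        patient_id = carriers[i], chrom = s$chrom, pos = s$pos, ref = s$ref,
        alt = s$alt, gene = s$gene, hgvs_p = sprintf("p.Sim%dXaa", i),
        consequence = ann$consequence,
        depth = sample(40:150, 1), genotype = "het",
        maf_KRGDB = s$af_krgdb, maf_ExAC = s$af_exac,
        stringsAsFactors = FALSE)
      for (p in predictor_names()) row[[p]] <- ann[[p]]
      row$gerp_rs <- ann$gerp_rs
      row$clinvar <- ann$clinvar
      row$hgmd <- ann$hgmd
      row$lof_mechanism_gene <- ann$lof_mechanism_gene
      row$functional_study_damaging <- ann$functional_study_damaging
      row$assumed_de_novo <- TRUE
      row
    })
    pl <- do.call(rbind, pls)
    rows$planted <- pl
    truth <- data.frame(
      patient_id = carriers,
      variant = paste(pl_sites$chrom, pl_sites$pos, pl_sites$ref,
                      pl_sites$alt, sep = ":"),
      gene = pl_sites$gene,
      template = pl_sites$template,
      intended_class = ifelse(pl_sites$template == "lof", "pathogenic",
                              "likely_pathogenic"),
      stringsAsFactors = FALSE)
  }

  variants <- if (length(rows)) {
    all <- Reduce(function(a, b) {
      for (col in setdiff(names(b), names(a))) a[[col]] <- FALSE
      for (col in setdiff(names(a), names(b))) b[[col]] <- FALSE
      rbind(a, b[names(a)])
    }, rows)
    all <- all[order(all$patient_id, all$chrom, all$pos), , drop = FALSE]
    as_variant_table(all)
  } else {
    variant_table(character(), character(), integer(), character(),
                  character(), character(), character(), numeric(),
                  character())
  }

  list(variants = variants, patients = patients,
       frequencies = .sites_to_freqs(sites), truth = truth)
}

#' Plant a two-hit patient into a synthetic cohort
#'
#' Adds two planted survivors in genes of different functional classes to
#' one patient who currently carries no planted variant, incrementing the
#' expected multi-hit count by exactly one.
#'
#' @param cohort result of [generate_cohort()].
#' @param gene_a,gene_b panel genes of distinct functional classes.
#' @param seed integer seed for the added annotations.
#' @param panel gene panel (defaults to the packaged panel).
#' @param cfg an [pipeline_config()] object.
#' @return the modified cohort list.
#' @export
plant_two_hit_patient <- function(cohort, gene_a, gene_b, seed,
                                  panel = read_gene_panel(),
                                  cfg = pipeline_config()) {
  meta <- panel_lookup(c(gene_a, gene_b), panel)
  if (any(is.na(meta$gene)))
    stop("both genes must be on the panel", call. = FALSE)
  if (meta$functional_class[1] == meta$functional_class[2])
    stop("the two genes must belong to different functional classes",
         call. = FALSE)
  free <- setdiff(cohort$patients$patient_id, cohort$truth$patient_id)
  if (!length(free))
    stop("no patient without a planted variant left", call. = FALSE)
  set.seed(seed)
  pid <- sample(free, 1)
  rows <- lapply(c(gene_a, gene_b), function(g) {
    ann <- .template_annotations("novel_missense", 0.95, cfg)
    row <- data.frame(
      patient_id = pid, chrom = sample(paste0("chr", 1:22), 1),
      pos = sample.int(2e8, 1), ref = "A", alt = "G", gene = g,
      hgvs_p = sprintf("p.TwoHit%s", g), consequence = ann$consequence,
      depth = sample(40:150, 1), genotype = "het",
      maf_KRGDB = NA_real_, maf_ExAC = NA_real_, stringsAsFactors = FALSE)
    for (p in predictor_names()) row[[p]] <- ann[[p]]
    row$gerp_rs <- ann$gerp_rs
    row$clinvar <- ann$clinvar
    row$hgmd <- ann$hgmd
    row$assumed_de_novo <- TRUE
    row
  })
  add <- do.call(rbind, rows)
  v <- as.data.frame(cohort$variants)
  for (col in setdiff(names(v), names(add))) add[[col]] <- FALSE
  cohort$variants <- as_variant_table(rbind(v, add[names(v)]))
  cohort$frequencies <- rbind(
    cohort$frequencies,
    data.frame(chrom = add$chrom, pos = add$pos, ref = add$ref,
               alt = add$alt, panel = rep(c("KRGDB", "ExAC"), each = 2),
               af = NA_real_, allele_number = rep(c(3708L, 121412L), each = 2),
               stringsAsFactors = FALSE))
  cohort$truth <- rbind(cohort$truth, data.frame(
    patient_id = pid,
    variant = paste(add$chrom, add$pos, add$ref, add$alt, sep = ":"),
    gene = add$gene, template = "novel_missense",
    intended_class = "likely_pathogenic", stringsAsFactors = FALSE))
  cohort
}
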