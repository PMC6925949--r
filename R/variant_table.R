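# Canonical tabular data model. One row per variant call; the TSV dialect
# written by write_variant_table() is the internal interchange format.

#' Names of the ten categorical deleteriousness predictors
#'
#' Column order is fixed; the two PolyPhen-2 scores and the two meta scores
#' are collapsed into single voting units by [deleteriousness_votes()].
#' @return character vector of length 10.
#' @export
predictor_names <- function() {
  c("Polyphen2_HDIV", "Polyphen2_HVAR", "SIFT", "MutationTaster",
    "MutationAssessor", "LRT", "FATHMM", "PROVEAN", "MetaSVM", "MetaLR")
}

#' Accepted consequence tokens
#' @return character vector of the 7-token consequence vocabulary.
#' @export
consequence_levels <- function() {
  c("frameshift", "nonsense", "missense", "inframe_indel",
    "canonical_splice", "synonymous", "other")
}

# consequence classes treated as protein-disrupting by the cascade
damaging_consequences <- function() {
  c("frameshift", "nonsense", "missense", "inframe_indel", "canonical_splice")
}

clinvar_levels <- function() c("pathogenic", "benign", "uncertain", "absent")
hgmd_levels <- function() c("disease_mutation", "benign", "uncertain", "absent")

knowledge_flag_names <- function() {
  c("lof_mechanism_gene", "same_aa_change_known_pathogenic",
    "other_missense_same_residue_pathogenic", "functional_study_damaging",
    "assumed_de_novo")
}

# required columns; everything else in the schema is optional and filled
# with explicit missing values on read
.required_cols <- function() {
  c("patient_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
    "depth", "genotype")
}

.optional_cols <- function() {
  c("hgvs_p", predictor_names(), "gerp_rs", "clinvar", "hgmd",
    knowledge_flag_names())
}

#' Construct an annotated variant table
#'
#' Builds (and validates) the canonical variant table from vectors. Allele
#' frequencies per reference panel are supplied as `maf_<panel>` columns via
#' `...` or the `maf` argument; a missing value means the variant is absent
#' from that panel.
#'
#' @param patient_id,chrom,pos,ref,alt,gene core call identity columns.
#' @param consequence one of [consequence_levels()] per row.
#' @param depth read depth (x) per call.
#' @param genotype `"het"` or `"hom_alt"`.
#' @param hgvs_p protein-level change string (optional).
#' @param maf named list of numeric vectors, one per frequency panel, e.g.
#'   `list(KRGDB = ..., ExAC = ...)`; values in \[0, 1\] or `NA`.
#' @param predictions data.frame with the [predictor_names()] columns
#'   (values `"deleterious"`, `"tolerated"`, or `NA`) and `gerp_rs`.
#' @param clinvar,hgmd database assertion columns.
#' @param ... knowledge-flag columns (logical), see
#'   `knowledge_flag_names()`.
#' @return a validated `data.frame` of class `epivar_variants`.
#' @export
variant_table <- function(patient_id, chrom, pos, ref, alt, gene,
                          consequence, depth, genotype, hgvs_p = NA_character_,
                          maf = list(), predictions = NULL,
                          clinvar = "absent", hgmd = "absent", ...) {
  n <- length(pos)
  df <- data.frame(patient_id = rep_len(patient_id, n),
                   chrom = rep_len(chrom, n), pos = as.integer(pos),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   gene = rep_len(gene, n), hgvs_p = rep_len(hgvs_p, n),
                   consequence = rep_len(consequence, n),
                   depth = rep_len(as.numeric(depth), n),
                   genotype = rep_len(genotype, n), stringsAsFactors = FALSE)
  for (panel in names(maf))
    df[[paste0("maf_", panel)]] <- rep_len(as.numeric(maf[[panel]]), n)
  if (is.null(predictions)) {
    for (p in predictor_names()) df[[p]] <- rep_len(NA_character_, n)
    df$gerp_rs <- rep_len(NA_real_, n)
  } else {
    for (p in c(predictor_names(), "gerp_rs")) {
      df[[p]] <- rep_len(
        if (p %in% names(predictions)) predictions[[p]] else NA, n)
    }
  }
  df$clinvar <- rep_len(clinvar, n)
  df$hgmd <- rep_len(hgmd, n)
  flags <- list(...)
  for (f in knowledge_flag_names()) {
    df[[f]] <- rep_len(
      if (f %in% names(flags)) as.logical(flags[[f]]) else FALSE, n)
  }
  as_variant_table(df)
}

#' Validate and class a data.frame as a variant table
#'
#' Fills absent optional annotation columns with explicit missing values,
#' rejects columns outside the documented schema (in particular unknown
#' predictor columns), and enforces the row invariants: `pos >= 1`,
#' `depth >= 0`, frequencies in \[0, 1\], `ref != alt`, enumerated
#' consequence/genotype/database tokens.
#'
#' @param df a data.frame carrying at least the required columns.
#' @return the validated table with class `epivar_variants`.
#' @export
as_variant_table <- function(df) {
  req <- .required_cols()
  missing_req <- setdiff(req, names(df))
  if (length(missing_req))
    stop("variant table lacks required columns: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  known <- c(req, .optional_cols())
  extra <- setdiff(names(df), known)
  extra <- extra[!grepl("^maf_", extra)]
  if (length(extra))
    stop("unknown variant-table columns (predictor names are a fixed set): ",
         paste(extra, collapse = ", "), call. = FALSE)
  for (col in setdiff(.optional_cols(), names(df))) {
    df[[col]] <- rep_len(switch(col,
      gerp_rs = NA_real_,
      hgvs_p = NA_character_,
      clinvar = "absent", hgmd = "absent",
      if (col %in% knowledge_flag_names()) FALSE else NA_character_),
      nrow(df))
  }
  for (f in knowledge_flag_names()) {
    df[[f]] <- as.logical(df[[f]])
    df[[f]][is.na(df[[f]])] <- FALSE
  }
  df$pos <- as.integer(df$pos)
  df$depth <- as.numeric(df$depth)
  df$gerp_rs <- as.numeric(df$gerp_rs)
  for (mc in grep("^maf_", names(df), value = TRUE)) df[[mc]] <- as.numeric(df[[mc]])

  .check_rows(df)
  # stable column order: identity, annotations, maf panels, predictors, db, flags
  ord <- c(req[1:6], "hgvs_p", "consequence", "depth", "genotype",
           sort(grep("^maf_", names(df), value = TRUE)),
           predictor_names(), "gerp_rs", "clinvar", "hgmd",
           knowledge_flag_names())
  df <- df[, ord]
  rownames(df) <- NULL
  class(df) <- c("epivar_variants", "data.frame")
  df
}

.check_rows <- function(df) {
  bad_line <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop("malformed variant row ", i[1], ": ", what, call. = FALSE)
  }
  bad_line(is.na(df$pos) | df$pos < 1, "pos must be >= 1")
  bad_line(is.na(df$depth) | df$depth < 0, "depth must be >= 0")
  bad_line(df$ref == df$alt, "ref and alt alleles must differ")
  bad <- !(df$consequence %in% consequence_levels())
  if (any(bad))
    stop("unknown consequence token '", df$consequence[which(bad)[1]],
         "' (row ", which(bad)[1], "); accepted tokens: ",
         paste(consequence_levels(), collapse = ", "), call. = FALSE)
  bad_line(!(df$genotype %in% c("het", "hom_alt")),
           "genotype must be 'het' or 'hom_alt'")
  for (mc in grep("^maf_", names(df), value = TRUE)) {
    v <- df[[mc]]
    bad_line(!is.na(v) & (v < 0 | v > 1),
             paste0(mc, " must lie in [0, 1]"))
  }
  for (p in predictor_names()) {
    v <- df[[p]]
    bad_line(!is.na(v) & !(v %in% c("deleterious", "tolerated")),
             paste0(p, " must be 'deleterious', 'tolerated', or missing"))
  }
  bad_line(!(df$clinvar %in% clinvar_levels()),
           "clinvar must be one of pathogenic/benign/uncertain/absent")
  bad_line(!(df$hgmd %in% hgmd_levels()),
           "hgmd must be one of disease_mutation/benign/uncertain/absent")
  invisible(df)
}

#' A stable per-call key `chrom:pos:ref:alt`
#' @param df a variant table (or any data.frame with the four columns).
#' @return character vector of variant keys.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Read an annotated variant table
#'
#' `dialect = "tsv"` reads the canonical tab-delimited dialect written by
#' [write_variant_table()]. `dialect = "vcf"` ingests a VCF 4.x file
#' (single- or multi-sample) via the vcfR parser: per-sample `GT` and `DP`
#' genotype fields are honoured, and annotations are mapped from INFO keys
#' `GENE`, `HGVSP`, `CSQ` (a SnpEff-style consequence term, translated by
#' [map_snpeff_consequence()]), `MAF_<PANEL>`, `PRED_<predictor>`
#' (`D`/`T`), `GERP_RS`, `CLINVAR`, `HGMD`, and upper-cased knowledge-flag
#' keys (`Flag` type).
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return an `epivar_variants` table (possibly with zero rows).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tsv") .read_variants_tsv(path) else .read_variants_vcf(path)
}

.read_variants_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0) {
    empty <- variant_table(character(), character(), integer(), character(),
                           character(), character(), character(), numeric(),
                           character())
    return(empty)
  }
  as_variant_table(df)
}

#' Write a variant table in the canonical TSV dialect
#'
#' Deterministic, column-stable output; `read_variant_table()` of the result
#' reproduces the input table exactly.
#'
#' @param df an `epivar_variants` table.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  df <- as_variant_table(as.data.frame(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Map a SnpEff-style consequence term onto the 7-token vocabulary
#'
#' Unrecognised terms map to `"other"`; the packaged lookup covers the
#' common SnpEff/Sequence Ontology annotations.
#'
#' @param term character vector of annotation terms.
#' @return character vector over [consequence_levels()].
#' @export
map_snpeff_consequence <- function(term) {
  lut <- c(frameshift_variant = "frameshift",
           stop_gained = "nonsense",
           stop_lost = "nonsense",
           start_lost = "nonsense",
           missense_variant = "missense",
           inframe_insertion = "inframe_indel",
           inframe_deletion = "inframe_indel",
           disruptive_inframe_insertion = "inframe_indel",
           disruptive_inframe_deletion = "inframe_indel",
           conservative_inframe_insertion = "inframe_indel",
           conservative_inframe_deletion = "inframe_indel",
           splice_acceptor_variant = "canonical_splice",
           splice_donor_variant = "canonical_splice",
           synonymous_variant = "synonymous")
  # pass canonical tokens through unchanged
  out <- ifelse(term %in% consequence_levels(), term,
                unname(lut[term]))
  out[is.na(out)] <- "other"
  out
}

.read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(variant_table(character(), character(), integer(), character(),
                         character(), character(), character(), numeric(),
                         character()))
  info_str <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  info_flag <- function(key) {
    info <- v@fix[, "INFO"]
    grepl(paste0("(^|;)", key, "($|;|=)"), info)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  samples <- colnames(gt)
  rows <- list()
  for (s in samples) {
    g <- gt[, s]
    called <- !is.na(g) & !(g %in% c("0/0", "0|0", "./.", "."))
    if (!any(called)) next
    geno <- ifelse(g[called] %in% c("1/1", "1|1"), "hom_alt", "het")
    idx <- which(called)
    base <- data.frame(
      patient_id = s,
      chrom = fix$CHROM[idx],
      pos = as.integer(fix$POS[idx]),
      ref = fix$REF[idx],
      alt = fix$ALT[idx],
      gene = info_str("GENE")[idx],
      hgvs_p = info_str("HGVSP")[idx],
      consequence = map_snpeff_consequence(info_str("CSQ")[idx]),
      depth = if (is.null(dp)) NA_real_ else as.numeric(dp[idx, s]),
      genotype = geno,
      stringsAsFactors = FALSE)
    info_keys <- unique(unlist(regmatches(
      v@fix[idx, "INFO"], gregexpr("(^|;)[A-Za-z0-9_]+", v@fix[idx, "INFO"]))))
    info_keys <- sub("^;", "", info_keys)
    for (k in grep("^MAF_", info_keys, value = TRUE)) {
      base[[paste0("maf_", sub("^MAF_", "", k))]] <- as.numeric(info_str(k)[idx])
    }
    for (p in predictor_names()) {
      call <- info_str(paste0("PRED_", toupper(p)))[idx]
      base[[p]] <- c(D = "deleterious", T = "tolerated")[call]
    }
    base$gerp_rs <- as.numeric(info_str("GERP_RS")[idx])
    cv <- tolower(info_str("CLINVAR")[idx]); cv[is.na(cv)] <- "absent"
    hg <- tolower(info_str("HGMD")[idx]); hg[is.na(hg)] <- "absent"
    base$clinvar <- cv
    base$hgmd <- hg
    for (f in knowledge_flag_names()) base[[f]] <- info_flag(toupper(f))[idx]
    rows[[s]] <- base
  }
  if (!length(rows)) {
    return(variant_table(character(), character(), integer(), character(),
                         character(), character(), character(), numeric(),
                         character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  as_variant_table(out)
}

#' Read patient metadata
#'
#' Tab-delimited with columns `patient_id`, `sex`, `age_recruit`,
#' `age_onset`, `drug_group` (`DR`/`DS`), `classification`
#' (`focal`/`generalized`/`unknown`), `etiology` (reserved token
#' `"Non-lesional"`), `febrile_seizure` (`Y`/`N`/`NA`).
#'
#' @param path input TSV.
#' @return data.frame of patient records.
#' @export
read_patient_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  validate_patient_table(df)
}

#' Validate a patient metadata table
#' @param df data.frame of patient records.
#' @return the validated data.frame.
#' @export
validate_patient_table <- function(df) {
  req <- c("patient_id", "age_onset", "drug_group")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("patient table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in patient table", call. = FALSE)
  if (!all(df$drug_group %in% c("DR", "DS")))
    stop("drug_group must be 'DR' or 'DS'", call. = FALSE)
  if ("classification" %in% names(df) &&
      !all(df$classification %in% c("focal", "generalized", "unknown")))
    stop("classification must be focal/generalized/unknown", call. = FALSE)
  if ("age_recruit" %in% names(df)) {
    bad <- !is.na(df$age_recruit) & df$age_onset > df$age_recruit
    if (any(bad))
      stop("age_onset exceeds age_recruit for patient ",
           df$patient_id[which(bad)[1]], call. = FALSE)
  }
  df
}

#' Write a patient metadata table
#' @param df patient records.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
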