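# Machine-readable encodings of the published classification and cohort
# tables, packaged so the classification engine and the yield analytics can
# be exercised against the printed results without any download.

#' Load the published classified-variant table
#'
#' 26 pathogenic / likely pathogenic variants in 15 panel genes, with the
#' printed odds ratio, 95% CI, ACMG criteria string, and interpretation.
#' Three rows (variants absent from the reference panels) carry missing
#' OR/CI.
#'
#' @return data.frame with columns `gene`, `chrom`, `pos`, `hgvs_p`,
#'   `or_value`, `ci_low`, `ci_high`, `criteria` (comma-joined code string),
#'   `interpretation`.
#' @examples
#' t3 <- load_fixture_classified()
#' nrow(t3)           # 26
#' sum(is.na(t3$or_value))  # 3
#' @export
load_fixture_classified <- function() {
  path <- system.file("extdata", "classified_variants_published.tsv",
                      package = "epivar", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  df$pos <- as.integer(df$pos)
  df
}

#' Load the published cohort table of presumed disease-causative variants
#'
#' 37 variant-patient rows over 32 distinct patients (five patients carry
#' two variants). Each row pairs a variant key (`gene`, `hgvs_p`,
#' `functional_class` section) with the patient's metadata fragment (sex,
#' recruitment and onset ages, drug-response group, febrile-seizure
#' history, epilepsy classification, etiology) plus flags marking the three
#' pathogenic variants and the two-hit patients.
#'
#' @return data.frame of 37 rows.
#' @export
load_fixture_cohort <- function() {
  path <- system.file("extdata", "cohort_variants_published.tsv",
                      package = "epivar", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  df$age_recruit <- as.integer(df$age_recruit)
  df$age_onset <- as.integer(df$age_onset)
  df$pathogenic <- as.logical(df$pathogenic)
  df$two_hit <- as.logical(df$two_hit)
  df
}

#' Patient records of the published cohort fixture
#'
#' One row per distinct patient of [load_fixture_cohort()] (n = 32).
#'
#' @return data.frame of patient records.
#' @export
fixture_patients <- function() {
  t4 <- load_fixture_cohort()
  pt <- t4[!duplicated(t4$patient_id),
           c("patient_id", "sex", "age_recruit", "age_onset", "drug_group",
             "febrile_seizure", "classification", "etiology")]
  rownames(pt) <- NULL
  validate_patient_table(pt)
}

#' Cohort denominators of the published screen
#'
#' The full screened cohort: 243 patients; onset strata 8 infantile /
#' 126 childhood / 109 adulthood; drug-response groups 121 DS / 122 DR.
#' Used to compute yields when only the positive patients are tabulated.
#'
#' @param n_patients,strata,groups override the published counts.
#' @return a named list of class `epivar_denominators`.
#' @export
cohort_denominators <- function(n_patients = 243,
                                strata = c(infantile = 8, childhood = 126,
                                           adulthood = 109),
                                groups = c(DS = 121, DR = 122)) {
  stopifnot(sum(strata) == n_patients, sum(groups) == n_patients)
  structure(list(n_patients = n_patients, strata = strata, groups = groups),
            class = "epivar_denominators")
}
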