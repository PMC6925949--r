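# Cohort-level analytics: onset strata, recessive-heterozygote exclusion,
# compound-heterozygote detection, diagnostic yields, and the DR/DS group
# contrasts.

#' Onset-age stratum
#'
#' Onset at or below `cfg$infantile_max` (default 1 year) is infantile; up
#' to `cfg$childhood_max` (default 18) childhood; above that adulthood.
#'
#' @param age_onset seizure-onset ages in years (>= 0).
#' @param cfg an [pipeline_config()] object.
#' @return character vector over `{infantile, childhood, adulthood}`.
#' @export
onset_stratum <- function(age_onset, cfg = pipeline_config()) {
  if (any(is.na(age_onset) | age_onset < 0))
    stop("age_onset must be non-negative", call. = FALSE)
  ifelse(age_onset <= cfg$infantile_max, "infantile",
         ifelse(age_onset <= cfg$childhood_max, "childhood", "adulthood"))
}

#' Detect candidate compound-heterozygote pairs
#'
#' Two or more distinct heterozygous P/LP variants in the same recessive
#' gene in one patient are flagged as a candidate compound-heterozygote
#' pair (and thus satisfy the recessive genotype).
#'
#' @param classified classified-variant table with `patient_id`, `gene`,
#'   `genotype`, `label` columns.
#' @param panel gene panel from [read_gene_panel()].
#' @return data.frame with one row per (patient, gene) pair: `patient_id`,
#'   `gene`, `n_variants`.
#' @export
detect_compound_het <- function(classified, panel) {
  plp <- classified[classified$label %in% c("pathogenic", "likely_pathogenic"), ,
                    drop = FALSE]
  if (nrow(plp) == 0)
    return(data.frame(patient_id = character(), gene = character(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  inh <- panel_lookup(plp$gene, panel)$inheritance
  het_rec <- plp$genotype == "het" & !is.na(inh) & inh == "recessive"
  cand <- plp[het_rec, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(patient_id = character(), gene = character(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  key <- paste(cand$patient_id, cand$gene, sep = "\r")
  distinct <- !duplicated(paste(key, variant_key(cand)))
  tab <- table(key[distinct])
  hit <- names(tab)[tab >= 2]
  if (!length(hit))
    return(data.frame(patient_id = character(), gene = character(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(hit, "\r", fixed = TRUE)
  data.frame(patient_id = vapply(parts, `[`, "", 1),
             gene = vapply(parts, `[`, "", 2),
             n_variants = as.integer(tab[hit]),
             stringsAsFactors = FALSE)
}

#' Exclude lone heterozygotes in recessive genes
#'
#' A P/LP variant that is heterozygous, lies in a gene of recessive
#' inheritance, and is not part of a candidate compound-heterozygote pair
#' in its carrier does not satisfy the inheritance model and is moved to
#' the excluded set (it is dropped from yield calculations, not
#' re-classified).
#'
#' @inheritParams detect_compound_het
#' @return list with `retained`, `excluded` (subsets of `classified`), and
#'   `counts` (named: retained, excluded_recessive_het, compound_het_pairs).
#' @export
recessive_het_exclusion <- function(classified, panel) {
  if (nrow(classified) == 0)
    return(list(retained = classified, excluded = classified,
                counts = c(retained = 0L, excluded_recessive_het = 0L,
                           compound_het_pairs = 0L)))
  plp <- classified$label %in% c("pathogenic", "likely_pathogenic")
  inh <- panel_lookup(classified$gene, panel)$inheritance
  lone_het <- plp & classified$genotype == "het" &
    !is.na(inh) & inh == "recessive"
  pairs <- detect_compound_het(classified, panel)
  if (nrow(pairs)) {
    paired <- paste(classified$patient_id, classified$gene) %in%
      paste(pairs$patient_id, pairs$gene)
    lone_het <- lone_het & !paired
  }
  excluded <- classified[plp & lone_het, , drop = FALSE]
  retained <- classified[plp & !lone_het, , drop = FALSE]
  rownames(excluded) <- rownames(retained) <- NULL
  list(retained = retained, excluded = excluded,
       counts = c(retained = nrow(retained),
                  excluded_recessive_het = nrow(excluded),
                  compound_het_pairs = nrow(pairs)))
}

#' Diagnostic-yield report over a cohort
#'
#' Aggregates retained P/LP assignments over patients. A patient counts
#' once toward every yield regardless of how many P/LPs they carry;
#' stratum and group denominators come from the full patient table (or
#' from explicit [cohort_denominators()] when only the positive patients
#' are tabulated); the lesional fraction is the share of P/LP patients
#' whose etiology is not the reserved token `"Non-lesional"`; multi-hit
#' patients carry two or more retained P/LPs.
#'
#' @param assignments data.frame of retained P/LP variant-patient rows:
#'   columns `patient_id`, `gene`, and optionally `hgvs_p`,
#'   `functional_class` (looked up from `panel` when absent).
#' @param patients patient metadata table covering at least every assigned
#'   patient (columns `patient_id`, `age_onset`, `drug_group`, `etiology`).
#' @param denominators optional [cohort_denominators()]; defaults to counts
#'   derived from `patients`.
#' @param panel gene panel for functional-class lookup (optional when
#'   `assignments` has a `functional_class` column).
#' @param cfg an [pipeline_config()] object.
#' @param excluded_recessive_het count carried into the report.
#' @return object of class `epivar_report` (see [write_report()]).
#' @export
diagnostic_yield <- function(assignments, patients, denominators = NULL,
                             panel = NULL, cfg = pipeline_config(),
                             excluded_recessive_het = 0L) {
  patients <- validate_patient_table(patients)
  orphan <- setdiff(assignments$patient_id, patients$patient_id)
  if (length(orphan))
    stop("P/LP assignment references unknown patient: ", orphan[1],
         call. = FALSE)
  if (is.null(denominators)) {
    strata <- table(factor(onset_stratum(patients$age_onset, cfg),
                           levels = c("infantile", "childhood", "adulthood")))
    groups <- table(factor(patients$drug_group, levels = c("DS", "DR")))
    denominators <- cohort_denominators(nrow(patients),
                                        strata = c(strata), groups = c(groups))
  }
  pct <- function(num, den) {
    if (den == 0) return(c(num = num, den = den, percent = NA_real_))
    c(num = num, den = den, percent = round_half_up(100 * num / den, 1))
  }

  pos_ids <- unique(assignments$patient_id)
  pidx <- match(pos_ids, patients$patient_id)
  pos <- patients[pidx, , drop = FALSE]

  strata_num <- table(factor(onset_stratum(pos$age_onset, cfg),
                             levels = c("infantile", "childhood", "adulthood")))
  group_num <- table(factor(pos$drug_group, levels = c("DS", "DR")))

  hits_per_patient <- table(
    unique(assignments[, c("patient_id", "gene",
                           intersect("hgvs_p", names(assignments)))])$patient_id)
  multi_ids <- sort(as.character(names(hits_per_patient)[hits_per_patient >= 2]))

  etio <- if ("etiology" %in% names(pos)) pos$etiology else
    rep(NA_character_, nrow(pos))
  lesional_num <- sum(!is.na(etio) & etio != "Non-lesional")

  gene_yields <- if (nrow(assignments)) {
    sort(tapply(assignments$patient_id, assignments$gene,
                function(x) length(unique(x))), decreasing = TRUE)
  } else {
    integer(0)
  }

  if (nrow(assignments) == 0) {
    fclass <- character(0)
  } else if ("functional_class" %in% names(assignments)) {
    fclass <- assignments$functional_class
  } else {
    if (is.null(panel))
      stop("need 'panel' or a functional_class column to stratify by class",
           call. = FALSE)
    fclass <- panel_lookup(assignments$gene, panel)$functional_class
  }
  category_yields <- if (length(fclass)) {
    cy <- tapply(assignments$patient_id, fclass,
                 function(x) length(unique(x)))
    cy[order(-cy, names(cy))]
  } else {
    integer(0)
  }

  report <- list(
    n_patients = denominators$n_patients,
    n_plp_patients = length(pos_ids),
    overall_yield = pct(length(pos_ids), denominators$n_patients),
    strata_yields = list(
      infantile = pct(strata_num[["infantile"]],
                      denominators$strata[["infantile"]]),
      childhood = pct(strata_num[["childhood"]],
                      denominators$strata[["childhood"]]),
      adulthood = pct(strata_num[["adulthood"]],
                      denominators$strata[["adulthood"]])),
    group_yields = list(
      DS = pct(group_num[["DS"]], denominators$groups[["DS"]]),
      DR = pct(group_num[["DR"]], denominators$groups[["DR"]])),
    multi_hit = list(ids = multi_ids,
                     frac = pct(length(multi_ids), denominators$n_patients)),
    gene_yields = gene_yields,
    category_yields = category_yields,
    lesional_fraction = pct(lesional_num, length(pos_ids)),
    excluded_recessive_het = excluded_recessive_het)
  class(report) <- "epivar_report"
  report
}

#' @export
print.epivar_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

# human-readable summary lines (also written by write_report)
format_report <- function(x) {
  f <- function(p) sprintf("%d/%d (%s%%)", p[["num"]], p[["den"]],
                           format(p[["percent"]]))
  c("Cohort diagnostic-yield report",
    sprintf("  patients screened:          %d", x$n_patients),
    sprintf("  patients with P/LP:         %d", x$n_plp_patients),
    sprintf("  overall yield:              %s", f(x$overall_yield)),
    sprintf("  onset infantile (<=1 y):    %s", f(x$strata_yields$infantile)),
    sprintf("  onset childhood (2-18 y):   %s", f(x$strata_yields$childhood)),
    sprintf("  onset adulthood (>=19 y):   %s", f(x$strata_yields$adulthood)),
    sprintf("  drug-responsive (DS):       %s", f(x$group_yields$DS)),
    sprintf("  drug-resistant (DR):        %s", f(x$group_yields$DR)),
    sprintf("  multi-hit patients:         %s  [%s]", f(x$multi_hit$frac),
            paste(x$multi_hit$ids, collapse = ", ")),
    sprintf("  lesional among P/LP:        %s", f(x$lesional_fraction)),
    sprintf("  excluded recessive-het P/LP: %d", x$excluded_recessive_het),
    "  per-gene patient counts:",
    sprintf("    %-10s %d", names(x$gene_yields), x$gene_yields),
    "  per-class patient counts:",
    sprintf("    %-20s %d", names(x$category_yields), x$category_yields))
}

# flatten a report into the key-value TSV rows used by write_report
.report_rows <- function(x) {
  row <- function(section, key, p) {
    data.frame(section = section, key = key, numerator = p[["num"]],
               denominator = p[["den"]], percent = p[["percent"]],
               stringsAsFactors = FALSE)
  }
  cnt <- function(section, key, n) {
    data.frame(section = section, key = key, numerator = n,
               denominator = NA_real_, percent = NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("overall", "yield", x$overall_yield),
    row("onset_stratum", "infantile", x$strata_yields$infantile),
    row("onset_stratum", "childhood", x$strata_yields$childhood),
    row("onset_stratum", "adulthood", x$strata_yields$adulthood),
    row("drug_group", "DS", x$group_yields$DS),
    row("drug_group", "DR", x$group_yields$DR),
    row("multi_hit", "patients", x$multi_hit$frac),
    row("lesional", "fraction", x$lesional_fraction),
    cnt("excluded", "recessive_het", x$excluded_recessive_het))
  if (length(x$gene_yields))
    out <- rbind(out, do.call(rbind, lapply(names(x$gene_yields), function(g)
      cnt("gene", g, x$gene_yields[[g]]))))
  if (length(x$category_yields))
    out <- rbind(out, do.call(rbind, lapply(names(x$category_yields),
      function(g) cnt("functional_class", g, x$category_yields[[g]]))))
  out
}

#' Write a cohort report
#'
#' Writes a deterministic, column-stable key-value TSV plus a
#' human-readable summary (`<path>` with `.txt` substituted for the
#' extension, or `<path>_summary.txt`). Two writes of the same report are
#' byte-identical.
#'
#' @param report an `epivar_report`.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "epivar_report"))
  rows <- .report_rows(report)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  summary_path <- if (grepl("\\.tsv$", path))
    sub("\\.tsv$", "_summary.txt", path) else paste0(path, "_summary.txt")
  writeLines(format_report(report), summary_path)
  invisible(path)
}

#' Read back a written cohort report table
#' @param path TSV written by [write_report()].
#' @return data.frame of report rows.
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test via [stats::fisher.test()].
#'
#' @param a,b,c,d the four counts (row-wise).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(is.na(x) | x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(x) == 0) stop("all-zero table", call. = FALSE)
  stats::fisher.test(matrix(x, nrow = 2, byrow = TRUE))$p.value
}

#' Equal-variance two-sample t test
#'
#' Student's t (pooled variance) via [stats::t.test()]; returns the group
#' means alongside the two-sided p-value.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list with `mean_x`, `mean_y`, `statistic`, `p_value`.
#' @export
students_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(mean_x = mean(x), mean_y = mean(y),
       statistic = unname(tt$statistic), p_value = tt$p.value)
}
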