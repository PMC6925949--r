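#' Run the full variant-interpretation pipeline
#'
#' Cascade filtering, per-variant case-control association, ACMG
#' classification, recessive-heterozygote exclusion with
#' compound-heterozygote rescue, and the cohort diagnostic-yield report.
#'
#' @param variants annotated variant table ([read_variant_table()]).
#' @param panel gene panel ([read_gene_panel()]).
#' @param patients patient metadata ([read_patient_table()]).
#' @param freqs reference frequency table ([read_frequency_table()]).
#' @param cfg an [pipeline_config()] object.
#' @param denominators optional [cohort_denominators()] override.
#' @return list of class `epivar_run`: `survivors`, `trace`, `association`,
#'   `classified`, `retained`, `excluded`, `compound_het`, `report`.
#' @export
run_pipeline <- function(variants, panel, patients, freqs,
                         cfg = pipeline_config(), denominators = NULL) {
  patients <- validate_patient_table(patients)
  casc <- run_cascade(variants, panel, cfg)
  assoc <- associate_variants(casc$survivors, freqs, nrow(patients), cfg)
  classified <- classify_variants(casc$survivors, assoc, panel, cfg)
  excl <- recessive_het_exclusion(classified, panel)
  pairs <- detect_compound_het(classified, panel)
  report <- diagnostic_yield(
    excl$retained, patients, denominators = denominators, panel = panel,
    cfg = cfg,
    excluded_recessive_het = unname(excl$counts["excluded_recessive_het"]))
  structure(list(survivors = casc$survivors, trace = casc$trace,
                 association = assoc, classified = classified,
                 retained = excl$retained, excluded = excl$excluded,
                 compound_het = pairs, report = report),
            class = "epivar_run")
}

#' @export
print.epivar_run <- function(x, ...) {
  cat("<epivar pipeline run>\n")
  print(x$trace)
  cat(sprintf("  classified P/LP calls: %d (retained %d, excluded %d)\n",
              sum(x$classified$label %in%
                    c("pathogenic", "likely_pathogenic")),
              nrow(x$retained), nrow(x$excluded)))
  print(x$report)
  invisible(x)
}

#' Write the outputs of a pipeline run into a directory
#'
#' Emits the classified-variant TSV, the filter trace, the cohort report
#' TSV + summary, and the configuration echo.
#'
#' @param run an `epivar_run`.
#' @param dir output directory (created if needed).
#' @param cfg the configuration used (echoed as `config.yaml`).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, cfg = pipeline_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- run$classified
  class(cls) <- "data.frame"
  utils::write.table(cls, file.path(dir, "classified_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  write_trace(run$trace, file.path(dir, "filter_trace.tsv"))
  write_report(run$report, file.path(dir, "cohort_report.tsv"))
  write_config_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
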