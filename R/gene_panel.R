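# Gene panel: 178 epilepsy-associated genes (105 epilepsy genes + 73
# neurodevelopment-associated genes). Panel membership filtering is exact
# on the printed symbol; metadata lookups additionally resolve the `alias`
# column (the panel lists GPR98, whose current HGNC symbol is ADGRV1).

#' Read a gene-panel file
#'
#' Tab-delimited with header; columns `gene` and `category`
#' (`epilepsy_gene`/`neurodevelopment_gene`) are required, `inheritance`
#' (`dominant`/`recessive`/`x_linked`/`unknown`), `functional_class`
#' (`ion_channel`/`mtor`/`adhesion`/`signal_transduction`/`ecm`/`other`)
#' and `alias` are optional and default to unknown/other/none.
#'
#' @param path panel TSV; defaults to the packaged 178-gene panel.
#' @return data.frame of panel entries keyed by unique symbol.
#' @export
read_gene_panel <- function(path = epivar_panel_file()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  if (!all(c("gene", "category") %in% names(df)))
    stop("gene panel needs 'gene' and 'category' columns", call. = FALSE)
  if (anyDuplicated(df$gene))
    stop("duplicate gene symbol in panel: ",
         df$gene[duplicated(df$gene)][1], call. = FALSE)
  if (!all(df$category %in% c("epilepsy_gene", "neurodevelopment_gene")))
    stop("category must be epilepsy_gene or neurodevelopment_gene",
         call. = FALSE)
  if (!"inheritance" %in% names(df)) df$inheritance <- "unknown"
  if (!"functional_class" %in% names(df)) df$functional_class <- "other"
  if (!"alias" %in% names(df)) df$alias <- ""
  df$alias[is.na(df$alias)] <- ""
  stopifnot(all(df$inheritance %in%
                  c("dominant", "recessive", "x_linked", "unknown")),
            all(df$functional_class %in%
                  c("ion_channel", "mtor", "adhesion", "signal_transduction",
                    "ecm", "other")))
  df
}

#' Path to the packaged 178-gene panel fixture
#' @return file path.
#' @export
epivar_panel_file <- function() {
  system.file("extdata", "gene_panel.tsv", package = "epivar", mustWork = TRUE)
}

# match gene symbols against panel symbols or their aliases;
# returns row indices into the panel (NA when not found)
panel_match <- function(gene, panel) {
  i <- match(gene, panel$gene)
  j <- match(gene, panel$alias)
  ifelse(is.na(i), j, i)
}

#' Look up panel metadata for gene symbols
#'
#' Resolves symbols via the panel's `gene` column or its `alias` column.
#'
#' @param gene character vector of symbols.
#' @param panel a gene-panel data.frame from [read_gene_panel()].
#' @return data.frame with one row per input symbol (`NA` rows for symbols
#'   outside the panel).
#' @export
panel_lookup <- function(gene, panel) {
  idx <- panel_match(gene, panel)
  out <- panel[ifelse(is.na(idx), 1L, idx),
               c("gene", "category", "inheritance", "functional_class")]
  out[is.na(idx), ] <- NA
  out$query <- gene
  rownames(out) <- NULL
  out
}

#' Read a reference allele-frequency table
#'
#' Long-format TSV emulating KRGDB/ExAC lookups, keyed by
#' (`chrom`, `pos`, `ref`, `alt`) with columns `panel`, `af`, and
#' `allele_number`.
#'
#' @param path input TSV.
#' @return data.frame of per-panel site frequencies.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "panel", "af", "allele_number")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("frequency table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.na(df$af) & (df$af < 0 | df$af > 1)))
    stop("af must lie in [0, 1]", call. = FALSE)
  df$pos <- as.integer(df$pos)
  df
}

#' Write a reference allele-frequency table
#' @param df frequency table.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
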